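#' Canonical 10-10 scalp labels used by the default montage
#'
#' Sixty scalp positions of the extended international 10-10 system plus the
#' two mastoid references M1/M2. Recordings may carry extra channels; channels
#' outside every ROI are simply never pooled into an ROI mean.
#'
#' @return Character vector of 62 channel labels.
#' @export
default_montage <- function() {
  c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2",
    "M1", "M2"
  )
}

# legacy / variant spellings seen in published electrode tables
.label_aliases <- c(
  "T3" = "T7", "T4" = "T8", "T5" = "P7", "T6" = "P8",
  "A1" = "M1", "A2" = "M2"
)

#' Normalize an electrode label to its canonical 10-10 spelling
#'
#' Handles the spelling variants that appear in published ROI tables:
#' case variants (`"Afz"` -> `"AFz"`, `"Poz"` -> `"POz"`, `"Cp2"` -> `"CP2"`),
#' underscore decorations (`"O_2"` -> `"O2"`), legacy 10-20 names
#' (`"T6"` -> `"P8"`), and compound legacy-modern labels (`"T6-P8"` -> `"P8"`,
#' `"T4-T8"` -> `"T8"`). Unknown labels are passed through unchanged with a
#' warning. Normalization is idempotent.
#'
#' @param raw Character vector of labels.
#' @param warn Warn on labels that cannot be matched (default `TRUE`).
#' @return Character vector of canonical labels, same length as `raw`.
#' @export
#' @examples
#' normalize_label(c("O_2", "T6-P8", "Afz", "Fz"))
normalize_label <- function(raw, warn = TRUE) {
  stopifnot(is.character(raw))
  canon <- default_montage()
  one <- function(lab) {
    x <- gsub("_", "", trimws(lab))
    # compound "legacy-modern": resolve each part, prefer one that normalizes
    if (grepl("-", x, fixed = TRUE)) {
      parts <- strsplit(x, "-", fixed = TRUE)[[1]]
      for (p in rev(parts)) { # modern spelling conventionally listed last
        r <- one_simple(p, canon)
        if (!is.na(r)) return(r)
      }
      return(NA_character_)
    }
    one_simple(x, canon)
  }
  one_simple <- function(x, canon) {
    hit <- match(toupper(x), toupper(canon))
    if (!is.na(hit)) return(canon[hit])
    ali <- match(toupper(x), toupper(names(.label_aliases)))
    if (!is.na(ali)) return(unname(.label_aliases[ali]))
    NA_character_
  }
  out <- vapply(raw, one, character(1), USE.NAMES = FALSE)
  unknown <- is.na(out)
  if (any(unknown)) {
    if (warn) {
      warning("unrecognized channel label(s) passed through unchanged: ",
              paste(unique(raw[unknown]), collapse = ", "))
    }
    out[unknown] <- raw[unknown]
  }
  out
}

#' Default frequency-band definitions
#'
#' Theta (4-7 Hz), alpha (8-12 Hz), beta (13-30 Hz) and gamma (31-48 Hz), the
#' conventional bands for scalp EEG synchrony analysis.
#'
#' @return Named list of `band_spec` objects.
#' @export
band_specs <- function() {
  list(
    theta = band_spec("theta", 4, 7),
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 13, 30),
    gamma = band_spec("gamma", 31, 48)
  )
}

#' Construct a frequency-band specification
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(lo), is.numeric(hi), lo > 0, hi > lo)
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' Resolve a band argument to a `band_spec`
#'
#' Accepts a `band_spec`, a default band name (`"theta"`, `"alpha"`, `"beta"`,
#' `"gamma"`, including the Greek spellings), or a numeric `c(lo, hi)` pair.
#'
#' @param band Band designator.
#' @return A `band_spec`.
#' @export
as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1) {
    key <- c("θ" = "theta", "α" = "alpha",
             "β" = "beta", "γ" = "gamma")[band]
    nm <- if (!is.na(key)) unname(key) else band
    bands <- band_specs()
    if (!nm %in% names(bands)) {
      stop("unknown band name: ", band, call. = FALSE)
    }
    return(bands[[nm]])
  }
  if (is.numeric(band) && length(band) == 2) {
    return(band_spec(paste0(band[1], "-", band[2], "Hz"), band[1], band[2]))
  }
  stop("cannot interpret band argument", call. = FALSE)
}

#' Default six-region ROI map
#'
#' Electrode groupings for the six scalp regions used in speaker-listener
#' synchrony analyses: frontal (F), frontal-central (FC), parietal (P), left
#' and right temporoparietal (left_tp / right_tp) and occipital (O). Labels
#' are stored in canonical 10-10 spelling; no label belongs to two ROIs.
#'
#' @return Named list mapping ROI name to character vector of channel labels.
#' @export
default_roi_map <- function() {
  raw <- list(
    F = c("AF4", "F2", "FP2", "Fz", "Afz", "F1", "FP1", "AF3", "F3",
          "F5", "F7", "F8", "F6", "F4"),
    FC = c("Fcz", "FC1", "FC3", "C1", "C3", "C4", "C2", "FC4", "FC2"),
    P = c("CP1", "P5", "P3", "P1", "Pz", "P2", "Cp2", "P4", "P6"),
    left_tp = c("FC5", "FT7", "C5", "T7", "TP7", "CP5", "P7"),
    right_tp = c("T6-P8", "CP6", "TP8", "C6", "T4-T8", "FT8", "FC6"),
    O = c("PO3", "O1", "Poz", "Oz", "PO4", "O_2")
  )
  out <- lapply(raw, normalize_label, warn = FALSE)
  labs <- unlist(out, use.names = FALSE)
  stopifnot(!anyDuplicated(labs))
  out
}

#' Validate an ROI map against a montage
#'
#' @param rois Named list of label vectors.
#' @param montage Character vector of available (canonical) labels.
#' @return The normalized ROI map, invisibly on success.
#' @export
validate_roi_map <- function(rois, montage = default_montage()) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  rois <- lapply(rois, normalize_label, warn = FALSE)
  labs <- unlist(rois, use.names = FALSE)
  if (anyDuplicated(labs)) {
    stop("ROI map assigns label(s) to more than one ROI: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(labs, montage)
  if (length(missing)) {
    stop("ROI label(s) absent from montage: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(rois)
}
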