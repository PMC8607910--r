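#' Write a recording as a plain-text matrix with a JSON sidecar
#'
#' The signal goes to `<prefix>.tsv` (samples in rows, one column per
#' channel, header row of labels) and the metadata — sampling rate, labels,
#' role, condition, dyad id, units — to `<prefix>.json`.
#'
#' @param rec A `continuous_recording`.
#' @param prefix Output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "continuous_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$labels
  utils::write.table(format(m, digits = 8, trim = TRUE, scientific = FALSE),
                     paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(fs = rec$fs, labels = rec$labels, role = rec$role,
               condition = rec$condition, dyad_id = rec$dyad_id,
               units = "uV")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' Channel labels are normalized to canonical 10-10 spelling on read.
#'
#' @param prefix Path prefix (expects `<prefix>.tsv` + `<prefix>.json`).
#' @param role,condition Optional overrides of the sidecar values.
#' @return A `continuous_recording`.
#' @export
read_recording <- function(prefix, role = NULL, condition = NULL) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  for (f in c(tsv, js)) {
    if (!file.exists(f)) stop("cannot read recording: missing file ", f,
                              call. = FALSE)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs)) {
    stop("cannot read recording: sidecar ", js, " lacks a numeric fs",
         call. = FALSE)
  }
  m <- as.matrix(utils::read.delim(tsv, check.names = FALSE))
  labels <- normalize_label(colnames(m), warn = FALSE)
  continuous_recording(t(m), meta$fs, labels,
                       role = if (is.null(role)) meta$role else role,
                       condition = if (is.null(condition)) meta$condition else condition,
                       dyad_id = meta$dyad_id)
}

#' Write a behavioral table as CSV
#'
#' @param behavior Data frame with columns `dyad_id`, `group`,
#'   `recall_emotion`, `recall_neutral`, `delta_recall`, `ios`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral table from CSV
#'
#' Recomputes `delta_recall` from the raw recall columns when absent.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) stop("cannot read behavioral table: ", path,
                               call. = FALSE)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "group", "ios")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("behavioral table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"delta_recall" %in% names(b) &&
      all(c("recall_emotion", "recall_neutral") %in% names(b))) {
    b$delta_recall <- b$recall_emotion - b$recall_neutral
  }
  b
}
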