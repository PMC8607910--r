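#!/usr/bin/env Rscript
# Stage 4 — group statistics.
#
# Happy-vs-sad pooled t tests on the six regional delta-PLV contrasts with
# BH (FDR) correction, the behavioral contrasts (recall-quality delta and
# IOS closeness), neural-behavioral correlations, and the simple-slopes
# moderation of the closeness ~ frontal delta-PLV relation by group.

suppressMessages(library(ibsync))

path <- "results/analysis/dyad_summary.csv"
if (!file.exists(path)) stop("run analysis/03_phase_sync.R first")
sm <- utils::read.csv(path, stringsAsFactors = FALSE)

contrasts <- roi_group_contrasts(sm)
utils::write.csv(contrasts, "results/analysis/group_contrasts.csv",
                 row.names = FALSE)
cat("regional happy-vs-sad contrasts (BH corrected):\n")
print(contrasts, digits = 3)

happy <- sm$group == "happy"
beh <- independent_ttest(sm$delta_recall[happy], sm$delta_recall[!happy])
ios <- independent_ttest(sm$ios[happy], sm$ios[!happy])
cat(sprintf("\nrecall-quality delta: t(%d) = %.2f, p = %.4g, d = %.2f\n",
            beh$df, beh$t, beh$p, beh$cohen_d))
cat(sprintf("IOS closeness:        t(%d) = %.2f, p = %.4g, d = %.2f\n",
            ios$df, ios$t, ios$p, ios$cohen_d))

cr <- pearson_corr(sm$dplv_F, sm$delta_recall)
ci <- pearson_corr(sm$dplv_F, sm$ios)
cat(sprintf("frontal delta-PLV ~ recall delta: r(%d) = %.2f, p = %.4g\n",
            cr$df, cr$r, cr$p))
cat(sprintf("frontal delta-PLV ~ IOS:          r(%d) = %.2f, p = %.4g\n",
            ci$df, ci$r, ci$p))

slopes <- simple_slopes(sm$dplv_F, sm$ios, sm$group)
utils::write.csv(slopes, "results/analysis/moderation_slopes.csv",
                 row.names = FALSE)
cat("\nsimple slopes of IOS on frontal delta-PLV by group:\n")
print(slopes, digits = 3)
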