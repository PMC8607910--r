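#!/usr/bin/env Rscript
# Stage 5 — directional coupling (Granger causality).
#
# Simulates 32 unidirectionally driven dyads (speaker drives listener with
# coefficient 0.3 at lag 1), z-scores each series to its resting baseline,
# selects the VAR order by AIC and computes the log residual-variance-ratio
# GC statistic in both directions; then tests the forward statistic against
# zero at the group level.

suppressMessages(library(ibsync))
set.seed(20240905)

rows <- lapply(sprintf("dyad%02d", 1:32), function(id) {
  vd <- make_var_dyad(5000, 0.3, 1)
  g <- dyad_gc(vd$x, vd$y, rnorm(500), rnorm(500), max_order = 10)
  data.frame(dyad_id = id, order = g$order, f_forward = g$f_forward,
             f_backward = g$f_backward, stringsAsFactors = FALSE)
})
gc_df <- do.call(rbind, rows)
utils::write.csv(gc_df, "results/analysis/gc.csv", row.names = FALSE)

fwd <- one_sample_ttest(gc_df$f_forward, 0)
bwd <- one_sample_ttest(gc_df$f_backward, 0)
cat(sprintf("speaker -> listener: mean F = %.4f, t(%d) = %.2f, p = %.3g\n",
            mean(gc_df$f_forward), fwd$df, fwd$t, fwd$p))
cat(sprintf("listener -> speaker: mean F = %.4f, t(%d) = %.2f, p = %.3g\n",
            mean(gc_df$f_backward), bwd$df, bwd$t, bwd$p))
cat(sprintf("forward > backward in %d/32 dyads\n",
            sum(gc_df$f_forward > gc_df$f_backward)))
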