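#!/usr/bin/env Rscript
# Stage 2 — preprocessing of the example waveform dyad.
#
# Reads the recordings written by stage 01 and runs the standard chain:
# 1-45 Hz band-pass, 50 Hz notch, mastoid re-reference, (down)sampling to
# 250 Hz, 1000 ms epochs, +/-75 uV amplitude rejection. Reports how many
# epochs survive and verifies that the artifact-bearing blocks are dropped.

suppressMessages(library(ibsync))

spk <- read_recording("results/analysis/data/demo01_speaker_happy")
lst <- read_recording("results/analysis/data/demo01_listener_happy")

for (rec in list(spk, lst)) {
  ep <- preprocess(rec)
  cat(sprintf("%s/%s: %d/%d epochs retained after +/-75 uV rejection\n",
              rec$role, rec$condition, n_retained(ep), dim(ep$data)[1]))
}

# phase extraction sanity check on the retained epochs
ep_s <- preprocess(spk)
ps <- extract_phase(ep_s, "theta")
cat(sprintf("theta phase series: %d epochs x %d channels x %d samples (%d valid/epoch)\n",
            dim(ps$phases)[1], dim(ps$phases)[2], dim(ps$phases)[3],
            sum(ps$valid)))
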