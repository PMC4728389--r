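#!/usr/bin/env Rscript
# Forward model of fluorophore release and spread from a degrading
# subcutaneous hydrogel depot.
#
# The release source is a Weibull pulse (shape 1.5, scale 10 day, phase lag
# 1.5 day, strength 500) confined to the 0.42 mm gel disk; the initial
# intensity profile is 0.1 + 0.8 exp(-0.16 r^1.5); transport is Fickian with
# the apparent diffusivity 4.32 mm^2/day. This driver evaluates the
# analytic Hankel-transform solution at the five reference radii daily over
# 60 days and writes the curves, plus the same grid from the
# finite-difference backend for comparison.

suppressPackageStartupMessages(library(geldiff))

cfg <- system.file("extdata", "params.toml", package = "geldiff")
out <- "results/forward_model"

ana <- run_simulate(cfg, out_dir = out, backend = "analytic")
fd <- run_simulate(cfg, out_dir = out, backend = "fd")

dev <- max(abs(ana$concentration - fd$concentration)) /
  max(fd$concentration - 0.1)
message(sprintf("analytic vs finite-difference on the output grid: %.3g%% of the excess scale", 100 * dev))

# where and when each radius peaks (the outward-travelling diffusive wave)
peaks <- do.call(rbind, lapply(split(ana, ana$r_mm), function(d) {
  data.frame(r_mm = d$r_mm[1], t_peak_day = d$t_day[which.max(d$concentration)],
             peak_excess = max(d$concentration) - 0.1)
}))
print(peaks, row.names = FALSE)
write.csv(peaks, file.path(out, "peak_times.csv"), row.names = FALSE)
message("curves in ", out)
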