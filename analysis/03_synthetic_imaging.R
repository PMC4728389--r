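#!/usr/bin/env Rscript
# Synthetic stand-in for the in vivo fluorescence image series: renders the
# model field on a 128 x 128 grid (0.2 mm pixels) every other day over 60
# days, applies 5% multiplicative camera noise, writes the stack as 32-bit
# float TIFF with a JSON sidecar, then re-extracts the radial intensity time
# series by azimuthal averaging -- the image-facing half of the pipeline.

suppressPackageStartupMessages(library(geldiff))

out <- "results/imaging"
cfg <- geldiff::read_toml(system.file("extdata", "params.toml",
                                      package = "geldiff"))
cfg$quadrature <- list(n_panels = 200, panel_rule_order = 8, tau_steps = 96)
cfg$imaging <- list(noise_rel = 0.05, seed = 1)
cfg$synth <- list(times = seq(0, 60, by = 2))

stack <- run_synth(cfg, out_dir = out)
obs <- run_extract(cfg, attr(stack, "path"), out_dir = out)

message(sprintf("stack: %d frames of %d x %d px at %s",
                length(stack$times), stack$config$n_px, stack$config$n_px,
                attr(stack, "path")))
message(sprintf("extracted series: %d radii x %d times -> %s",
                length(obs$radii), length(obs$times), attr(obs, "path")))
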