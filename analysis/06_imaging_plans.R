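#!/usr/bin/env Rscript
# Step-by-step imaging-parameter optimisation: worked plans for the deep
# cortex (~2 EALs) and hippocampus (~4 EALs) at 1320 nm, and the
# 1280-vs-1320 nm wavelength trade-off.

library(threephoton)
dir.create("results", showWarnings = FALSE)

cat("Deep cortex, 600 um (~2 EALs at 1320 nm):\n")
p1 <- make_plan(600, 300)
print(p1)

cat("\nHippocampus, ~1.2 mm (~4 EALs including white matter):\n")
p2 <- make_plan(4 * 293, 293)
print(p2)

plans <- data.frame(
  target = c("cortex_600um", "hippocampus_4EAL"),
  e_surface_nj = c(p1$e_surface_nj, p2$e_surface_nj),
  rep_rate_mhz = c(p1$rep_rate_hz, p2$rep_rate_hz) / 1e6,
  fov_um = c(p1$fov_um, p2$fov_um),
  frame_rate_hz = c(p1$frame_rate_hz, p2$frame_rate_hz),
  pulses_per_pixel = c(p1$pulses_per_pixel, p2$pulses_per_pixel))
write.csv(plans, "results/imaging_plans.csv", row.names = FALSE)

cat("\nWavelength trade-off (power headroom vs indicator sensitivity):\n")
print(wavelength_tradeoff(), row.names = FALSE, digits = 3)
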