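#!/usr/bin/env Rscript
# Signal-to-background depth limit: theoretical SBR versus normalised depth
# for 2PE and 3PE at staining inhomogeneity 50, the depth where 2PM SBR
# reaches 1, and a measurement round trip on a synthetic vasculature stack.

library(threephoton)
dir.create("results", showWarnings = FALSE)

st <- staining_model(chi = 50)
depths <- seq(0.5, 7, by = 0.25)
prof <- rbind(
  cbind(order = 2, sbr_vs_depth(2, st, depths)),
  cbind(order = 3, sbr_vs_depth(3, st, depths)))
write.csv(prof, "results/sbr_vs_depth.csv", row.names = FALSE)

z1 <- sbr_unity_depth(2, st)
cat(sprintf("2PM SBR reaches 1 at %.2f EALs for chi = 50 (%.0f um at EAL 154 um);\n",
            z1, z1 * 154))
cat(sprintf("3PM SBR at the same normalised depth: %.0f.\n",
            sbr_vs_depth(3, st, z1)$sbr))
cat(sprintf("At SBR = 1 the apparent dF/F is halved: %.2f -> %.2f.\n",
            0.30, apparent_dff(0.30, 1)))

# measurement round trip on a synthetic stack
gs <- gen_stack(stack_spec(depths_um = seq(200, 600, 50),
                           signal_peak_counts = 3000, seed = 4))
bg_mask <- !apply(gs$mask, 1:2, any)
meas <- measure_sbr(gs$stack, background_mask = bg_mask)
est <- estimate_staining(gs$stack)
write.csv(cbind(depth_um = gs$depths_um, meas),
          "results/sbr_measured_stack.csv", row.names = FALSE)
cat(sprintf("\nSynthetic stack: labelled fraction %.3f (target 0.020), chi %.0f;\n",
            est$volume_fraction, est$chi))
cat("measured SBR per frame follows the generator's theory-driven background:\n")
print(data.frame(depth_um = gs$depths_um, sbr_true = round(gs$truth$sbr, 1),
                 sbr_measured = round(meas$sbr, 1)), row.names = FALSE)
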