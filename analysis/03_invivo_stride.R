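#!/usr/bin/env Rscript
# Step 3 — simulated in vivo stride cycles.
#
# Generates one 401-frame walking stride per joint from the stride presets
# (FE-dominant sinusoids whose ranges match in vivo walking magnitudes:
# hip FE ~117 deg, knee FE ~115 deg, hip ABAD about a third of the
# ligamentous range) and writes their pose tables and RoM summaries.
#
# Outputs: results/invivo_stride_<joint>.csv (pose tables),
#          results/invivo_rom.csv.

suppressPackageStartupMessages(library(romsfp))
dir.create("results", showWarnings = FALSE)

# a permissive envelope model: the stride presets describe observed walking
# kinematics, not a feasibility claim, so they are validated only against a
# wide envelope here (step 4 compares them against ex vivo pose space)
envelope <- function(spec) {
  joint_limit_model(center = spec$mean, semi_axes = c(95, 95, 95))
}

sums <- list()
for (joint in c("hip", "knee")) {
  spec <- stride_preset(joint)
  st <- simulate_stride(envelope(spec), spec,
                        specimen = paste0("synthetic_", joint), joint = joint)
  write_pose_table(st, sprintf("results/invivo_stride_%s.csv", joint),
                   form = "euler")
  sums[[joint]] <- rom_summary(st)
  e <- pose_sequence_euler(st)
  cat(sprintf("%s stride: %d frames, periodic (first vs last pose %.2f deg)\n",
              joint, length(st),
              max(abs(e[1, 3:5] - e[nrow(e), 3:5]))))
}
tab <- rom_table(sums, specimen = paste0("stride_", names(sums)))
write.csv(tab, "results/invivo_rom.csv", row.names = FALSE)
print(tab[, c("specimen", "axis", "max", "min", "range")])
cat("\nFE dominates both joints; ABAD and LAR stay in narrow bands,",
    "\nas in walking kinematics.\n")
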