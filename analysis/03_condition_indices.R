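#!/usr/bin/env Rscript
# Step 3: per-individual condition scores for the reference populations.
#
# The scaled mass index standardizes each animal's mass to the reference
# length L0 (the population mean pronotum length) using the common SMA
# exponent from step 2; the residual index is the standardized residual of
# the pooled OLS fit.  Both score tables feed the validation step.

suppressPackageStartupMessages(library(condindex))

constants <- list(reference_gtex = NULL, reference_adom = NULL)
for (nm in names(constants)) {
  pop <- read_morph_table(file.path("results", paste0(nm, ".csv")))
  x <- log(pop$pronotum); y <- log(pop$fresh_mass)
  b <- test_common_slope_sma(x, y, pop$sex)$common_slope
  L0 <- reference_length(pop)
  constants[[nm]] <- scaling_constants(b, L0, source = nm)
  smi <- scaled_mass_index(pop, constants[[nm]])
  ri <- residual_index(pop)
  scores <- merge(smi, ri, by = "id")
  out <- file.path("results", paste0(nm, "_scores.csv"))
  write.csv(scores, out, row.names = FALSE)
  cat(sprintf("%s: b_SMA = %.3f, L0 = %.3f mm; scores for %d animals -> %s\n",
              nm, b, L0, nrow(scores), out))
  cat(sprintf("  SMI: mean %.4f g (sd %.4f); residual index: mean %.2g (sd %.3f)\n",
              mean(scores$smi), sd(scores$smi),
              mean(scores$residual_index), sd(scores$residual_index)))
}
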