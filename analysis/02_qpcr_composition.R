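#!/usr/bin/env Rscript

# Step 2: absolute qPCR quantification of the 7-virus mock community.
# Fits per-virus standard curves, quantifies a balanced mock sample and a
# centrifuged aliquot in which the largest virus is depleted, and reports
# composition and treatment fold changes.
#
# Writes: results/qpcr_standard_curves.tsv, results/qpcr_composition.tsv,
#         results/qpcr_fold_changes.tsv

suppressPackageStartupMessages(library(virobias))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 20251102

members <- mock_community_members()
balanced <- setNames(rep(2e6, 7), members$id)
# centrifugation pellets the largest particle: 30-fold vaccinia loss
centrifuged <- balanced
centrifuged["vaccinia_WR"] <- centrifuged["vaccinia_WR"] / 30

fx_pre <- generate_qpcr_fixture(balanced, noise_sd_cq = 0.05, seed = seed,
                                sample = "mock_pre")
fx_post <- generate_qpcr_fixture(centrifuged, noise_sd_cq = 0.05,
                                 seed = seed + 1, sample = "mock_post")

curves <- lapply(split(fx_pre$standards, fx_pre$standards$virus),
                 fit_standard_curve)
curve_tbl <- do.call(rbind, lapply(names(curves), function(v)
  data.frame(virus = v, slope = curves[[v]]$slope,
             intercept = curves[[v]]$intercept,
             r_squared = curves[[v]]$r_squared,
             efficiency_pct = curves[[v]]$efficiency_pct)))
write.table(curve_tbl, file.path(out_dir, "qpcr_standard_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("standard-curve efficiencies (%):\n")
print(setNames(round(curve_tbl$efficiency_pct, 2), curve_tbl$virus))

pre <- quantify_samples(fx_pre$standards, fx_pre$samples)
post <- quantify_samples(fx_post$standards, fx_post$samples)
comp <- community_composition(rbind(pre, post)[, c("virus", "sample",
                                                   "copies")])
write.table(comp, file.path(out_dir, "qpcr_composition.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fc <- treatment_fold_changes(comp[comp$sample == "mock_pre", ],
                             comp[comp$sample == "mock_post", ],
                             mode = "total_amount")
write.table(fc, file.path(out_dir, "qpcr_fold_changes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ntreatment fold changes (total genome amount):\n")
print(fc)
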