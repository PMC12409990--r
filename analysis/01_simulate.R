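#!/usr/bin/env Rscript
# Stage 1 -- simulate every input the downstream analyses consume:
#  * toy conformational ensembles for a "water" and a "urea" condition
#    (the denaturant condition has doubled planted-mode amplitudes),
#  * per-position conservation grades and structural-region annotations,
#  * equilibrium unfolding/refolding datasets from the two folding presets,
#  * a limited-proteolysis band-intensity time course.
suppressPackageStartupMessages(library(caspensemble))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20251001L

message("Simulating ensembles (30 residues, 300 frames) ...")
spec_water <- ensemble_spec(n_residues = 30, n_frames = 300, mode_sds = c(2, 1),
                            isotropic_noise_sd = 0.05, seed = seed)
spec_urea <- ensemble_spec(n_residues = 30, n_frames = 300, mode_sds = c(4, 2),
                           isotropic_noise_sd = 0.05, seed = seed + 1L)
ens_water <- make_toy_ensemble(spec_water)
ens_urea <- make_toy_ensemble(spec_urea)
write_ensemble_pdb(ens_water, file.path(out, "ensemble_water.pdb"))
write_ensemble_pdb(ens_urea, file.path(out, "ensemble_urea.pdb"))

message("Writing conservation grades and region annotation ...")
cons <- make_conservation_table(30, hub_positions = c(5, 12, 20), seed = seed + 2L)
write_conservation_tsv(cons, file.path(out, "conservation.tsv"))
write_region_tsv(toy_region_classes(30), file.path(out, "regions.tsv"))

message("Simulating unfolding/refolding datasets ...")
d21 <- make_unfolding_datasets(folding_preset("21M"),
                               noise_sd_fraction = 0.02, seed = seed + 3L)
write_unfolding_tsv(d21, file.path(out, "unfolding_21M.tsv"))
dhub <- make_unfolding_datasets(folding_preset("hub_mutant"),
                                noise_sd_fraction = 0.02, seed = seed + 4L)
write_unfolding_tsv(dhub, file.path(out, "unfolding_hub_mutant.tsv"))

message("Simulating a proteolysis time course (k = 0.12 / min) ...")
set.seed(seed + 5L)
tc <- data.frame(time_min = seq(0, 60, by = 3))
tc$intensity <- 4 * exp(-0.12 * tc$time_min) + 0.5 +
  rnorm(nrow(tc), sd = 0.08)
write.table(tc, file.path(out, "proteolysis_timecourse.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Done. Inputs written under ", out)
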