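#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds (a) the accession ledger of the epimutagenised population,
# (b) the 14-line MSAP screening cohort (2 S2 + 2 S3 controls, 5 E2 +
# 5 E3 treated lines, 10 seedlings each, paired HpaII/MspI digests,
# 500 loci, 4 treated lines truly hypomethylated), (c) the 6-dose x
# 4-replicate x 100-seedling survival experiment on the constrained
# logistic with A = 40%, m = 0.32 mM, and (d) per-line seed and
# composition traits calibrated to the screen's reported group means.

suppressPackageStartupMessages(library(epimsap))
SEED <- 1234L
out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ped <- build_population_pedigree(n_e1 = 473, siliques_per_plant = 3,
                                 pooled_per_plant = 1,
                                 n_selected_lines = 100,
                                 seeds_sown_per_selected_line = 10)
write.csv(ped, file.path(out, "pedigree.csv"), row.names = FALSE)
message(sprintf("pedigree: %d E2 seed accessions from %d E1 plants, %d E2 plants",
                sum(ped$generation == "E2_seed"),
                sum(ped$generation == "E1"),
                sum(ped$generation == "E2_plant")))

pop <- simulate_msap_population(cohort_spec(rng_seed = SEED))
write_msap(pop$hpaii, file.path(out, "msap_hpaii.tsv"))
write_msap(pop$mspi, file.path(out, "msap_mspi.tsv"))
write_genalex(pop$hpaii, file.path(out, "msap_hpaii_genalex.csv"))
write.csv(pop$lines, file.path(out, "lines.csv"), row.names = FALSE)
message(sprintf("MSAP cohort: %d samples x %d loci per enzyme; truly hypomethylated: %s",
                nrow(pop$hpaii$values), ncol(pop$hpaii$values),
                paste(pop$lines$line_id[pop$lines$effective], collapse = ", ")))

dose_tab <- simulate_dose_response(dose_response_spec(rng_seed = SEED))
write.csv(dose_tab, file.path(out, "dose_response.csv"), row.names = FALSE)
message(sprintf("dose-response: %d observations over %d doses",
                nrow(dose_tab), length(unique(dose_tab$dose))))

traits <- simulate_traits(trait_spec(rng_seed = SEED), pop$lines)
write.csv(traits, file.path(out, "traits.csv"), row.names = FALSE)
message(sprintf("traits: %d observations of %d traits on %d lines",
                nrow(traits), length(unique(traits$trait)),
                length(unique(traits$line_id))))
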