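#!/usr/bin/env Rscript

# Stage 3: relative-rate tests against the outgroup. For each non-focal
# species, the observed ortholog divergence peak is decomposed into
# per-lineage Ks distances and corrected to the focal lineage's rate scale.
# Reads results/data/, writes results/rate_table.tsv.

suppressPackageStartupMessages(library(wgdplacer))

config <- validate_config("results/data/config.yaml")
dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

ortho <- lapply(config$inputs$ortholog_tables, utils::read.delim)
species <- unique(unlist(strsplit(names(ortho), "|", fixed = TRUE)))
others <- setdiff(species, c(config$focal_species, config$outgroup))

profile <- rate_profile(config$focal_species, others, config$outgroup, ortho)
write_rate_table(profile, file.path(config$output_dir, "rate_table.tsv"))

print(profile)
cat("fastest lineage:", attr(profile, "fastest"), "\n")
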