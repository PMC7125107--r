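#!/usr/bin/env Rscript

# Stage 1: simulate the study data.
#
# Four species: focal lineage A carries two nested WGDs (true Ks 0.5 and
# 0.8), B is its sister, C a further ingroup, D the outgroup. Lineage rates
# differ (B evolves almost twice as fast as A), so the later stages have to
# correct divergence peaks before comparing them with the WGD peaks.
# Everything is seeded; outputs go to results/data/.

suppressPackageStartupMessages(library(wgdplacer))

seed <- 101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# D diverges first, so it is a valid outgroup for every focal comparison
tree <- "(((A:1,B:1)ab:0.5,C:1.5)abc:0.5,D:2)r;"
rates <- c(A = 0.5, B = 0.9, C = 0.6, D = 0.5)
species <- c("A", "B", "C", "D")

config <- simulation_config(
  tree, rates,
  wgd_events = list(
    list(branch = "A", age = 0.5, sigma_ks = 0.08, n_pairs = 2000),
    list(branch = "A", age = 0.8, sigma_ks = 0.08, n_pairs = 2000)),
  ssd = list(n_pairs = 1000, decay_rate = 1.0),
  ortholog_sampling = list(n_pairs = 2000, noise_sd = 0.05),
  anchor_fraction = 0.5,
  seed = seed)

dataset <- simulate_paranome(config, "A")
write_synthetic_dataset(dataset, out)

ortho_paths <- list()
for (i in 1:3) for (j in (i + 1):4) {
  s <- simulate_ortholog_ks(config, species[i], species[j])
  p <- file.path(out, sprintf("ortho_%s_%s.tsv", species[i], species[j]))
  utils::write.table(data.frame(ks = s$values), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ortho_paths[[pair_key(species[i], species[j])]] <- p
}

writeLines("(((A,B)ab,C)abc,D)r;", file.path(out, "topology.nwk"))

yaml::write_yaml(list(
  focal_species = "A", outgroup = "D", seed = seed, n_boot = 100,
  output_dir = "results",
  inputs = list(families = file.path(out, "families.tsv"),
                ks_table = file.path(out, "ks_table.tsv"),
                anchors = file.path(out, "anchor_pairs.tsv"),
                topology = file.path(out, "topology.nwk"),
                ortholog_tables = ortho_paths)),
  file.path(out, "config.yaml"))

cat("simulated", nrow(dataset$ks_table), "paralog pairs for species A;",
    "true WGD Ks peaks at 0.5 and 0.8\n")
cat("wrote study inputs and config to", out, "\n")
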