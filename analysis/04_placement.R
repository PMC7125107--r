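#!/usr/bin/env Rscript

# Stage 4: place the WGD peaks on the species phylogeny. Branch lengths in
# Ks units are estimated from the ortholog divergence modes, each detected
# peak's half-Ks is walked from the focal tip toward the root, and each
# peak is classified as shared with or independent of every divergence.
# Reads results/data/ and results/peaks.tsv, writes placements, the event
# table and the annotated tree to results/.

suppressPackageStartupMessages(library(wgdplacer))

config <- validate_config("results/data/config.yaml")
out <- config$output_dir

topology <- ape::read.tree(config$inputs$topology)
ortho <- lapply(config$inputs$ortholog_tables, utils::read.delim)
peaks <- utils::read.delim(file.path(out, "peaks.tsv"))
rates <- utils::read.delim(file.path(out, "rate_table.tsv"))

# pairwise species Ks matrix from the ortholog divergence modes
sp <- topology$tip.label
m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
diag(m) <- 0
for (key in names(ortho)) {
  ab <- strsplit(key, "|", fixed = TRUE)[[1]]
  m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- kde_mode(ortho[[key]]$ks)
}
tree <- estimate_ks_branch_lengths(topology, m)
cat(sprintf("Ks branch lengths estimated (residual %.2e)\n",
            attr(tree, "residual")))

placements <- list()
calls <- list()
for (i in seq_len(nrow(peaks))) {
  pl <- map_peak_to_branch(tree, config$focal_species, peaks$peak_ks[i],
                           ci95 = c(peaks$ci_lo[i], peaks$ci_hi[i]))
  placements[[i]] <- pl
  print(pl)
  for (r in seq_len(nrow(rates))) {
    cl <- classify_shared(c(peaks$ci_lo[i], peaks$ci_hi[i]),
                          2 * rates$d_focal[r],
                          focal_tip = config$focal_species,
                          other_lineage = rates$species[r])
    calls[[length(calls) + 1L]] <- cl
    cat(sprintf("  vs divergence from %s (corrected Ks %.3f): %s\n",
                cl$other_lineage, cl$divergence_ks, cl$verdict))
  }
}

events <- multi_lineage_synthesis(placements, calls)
write_placements(placements, file.path(out, "placements.tsv"))
write_event_table(events, file.path(out, "events.json"))
write_annotated_tree(tree, events, file.path(out, "ks_tree_annotated.nwk"))
cat("wrote placements, events and annotated tree to", out, "\n")
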