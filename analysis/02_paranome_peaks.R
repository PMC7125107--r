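#!/usr/bin/env Rscript

# Stage 2: build the node-weighted Ks age distribution for the focal
# paranome, fit the density, detect peaks and bootstrap their CIs.
# Reads results/data/ (from 01_simulate.R), writes tables to results/.

suppressPackageStartupMessages(library(wgdplacer))

config <- validate_config("results/data/config.yaml")
dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

families <- utils::read.delim(config$inputs$families)
ks_table <- read_ks_table(config$inputs$ks_table)
anchors <- utils::read.delim(config$inputs$anchors)

dist <- build_distribution(families, ks_table, anchors = anchors,
                           cutoff = config$cutoff, ks_range = config$ks_range)
write_distribution(dist, file.path(config$output_dir, "weighted_ks.tsv"))
lg <- attr(dist, "log")
cat(sprintf("weighted distribution: %d samples from %d families (%d anchors flagged)\n",
            lg[["kept"]], lg[["families"]], sum(dist$anchor)))

curve <- fit_density(dist, range = config$ks_range,
                     bin_width = config$bin_width)
utils::write.table(data.frame(ks = curve$grid, density = curve$height),
                   file.path(config$output_dir, "density_curve.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

found <- find_peaks(curve)
peaks <- lapply(found$location, function(p)
  bootstrap_peak_ci(dist, p, n_boot = config$n_boot, seed = config$seed,
                    bin_width = config$bin_width, range = config$ks_range,
                    curve = curve))

tab <- do.call(rbind, lapply(peaks, function(p)
  data.frame(peak_ks = p$location, ci_lo = p$ci95[1], ci_hi = p$ci95[2],
             window_lo = p$window[1], window_hi = p$window[2],
             n_in_window = p$n_in_window, n_boot = p$n_boot)))
utils::write.table(tab, file.path(config$output_dir, "peaks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("detected peaks:\n")
for (p in peaks) print(p)
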