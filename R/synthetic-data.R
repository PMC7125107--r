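# Seeded generator for paranome, anchor-pair and ortholog Ks datasets with a
# known ground truth (true WGD ages, lineage rate multipliers, pair origins),
# used by every downstream recovery test.

# deterministic per-operation substream: keeps independent operations from
# sharing a random stream while remaining reproducible from one config seed
.substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

# truncated-at-zero normal via inversion; sd = 0 degenerates to the mean
.rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Configuration for the synthetic Ks data generator
#'
#' Defines the study conditions a simulated dataset emulates: a rooted
#' species tree with branch lengths in time units, per-lineage substitution
#' rate multipliers (Ks per unit time, so a lineage accumulates Ks distance
#' `rate * time`), WGD events with a true age and a spread of retained-pair
#' Ks values, an exponential background of small-scale duplications (SSD),
#' and ortholog sampling noise.
#'
#' @param species_tree Rooted tree: an `ape::phylo` object or a newick string.
#'   Branch lengths are time depths in arbitrary units; tips are assumed
#'   contemporaneous.
#' @param rate_multipliers Named positive numeric vector: lineage substitution
#'   rates (Ks per unit time). One entry per tip is required and applies to
#'   that tip's terminal branch; entries named after internal node labels set
#'   the rate of the branch subtending that node; unnamed internal branches
#'   evolve at rate 1. Rates are per branch, so pairwise distances are
#'   additive on the tree (the regime the relative rate test assumes).
#' @param wgd_events List of events, each a list with `branch` (a tip name or
#'   internal node label on whose subtending branch the WGD occurred), `age`
#'   (time before present), `sigma_ks` (spread of retained-pair Ks, >= 0),
#'   `n_pairs` (retained duplicate pairs).
#' @param ssd List `n_pairs` (number of small-scale duplication events) and
#'   `decay_rate` (exponential rate lambda of the SSD Ks density; mean Ks is
#'   `1/lambda`).
#' @param ortholog_sampling List `n_pairs` (ortholog pairs per species pair)
#'   and `noise_sd` (zero-mean Gaussian noise on ortholog Ks, truncated at 0).
#' @param family_size Family-size distribution for assembling SSD events into
#'   gene families: `list(type = "fixed", size = 2)` (default: each duplication
#'   is its own two-gene family), `list(type = "geometric", prob =, min =, max =)`,
#'   or `list(type = "uniform", min =, max =)`.
#' @param anchor_fraction Fraction of WGD-derived pairs emitted as anchor
#'   (syntenic) pairs.
#' @param seed Integer master seed; all operations derive deterministic
#'   substreams from it.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(species_tree,
                              rate_multipliers,
                              wgd_events = list(),
                              ssd = list(n_pairs = 0L, decay_rate = 1.0),
                              ortholog_sampling = list(n_pairs = 1000L, noise_sd = 0.05),
                              family_size = list(type = "fixed", size = 2L),
                              anchor_fraction = 0.5,
                              seed = 1L) {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  if (!inherits(species_tree, "phylo")) stop("`species_tree` must be a phylo or newick string")
  if (!ape::is.rooted(species_tree)) stop("`species_tree` must be rooted")
  tips <- species_tree$tip.label
  if (is.null(names(rate_multipliers)) || !all(tips %in% names(rate_multipliers)))
    stop("`rate_multipliers` must be named and cover every tip")
  if (any(rate_multipliers <= 0)) stop("rate multipliers must be strictly positive")
  unknown <- setdiff(names(rate_multipliers), c(tips, species_tree$node.label))
  if (length(unknown))
    stop("rate multiplier(s) for unknown lineage(s): ", paste(unknown, collapse = ", "))
  valid_branch_ids <- c(tips, species_tree$node.label)
  for (ev in wgd_events) {
    if (!all(c("branch", "age", "sigma_ks", "n_pairs") %in% names(ev)))
      stop("each WGD event needs fields branch, age, sigma_ks, n_pairs")
    if (!ev$branch %in% valid_branch_ids)
      stop("WGD branch id not found in the species tree: ", ev$branch)
    if (ev$age <= 0 || ev$n_pairs <= 0 || ev$sigma_ks < 0)
      stop("WGD event ", ev$branch, ": age and n_pairs must be positive, sigma_ks >= 0")
  }
  if (ssd$n_pairs < 0 || ssd$decay_rate <= 0)
    stop("ssd: n_pairs >= 0 and decay_rate > 0 required")
  if (ortholog_sampling$n_pairs <= 0 || ortholog_sampling$noise_sd < 0)
    stop("ortholog_sampling: n_pairs > 0 and noise_sd >= 0 required")
  if (anchor_fraction < 0 || anchor_fraction > 1)
    stop("anchor_fraction must lie in [0, 1]")
  structure(list(
    species_tree = species_tree,
    rate_multipliers = rate_multipliers,
    wgd_events = wgd_events,
    ssd = ssd,
    ortholog_sampling = ortholog_sampling,
    family_size = family_size,
    anchor_fraction = anchor_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# node depths (time before present) assuming contemporaneous tips
.node_times <- function(tree) {
  d <- ape::node.depth.edgelength(tree) # distance from root
  max(d[seq_len(ape::Ntip(tree))]) - d
}

# per-edge substitution rate: the multiplier named after the edge's child
# (tip name or internal node label) when provided, else 1
.edge_rates <- function(config) {
  tree <- config$species_tree
  ntip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  labs <- rep(NA_character_, length(child))
  is_tip <- child <= ntip
  labs[is_tip] <- tree$tip.label[child[is_tip]]
  if (!is.null(tree$node.label))
    labs[!is_tip] <- tree$node.label[child[!is_tip] - ntip]
  r <- rep(1, length(child))
  hit <- !is.na(labs) & nzchar(labs) & labs %in% names(config$rate_multipliers)
  r[hit] <- config$rate_multipliers[labs[hit]]
  r
}

# Ks accumulated by `tip`'s lineage from the present back to `upto` time
# units ago, integrating per-branch rates along the tip-to-root path
.lineage_ks_depth <- function(config, tip, upto) {
  tree <- config$species_tree
  times <- .node_times(tree)
  rates <- .edge_rates(config)
  ti <- match(tip, tree$tip.label)
  root <- ape::Ntip(tree) + 1L
  total <- 0
  node <- ti
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    overlap <- max(0, min(times[tree$edge[e, 1]], upto) - max(times[node], 0))
    total <- total + rates[e] * overlap
    node <- tree$edge[e, 1]
  }
  total
}

# labels of the focal tip's lineage: the tip itself plus ancestor node labels
.lineage_labels <- function(tree, tip) {
  ti <- match(tip, tree$tip.label)
  root <- ape::Ntip(tree) + 1L
  labs <- tip
  node <- ti
  while (node != root) {
    node <- tree$edge[tree$edge[, 2] == node, 1]
    lab_idx <- node - ape::Ntip(tree)
    if (!is.null(tree$node.label) && !is.na(tree$node.label[lab_idx]) &&
        nzchar(tree$node.label[lab_idx]))
      labs <- c(labs, tree$node.label[lab_idx])
  }
  labs
}

.draw_family_sizes <- function(fs, n_events) {
  sizes <- integer(0)
  used <- 0L
  while (used < n_events) {
    s <- switch(fs$type,
      fixed = fs$size,
      geometric = {
        mn <- if (is.null(fs$min)) 2L else fs$min
        mx <- if (is.null(fs$max)) 20L else fs$max
        min(mx, mn + stats::rgeom(1L, fs$prob))
      },
      uniform = sample(seq(fs$min, fs$max), 1L),
      stop("unknown family_size type: ", fs$type)
    )
    s <- min(s, n_events - used + 1L) # last family shrinks to fit
    if (s < 2L) s <- 2L
    sizes <- c(sizes, s)
    used <- used + s - 1L
  }
  sizes
}

# Random duplication history for one family: `ks_events` are the duplication
# ages in Ks units, ascending. Clusters are merged in that order, so the pair
# Ks of any two genes equals the age of their most recent common duplication.
# Returns the full pairwise table plus node membership, exactly consistent
# with UPGMA reconstruction.
.assemble_family <- function(gene_ids, ks_events, node_prefix) {
  ks_events <- sort(ks_events)
  clusters <- as.list(gene_ids)
  rows <- list()
  for (i in seq_along(ks_events)) {
    pick <- sample.int(length(clusters), 2L)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    node_id <- paste0(node_prefix, "n", i)
    cross <- expand.grid(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
    cross$ks <- ks_events[i]
    cross$node_id <- node_id
    rows[[i]] <- cross
    clusters[[pick[1]]] <- c(a, b)
    clusters[[pick[2]]] <- NULL
  }
  do.call(rbind, rows)
}

#' Simulate a paranome Ks dataset for one species
#'
#' WGD-derived duplicate pairs get Ks values drawn from a normal distribution
#' centred on `2 * rate * age` (the Ks distance accumulated along both copies
#' since the duplication) with spread `sigma_ks`, truncated at zero. The SSD
#' background draws duplication ages in Ks units from an exponential with the
#' configured decay rate; SSD events are assembled into families per the
#' family-size distribution, and all within-family pairwise Ks values are
#' emitted (consistent with the duplication history, so node weighting can be
#' checked exactly). A configurable fraction of WGD pairs is emitted as
#' anchor pairs.
#'
#' @param config A [simulation_config()].
#' @param focal_species Tip name of the species whose paranome is simulated.
#' @return Object of class `synthetic_dataset`: list with `family_table`
#'   (family_id, species, gene_id), `ks_table` (gene_a, gene_b, ks),
#'   `anchor_pairs` (gene_a, gene_b), `truth` (per pair: origin, true_ks,
#'   node_id, family_id), `wgd_truth` (per event: branch, age, true_ks), and
#'   `focal_species`.
#' @export
simulate_paranome <- function(config, focal_species) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$species_tree
  if (!focal_species %in% tree$tip.label)
    stop("unknown focal species: ", focal_species)
  lineage <- .lineage_labels(tree, focal_species)
  events <- Filter(function(ev) ev$branch %in% lineage, config$wgd_events)
  n_ssd <- config$ssd$n_pairs
  if (length(events) == 0L && n_ssd == 0L)
    stop("zero pairs requested: no WGD event on the focal lineage and no SSD background")
  set.seed(.substream_seed(config$seed, paste0("paranome|", focal_species)))

  fam_rows <- list(); ks_rows <- list(); truth_rows <- list(); anchor_rows <- list()
  wgd_truth <- list()
  fam_counter <- 0L; gene_counter <- 0L
  new_genes <- function(k) {
    ids <- sprintf("%s_g%06d", focal_species, gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    ids
  }

  for (ei in seq_along(events)) {
    ev <- events[[ei]]
    # both retained copies accumulate the focal lineage's Ks depth since the
    # duplication, so the pair distance is twice that depth
    true_ks <- 2 * .lineage_ks_depth(config, focal_species, ev$age)
    wgd_truth[[ei]] <- data.frame(event = paste0("WGD-", ei), branch = ev$branch,
                                  age = ev$age, true_ks = true_ks)
    ks_vals <- .rtnorm0(ev$n_pairs, true_ks, ev$sigma_ks)
    is_anchor <- stats::runif(ev$n_pairs) < config$anchor_fraction
    for (p in seq_len(ev$n_pairs)) {
      fam_counter <- fam_counter + 1L
      fid <- sprintf("F%06d", fam_counter)
      g <- new_genes(2L)
      nid <- paste0(fid, ".n1")
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(family_id = fid, species = focal_species, gene_id = g)
      ks_rows[[length(ks_rows) + 1L]] <-
        data.frame(gene_a = g[1], gene_b = g[2], ks = ks_vals[p])
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(gene_a = g[1], gene_b = g[2], origin = paste0("WGD-", ei),
                   true_ks = true_ks, node_id = nid, family_id = fid)
      if (is_anchor[p])
        anchor_rows[[length(anchor_rows) + 1L]] <-
          data.frame(gene_a = g[1], gene_b = g[2])
    }
  }

  if (n_ssd > 0L) {
    ssd_ks <- stats::rexp(n_ssd, rate = config$ssd$decay_rate)
    sizes <- .draw_family_sizes(config$family_size, n_ssd)
    used <- 0L
    for (s in sizes) {
      fam_counter <- fam_counter + 1L
      fid <- sprintf("F%06d", fam_counter)
      g <- new_genes(s)
      evs <- ssd_ks[used + seq_len(s - 1L)]
      used <- used + s - 1L
      tab <- .assemble_family(g, evs, paste0(fid, "."))
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(family_id = fid, species = focal_species, gene_id = g)
      ks_rows[[length(ks_rows) + 1L]] <- tab[, c("gene_a", "gene_b", "ks")]
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(gene_a = tab$gene_a, gene_b = tab$gene_b, origin = "SSD",
                   true_ks = tab$ks, node_id = tab$node_id, family_id = fid)
    }
  }

  structure(list(
    family_table = do.call(rbind, fam_rows),
    ks_table = do.call(rbind, ks_rows),
    anchor_pairs = if (length(anchor_rows)) do.call(rbind, anchor_rows) else
      data.frame(gene_a = character(0), gene_b = character(0)),
    truth = do.call(rbind, truth_rows),
    wgd_truth = if (length(wgd_truth)) do.call(rbind, wgd_truth) else NULL,
    focal_species = focal_species
  ), class = "synthetic_dataset")
}

#' Simulate an ortholog Ks sample for a species pair
#'
#' Ortholog Ks values are centred on the sum of the two lineages' rate-scaled
#' path lengths since divergence (for sister species with terminal-branch
#' rates `r_a`, `r_b` and divergence time `T`, exactly `(r_a + r_b) * T`);
#' zero-mean Gaussian noise truncated at 0 is added. The true per-lineage
#' distances (path integrals of per-branch rate over time since the MRCA)
#' are recorded.
#'
#' @param config A [simulation_config()].
#' @param species_a,species_b Distinct tip names.
#' @return List with `species_a`, `species_b`, `values` (Ks sample),
#'   `location` (true peak position), `d_a`, `d_b` (true per-lineage Ks
#'   distances), `t_div` (divergence time).
#' @export
simulate_ortholog_ks <- function(config, species_a, species_b) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$species_tree
  if (identical(species_a, species_b)) stop("species_a and species_b must differ")
  for (sp in c(species_a, species_b))
    if (!sp %in% tree$tip.label) stop("unknown species: ", sp)
  mrca <- ape::getMRCA(tree, c(species_a, species_b))
  t_div <- .node_times(tree)[mrca]
  d_a <- .lineage_ks_depth(config, species_a, t_div)
  d_b <- .lineage_ks_depth(config, species_b, t_div)
  loc <- d_a + d_b
  set.seed(.substream_seed(config$seed, paste0("ortho|", species_a, "|", species_b)))
  vals <- .rtnorm0(config$ortholog_sampling$n_pairs, loc,
                   config$ortholog_sampling$noise_sd)
  list(species_a = species_a, species_b = species_b, values = vals,
       location = loc, d_a = d_a, d_b = d_b, t_div = t_div)
}

#' Simulate a diverged in-frame codon sequence pair with known Ks
#'
#' Builds an ancestral sequence from codons whose third position is four-fold
#' degenerate and whose first two positions admit no synonymous change (so
#' every codon contributes exactly one synonymous site), then evolves the two
#' copies' third positions independently under a Jukes-Cantor process with
#' total expected synonymous distance `target_ks`. The NG86 estimator is
#' consistent for `target_ks` on this output.
#'
#' @param target_ks Expected synonymous distance, in `[0, 5]`. Larger values
#'   approach saturation (`ps -> 3/4`) where the Jukes-Cantor correction is
#'   undefined and are refused.
#' @param n_codons Number of codons (>= 1).
#' @param seed Integer seed.
#' @return List with character sequences `a` and `b` and `target_ks`.
#' @export
evolve_codon_pair <- function(target_ks, n_codons, seed = 1L) {
  if (target_ks < 0) stop("target_ks must be >= 0")
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (target_ks > 5)
    stop("saturation: target_ks = ", target_ks,
         " is beyond the recoverable range of the Jukes-Cantor correction (max 5)")
  # prefixes with no synonymous first/second-position neighbours and no stop
  # codon for any third base
  prefixes <- c("GG", "GC", "GT", "CC", "AC", "TC")
  set.seed(as.integer(seed))
  pre <- sample(prefixes, n_codons, replace = TRUE)
  anc <- sample(.bases, n_codons, replace = TRUE)
  d <- target_ks / 2 # per branch
  p_stay <- 0.25 + 0.75 * exp(-4 * d / 3)
  evolve <- function(x) {
    change <- stats::runif(length(x)) > p_stay
    if (any(change)) {
      x[change] <- vapply(x[change],
                          function(b) sample(.bases[.bases != b], 1L),
                          character(1))
    }
    x
  }
  third_a <- evolve(anc)
  third_b <- evolve(anc)
  list(a = paste0(pre, third_a, collapse = ""),
       b = paste0(pre, third_b, collapse = ""),
       target_ks = target_ks)
}

#' Write a synthetic dataset to TSV/JSON files
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(dataset$family_table, "families.tsv")
  w(dataset$ks_table, "ks_table.tsv")
  w(dataset$anchor_pairs, "anchor_pairs.tsv")
  w(dataset$truth, "truth_pairs.tsv")
  jsonlite::write_json(list(focal_species = dataset$focal_species,
                            wgd_truth = dataset$wgd_truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
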