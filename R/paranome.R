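# Redundancy-corrected Ks age distributions. A family of n genes yields
# n(n-1)/2 pairwise Ks values for only n-1 duplication events, so each
# duplication node's m cross-clade pairs enter the distribution with weight
# 1/m, making every duplication contribute total weight 1.

# symmetric matrix from a prebuilt unordered-pair lookup; NA where absent
.family_matrix_from_lut <- function(members, lut) {
  n <- length(members)
  m <- matrix(NA_real_, n, n, dimnames = list(members, members))
  diag(m) <- 0
  idx <- which(upper.tri(m), arr.ind = TRUE)
  vals <- unname(lut[.pair_key(members[idx[, 1]], members[idx[, 2]])])
  m[idx] <- vals
  m[idx[, c(2, 1), drop = FALSE]] <- vals
  m
}

#' Split a gene family into subfamilies at a Ks cutoff
#'
#' Complete-linkage agglomeration on the pairwise Ks matrix, cut so that every
#' defined within-subfamily Ks is at most `cutoff`. Missing (saturated) Ks
#' entries are treated as exceeding the cutoff. Merge ties are broken by the
#' lexicographically smallest gene-id pair, so the partition is deterministic.
#'
#' @param matrix Symmetric Ks matrix with gene ids as dimnames (`NA` allowed).
#' @param cutoff Maximum within-subfamily Ks (default 5).
#' @return List of character vectors (subfamily memberships); singletons may
#'   occur and are dropped by downstream analysis.
#' @export
split_subfamilies <- function(matrix, cutoff = 5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  .agglomerate(matrix, linkage = "complete", stop_height = cutoff)$clusters
}

# Deterministic agglomerative clustering over a Ks matrix.
# linkage "complete": merge criterion is the max cross-pair distance;
# linkage "average": the mean over all cross pairs (UPGMA).
# With stop_height set, merging halts when no pair can merge at or below it
# and the surviving clusters are returned; otherwise merges run to a single
# cluster and the per-merge node records are returned.
.agglomerate <- function(matrix, linkage, stop_height = NULL) {
  genes <- rownames(matrix)
  if (is.null(genes)) stop("Ks matrix must carry gene ids as dimnames")
  n <- length(genes)
  clusters <- as.list(genes)
  nodes <- list()
  crit <- function(a, b) {
    vals <- matrix[a, b, drop = FALSE]
    if (linkage == "complete") {
      if (anyNA(vals)) Inf else max(vals)
    } else {
      if (anyNA(vals)) stop("missing Ks within subfamily; cannot build duplication tree")
      mean(vals)
    }
  }
  while (length(clusters) > 1L) {
    best <- NULL; best_h <- Inf; best_key <- NULL
    for (i in seq_len(length(clusters) - 1L)) for (j in seq(i + 1L, length(clusters))) {
      h <- crit(clusters[[i]], clusters[[j]])
      key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))), collapse = "\r")
      if (h < best_h || (h == best_h && !is.null(best_key) && key < best_key)) {
        best <- c(i, j); best_h <- h; best_key <- key
      }
    }
    if (!is.null(stop_height) && best_h > stop_height) break
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    nodes[[length(nodes) + 1L]] <- list(
      node_id = paste0("n", length(nodes) + 1L),
      left_clade = a, right_clade = b,
      m = length(a) * length(b),
      node_ks = if (linkage == "average") best_h else mean(matrix[a, b]))
    clusters[[best[1]]] <- sort(c(a, b))
    clusters[[best[2]]] <- NULL
  }
  list(clusters = clusters, nodes = nodes)
}

#' Infer duplication nodes for a subfamily by UPGMA on the Ks matrix
#'
#' Average-linkage agglomeration, so each internal node's height equals the
#' mean Ks over all cross-clade pairs. A subfamily of n members yields n - 1
#' duplication nodes with non-decreasing heights from leaves to root. Ties
#' are broken by the lexicographically smallest gene-id pair.
#'
#' @param matrix Symmetric Ks matrix for one subfamily; all pairwise entries
#'   must be defined.
#' @return List of duplication nodes, each a list with `node_id`,
#'   `left_clade`, `right_clade`, `m` (= |left| * |right| cross-clade pairs)
#'   and `node_ks` (mean cross-clade Ks).
#' @export
build_duplication_tree <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need >= 2 members to build a duplication tree")
  if (anyNA(matrix[upper.tri(matrix)]))
    stop("missing Ks within subfamily; cannot build duplication tree")
  .agglomerate(matrix, linkage = "average")$nodes
}

#' Node-weighted Ks samples for a set of duplication nodes
#'
#' Each duplication node with m cross-clade pairs contributes all m pairwise
#' Ks values, each with weight 1/m, so the node's total weight is exactly 1
#' and a subfamily of n members contributes total weight n - 1.
#'
#' @param nodes Duplication nodes from [build_duplication_tree()].
#' @param matrix The subfamily's Ks matrix.
#' @return Data frame with columns `ks`, `weight`, `gene_a`, `gene_b`,
#'   `node_id`.
#' @export
weight_duplications <- function(nodes, matrix) {
  rows <- lapply(nodes, function(nd) {
    cross <- expand.grid(gene_a = nd$left_clade, gene_b = nd$right_clade,
                         stringsAsFactors = FALSE)
    data.frame(ks = matrix[cbind(cross$gene_a, cross$gene_b)],
               weight = 1 / nd$m,
               gene_a = cross$gene_a, gene_b = cross$gene_b,
               node_id = nd$node_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a redundancy-corrected weighted Ks age distribution
#'
#' For every gene family: build the pairwise Ks matrix, split into
#' subfamilies at the Ks cutoff, infer duplication nodes per subfamily by
#' UPGMA, and emit node-weighted Ks samples. Samples whose genes form an
#' anchor pair are flagged. Samples outside the analysis Ks range are
#' excluded and counted.
#'
#' @param families Data frame (`family_id`, `species`, `gene_id`) or a named
#'   list of gene-id vectors.
#' @param ks_table Data frame with `gene_a`, `gene_b`, `ks` covering the
#'   family pairs (pairs absent from the table are treated as undefined).
#' @param anchors Optional data frame (`gene_a`, `gene_b`) of anchor pairs;
#'   pairs whose genes occur in no family trigger a warning and are skipped.
#' @param cutoff Subfamily Ks cutoff (default 5).
#' @param ks_range Analysis range `c(min, max)`, default `c(0.05, 5)`: the
#'   lower bound excludes allelic/assembly artifacts, the upper matches the
#'   subfamily cutoff.
#' @return Object of class `ks_distribution`: data frame with `ks`, `weight`,
#'   `gene_a`, `gene_b`, `family_id`, `node_id`, `anchor`; attributes `log`
#'   (named counts: families, subfamilies, singletons dropped, samples kept,
#'   samples excluded by range, anchors unmatched) and `ks_range`.
#' @export
build_distribution <- function(families, ks_table, anchors = NULL,
                               cutoff = 5, ks_range = c(0.05, 5)) {
  if (is.data.frame(families)) {
    fam_list <- split(families$gene_id, families$family_id)
  } else {
    fam_list <- families
    if (is.null(names(fam_list)))
      names(fam_list) <- sprintf("F%06d", seq_along(fam_list))
  }
  log <- c(families = length(fam_list), subfamilies = 0L, singletons = 0L,
           kept = 0L, excluded_range = 0L, anchors_unmatched = 0L)
  lut <- stats::setNames(ks_table$ks, .pair_key(ks_table$gene_a, ks_table$gene_b))
  sizes <- lengths(fam_list)
  log["singletons"] <- sum(sizes < 2L)

  out <- list()
  # two-member families are a single duplication node with weight 1; handle
  # them in one vectorized pass (they dominate simulated paranomes)
  two <- names(fam_list)[sizes == 2L]
  if (length(two)) {
    ga <- vapply(fam_list[two], `[`, character(1), 1L)
    gb <- vapply(fam_list[two], `[`, character(1), 2L)
    ks <- unname(lut[.pair_key(ga, gb)])
    keep <- !is.na(ks) & ks <= cutoff
    drop_sat <- !is.na(ks) & ks > cutoff  # splits into two singletons
    log["singletons"] <- log["singletons"] + 2L * sum(drop_sat) + 2L * sum(is.na(ks))
    log["subfamilies"] <- log["subfamilies"] + sum(keep)
    if (any(keep))
      out[[1L]] <- data.frame(ks = ks[keep], weight = 1,
                              gene_a = unname(ga[keep]), gene_b = unname(gb[keep]),
                              node_id = paste0(two[keep], ".s1.n1"),
                              family_id = two[keep])
  }

  for (fid in names(fam_list)[sizes > 2L]) {
    members <- as.character(fam_list[[fid]])
    m <- .family_matrix_from_lut(members, lut)
    subs <- split_subfamilies(m, cutoff = cutoff)
    for (si in seq_along(subs)) {
      sub <- subs[[si]]
      if (length(sub) < 2L) { log["singletons"] <- log["singletons"] + 1L; next }
      log["subfamilies"] <- log["subfamilies"] + 1L
      nodes <- build_duplication_tree(m[sub, sub, drop = FALSE])
      w <- weight_duplications(nodes, m)
      w$family_id <- fid
      w$node_id <- paste0(fid, ".s", si, ".", w$node_id)
      out[[length(out) + 1L]] <- w
    }
  }
  if (length(out) == 0L) stop("empty distribution: no family yielded weighted samples")
  df <- do.call(rbind, out)

  df$anchor <- FALSE
  if (!is.null(anchors) && nrow(anchors) > 0) {
    all_genes <- unique(unlist(fam_list, use.names = FALSE))
    known <- anchors$gene_a %in% all_genes & anchors$gene_b %in% all_genes
    if (any(!known)) {
      log["anchors_unmatched"] <- sum(!known)
      warning(sum(!known), " anchor pair(s) not found in any family; skipped")
    }
    akeys <- .pair_key(anchors$gene_a[known], anchors$gene_b[known])
    df$anchor <- .pair_key(df$gene_a, df$gene_b) %in% akeys
  }

  in_range <- df$ks >= ks_range[1] & df$ks <= ks_range[2] & !is.na(df$ks)
  log["excluded_range"] <- sum(!in_range)
  df <- df[in_range, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty distribution: all samples outside the Ks range")
  log["kept"] <- nrow(df)
  rownames(df) <- NULL
  df <- df[, c("ks", "weight", "gene_a", "gene_b", "family_id", "node_id", "anchor")]
  structure(df, class = c("ks_distribution", "data.frame"),
            log = log, ks_range = ks_range)
}

#' Write / read weighted Ks sample tables
#'
#' TSV with header columns `ks`, `weight`, `gene_a`, `gene_b`, `family_id`,
#' `node_id`, `anchor`.
#'
#' @param dist A `ks_distribution` (or plain data frame with those columns).
#' @param path File path.
#' @export
write_distribution <- function(dist, path) {
  utils::write.table(as.data.frame(dist), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ks", "weight")
  if (!all(need %in% names(df)))
    stop("weighted sample table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"anchor" %in% names(df)) df$anchor <- FALSE
  structure(df, class = c("ks_distribution", "data.frame"))
}
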