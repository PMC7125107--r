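# Placing WGD peaks on a species phylogeny with branch lengths in Ks units:
# half of a peak's Ks value is walked from the tip toward the root (duplicate
# copies are assumed to evolve at similar rates, so each accumulates half the
# pairwise distance), and shared vs lineage-specific WGDs are decided by
# comparing the WGD peak CI against rate-corrected divergence peaks.

.root_node <- function(tree) ape::Ntip(tree) + 1L

# edge indices on the path between two tips
.path_edges <- function(tree, i, j) {
  nodes <- ape::nodepath(tree, i, j)
  vapply(seq_len(length(nodes) - 1L), function(k) {
    e <- which((tree$edge[, 1] == nodes[k] & tree$edge[, 2] == nodes[k + 1L]) |
               (tree$edge[, 1] == nodes[k + 1L] & tree$edge[, 2] == nodes[k]))
    e[1]
  }, 0L)
}

#' Estimate branch lengths in Ks units by non-negative least squares
#'
#' Given a fixed rooted topology and a complete matrix of pairwise species
#' Ks distances (e.g. modes of ortholog Ks distributions), solves for
#' non-negative branch lengths such that the path length between every tip
#' pair matches its observed distance, in the least-squares sense. Tip-to-tip
#' distances determine only the sum of the two root-adjacent branches; that
#' sum is split equally between them. An additive input metric is reproduced
#' exactly (zero residual).
#'
#' @param topology Rooted `ape::phylo` (branch lengths, if any, are ignored)
#'   or a newick string.
#' @param pairwise_ks Symmetric numeric matrix with tip names as dimnames;
#'   every off-diagonal entry must be present.
#' @return The tree with estimated `edge.length` (class `phylo`, additionally
#'   `ks_tree`), with attribute `residual` (Euclidean norm of path-distance
#'   residuals).
#' @export
estimate_ks_branch_lengths <- function(topology, pairwise_ks) {
  tree <- if (is.character(topology)) ape::read.tree(text = topology) else topology
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("topology must be rooted")
  tips <- tree$tip.label
  miss <- tips[!tips %in% rownames(pairwise_ks)]
  if (length(miss))
    stop("pairwise Ks matrix lacks species: ", paste(miss, collapse = ", "))
  pairs <- utils::combn(seq_along(tips), 2L)
  d <- pairwise_ks[cbind(tips[pairs[1, ]], tips[pairs[2, ]])]
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("missing pairwise Ks for: ",
         paste(paste(tips[pairs[1, bad]], tips[pairs[2, bad]], sep = "-"),
               collapse = ", "))
  }
  ne <- nrow(tree$edge)
  root_edges <- which(tree$edge[, 1] == .root_node(tree))
  merge_root <- length(root_edges) == 2L
  # columns of the design matrix; the two root edges share one column because
  # only their sum is identifiable from tip-to-tip paths
  col_of <- seq_len(ne)
  if (merge_root) col_of[root_edges[2]] <- root_edges[1]
  keep_cols <- sort(unique(col_of))
  A <- matrix(0, ncol(pairs), length(keep_cols))
  for (r in seq_len(ncol(pairs))) {
    es <- .path_edges(tree, pairs[1, r], pairs[2, r])
    cols <- unique(match(col_of[es], keep_cols))
    A[r, cols] <- 1
  }
  sol <- pracma::lsqnonneg(A, d)
  x <- sol$x
  lens <- numeric(ne)
  lens[keep_cols] <- x
  if (merge_root) {
    lens[root_edges] <- x[match(root_edges[1], keep_cols)] / 2
  }
  tree$edge.length <- lens
  attr(tree, "residual") <- sqrt(sum((A %*% x - d)^2))
  class(tree) <- c("ks_tree", "phylo")
  tree
}

#' Map half of a Ks peak from a tip toward the root
#'
#' Walking from `tip` toward the root of a Ks-unit tree and accumulating
#' branch lengths, the peak is placed on the branch whose cumulative Ks
#' interval contains `peak_ks / 2`. A half-Ks value exactly at a node
#' boundary is assigned to the rootward branch; a value exceeding the
#' tip-to-root depth sets the `beyond_root` flag. CI endpoints (full-scale,
#' halved internally) are mapped the same way; `ci_spans_nodes` is set when
#' the two endpoints land on different branches.
#'
#' @param tree A `phylo`/`ks_tree` with branch lengths in Ks units.
#' @param tip Tip name (the species whose paranome produced the peak).
#' @param peak_ks Peak location on the full (pairwise) Ks scale, or a
#'   [bootstrap_peak_ci()] `peak_estimate` (its CI is then used).
#' @param ci95 Optional full-scale CI `c(lo, hi)`.
#' @return Object of class `wgd_placement`: list with `tip`, `peak_ks`,
#'   `half_ks`, `branch` (edge index, `NA` if beyond root), `branch_child`
#'   (child node of that edge), `position` (Ks from the tip), `ci95_half`,
#'   `ci_branches`, `depth` (tip-to-root Ks), and `flags`
#'   (`beyond_root`, `ci_spans_nodes`).
#' @export
map_peak_to_branch <- function(tree, tip, peak_ks, ci95 = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (inherits(peak_ks, "peak_estimate")) {
    if (is.null(ci95)) ci95 <- peak_ks$ci95
    peak_ks <- peak_ks$location
  }
  if (peak_ks < 0) stop("peak_ks must be >= 0")
  ti <- match(tip, tree$tip.label)
  if (is.na(ti)) stop("unknown tip: ", tip)
  root <- .root_node(tree)
  edges <- integer(0)
  node <- ti
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    edges <- c(edges, e)
    node <- tree$edge[e, 1]
  }
  len <- tree$edge.length[edges]
  cum_hi <- cumsum(len)
  cum_lo <- c(0, cum_hi[-length(cum_hi)])
  depth <- cum_hi[length(cum_hi)]
  locate <- function(h) {
    i <- which(h >= cum_lo & h < cum_hi)[1] # boundary values fall rootward
    if (is.na(i)) NA_integer_ else edges[i]
  }
  half <- peak_ks / 2
  branch <- locate(half)
  beyond <- is.na(branch)
  ci_half <- if (is.null(ci95) || anyNA(ci95)) c(NA_real_, NA_real_) else ci95 / 2
  ci_branches <- if (anyNA(ci_half)) c(NA_integer_, NA_integer_) else
    c(locate(ci_half[1]), locate(ci_half[2]))
  spans <- !anyNA(ci_branches) && ci_branches[1] != ci_branches[2]
  structure(list(tip = tip, peak_ks = peak_ks, half_ks = half,
                 branch = branch,
                 branch_child = if (beyond) NA_integer_ else tree$edge[branch, 2],
                 position = if (beyond) NA_real_ else half,
                 ci95_half = ci_half, ci_branches = ci_branches,
                 depth = depth,
                 flags = list(beyond_root = beyond, ci_spans_nodes = isTRUE(spans))),
            class = "wgd_placement")
}

#' @export
print.wgd_placement <- function(x, ...) {
  if (x$flags$beyond_root) {
    cat(sprintf("%s: half-Ks %.3f exceeds tip-to-root depth %.3f (beyond root)\n",
                x$tip, x$half_ks, x$depth))
  } else {
    cat(sprintf("%s: peak Ks %.3f -> half %.3f on edge %d (child node %d), %.3f Ks from tip\n",
                x$tip, x$peak_ks, x$half_ks, x$branch, x$branch_child, x$position))
  }
  invisible(x)
}

#' Classify a WGD as shared or independent relative to a divergence
#'
#' Both quantities must be on the focal lineage's rate scale and the full
#' (two-lineage) Ks scale: the WGD peak CI versus the corrected ortholog
#' divergence peak (`2 * d_focal`). The WGD is `shared` when its CI lies
#' entirely above the divergence peak (the WGD predates the split),
#' `independent` when entirely below, `unresolved` when the CI straddles the
#' divergence or is missing.
#'
#' @param wgd_ci Full-scale 95% CI `c(lo, hi)` of the WGD peak.
#' @param divergence_ks Corrected divergence peak (full scale).
#' @param focal_tip,other_lineage Names, recorded in the call.
#' @return Object of class `shared_call`: list with `focal_tip`,
#'   `other_lineage`, `wgd_interval`, `divergence_ks`, `verdict`, `margin`
#'   (distance from the nearer CI endpoint to the divergence, signed positive
#'   for shared).
#' @export
classify_shared <- function(wgd_ci, divergence_ks, focal_tip = NA_character_,
                            other_lineage = NA_character_) {
  if (is.null(wgd_ci) || anyNA(wgd_ci)) {
    warning("missing WGD CI; verdict unresolved")
    verdict <- "unresolved"
    margin <- NA_real_
  } else if (wgd_ci[1] > divergence_ks) {
    verdict <- "shared"
    margin <- wgd_ci[1] - divergence_ks
  } else if (wgd_ci[2] < divergence_ks) {
    verdict <- "independent"
    margin <- wgd_ci[2] - divergence_ks
  } else {
    verdict <- "unresolved"
    margin <- 0
  }
  structure(list(focal_tip = focal_tip, other_lineage = other_lineage,
                 wgd_interval = wgd_ci, divergence_ks = divergence_ks,
                 verdict = verdict, margin = margin),
            class = "shared_call")
}

#' Synthesize per-tip placements into a WGD event table
#'
#' Placements mapping inside the same branch whose CIs overlap (placements
#' without a CI use their point position) are grouped into one candidate
#' shared event; the event CI is the union of supporter CIs. Placements on
#' distinct branches remain separate (independent) events. Placements beyond
#' the root are reported but not grouped.
#'
#' @param placements List of [map_peak_to_branch()] results on one tree.
#' @param calls Optional list of [classify_shared()] results, attached as an
#'   attribute.
#' @return Data frame with `event_id`, `branch`, `branch_child`,
#'   `n_supporting`, `tips`, `ci_lo`, `ci_hi` (half-Ks scale, union),
#'   `shared` (> 1 supporter), `beyond_root`.
#' @export
multi_lineage_synthesis <- function(placements, calls = NULL) {
  if (length(placements) == 0L) stop("need at least one placement")
  info <- lapply(placements, function(p) {
    ci <- if (anyNA(p$ci95_half)) c(p$position, p$position) else p$ci95_half
    data.frame(tip = p$tip, branch = ifelse(p$flags$beyond_root, NA, p$branch),
               branch_child = ifelse(p$flags$beyond_root, NA, p$branch_child),
               lo = ci[1], hi = ci[2],
               beyond = p$flags$beyond_root)
  })
  info <- do.call(rbind, info)
  events <- list()
  for (br in unique(info$branch[!info$beyond])) {
    grp <- info[!info$beyond & info$branch == br, , drop = FALSE]
    grp <- grp[order(grp$lo), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    members <- list(cur)
    flush <- function(members) {
      m <- do.call(rbind, members)
      data.frame(branch = br, branch_child = m$branch_child[1],
                 n_supporting = nrow(m),
                 tips = paste(m$tip, collapse = ","),
                 ci_lo = min(m$lo), ci_hi = max(m$hi),
                 shared = nrow(m) > 1L, beyond_root = FALSE)
    }
    if (nrow(grp) > 1L) {
      hi_so_far <- grp$hi[1]
      for (k in 2:nrow(grp)) {
        if (grp$lo[k] <= hi_so_far) { # CI overlap: same candidate event
          members[[length(members) + 1L]] <- grp[k, , drop = FALSE]
          hi_so_far <- max(hi_so_far, grp$hi[k])
        } else {
          events[[length(events) + 1L]] <- flush(members)
          members <- list(grp[k, , drop = FALSE])
          hi_so_far <- grp$hi[k]
        }
      }
    }
    events[[length(events) + 1L]] <- flush(members)
  }
  for (k in which(info$beyond)) {
    events[[length(events) + 1L]] <-
      data.frame(branch = NA_integer_, branch_child = NA_integer_,
                 n_supporting = 1L, tips = info$tip[k],
                 ci_lo = info$lo[k], ci_hi = info$hi[k],
                 shared = FALSE, beyond_root = TRUE)
  }
  out <- do.call(rbind, events)
  out <- cbind(event_id = sprintf("E%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}

#' Write placements and event tables
#'
#' @param placements List of `wgd_placement` objects.
#' @param path File path (TSV).
#' @export
write_placements <- function(placements, path) {
  rows <- lapply(placements, function(p) {
    data.frame(tip = p$tip, peak_ks = p$peak_ks, half_ks = p$half_ks,
               branch = p$branch, branch_child = p$branch_child,
               position = p$position,
               ci_half_lo = p$ci95_half[1], ci_half_hi = p$ci95_half[2],
               beyond_root = p$flags$beyond_root,
               ci_spans_nodes = p$flags$ci_spans_nodes)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @param events Event table from [multi_lineage_synthesis()].
#' @export
write_event_table <- function(events, path) {
  jsonlite::write_json(as.data.frame(events), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Annotate a Ks tree with WGD events and write newick
#'
#' Events are recorded as node comments (`[&WGD=...]`) on the child node of
#' the mapped branch.
#'
#' @param tree A `ks_tree`/`phylo`.
#' @param events Event table from [multi_lineage_synthesis()].
#' @param path File path.
#' @export
write_annotated_tree <- function(tree, events, path) {
  labs <- character(max(tree$edge))
  ntip <- ape::Ntip(tree)
  ev <- events[!events$beyond_root, , drop = FALSE]
  for (k in seq_len(nrow(ev))) {
    child <- ev$branch_child[k]
    labs[child] <- paste0(labs[child], "[&WGD=", ev$event_id[k], "]")
  }
  t2 <- tree
  class(t2) <- "phylo"
  nl <- labs[(ntip + 1L):max(tree$edge)]
  t2$node.label <- ifelse(nzchar(nl), nl, if (is.null(tree$node.label)) "" else tree$node.label)
  ape::write.tree(t2, file = path)
  invisible(path)
}
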