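test_that("three-taxon branch lengths split root-adjacent sums equally", {
  m <- matrix(c(0, 0.4, 0.6, 0.4, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- estimate_ks_branch_lengths("((A,B),C);", m)
  lens <- stats::setNames(tr$edge.length, c(tr$tip.label, rep(NA, 10))[tr$edge[, 2]])
  expect_equal(unname(lens["A"]), 0.2)
  expect_equal(unname(lens["B"]), 0.2)
  # internal + C sum to 0.4 and are split equally at the root
  root_edges <- which(tr$edge[, 1] == ape::Ntip(tr) + 1L)
  expect_equal(sum(tr$edge.length[root_edges]), 0.4)
  expect_equal(tr$edge.length[root_edges[1]], tr$edge.length[root_edges[2]])
  expect_lt(attr(tr, "residual"), 1e-10)
})

test_that("an additive five-taxon metric is reproduced exactly", {
  newick <- "(((A:0.2,B:0.3):0.15,C:0.5):0.1,(D:0.4,E:0.25):0.3);"
  m <- tt_cophenetic(newick)
  tr <- estimate_ks_branch_lengths("(((A,B),C),(D,E));", m)
  expect_lt(attr(tr, "residual"), 1e-10)
  got <- ape::cophenetic.phylo(tr)
  expect_equal(got[rownames(m), colnames(m)], m, tolerance = 1e-8)
})

test_that("branch estimates degrade gracefully under metric noise", {
  newick <- "(((A:0.2,B:0.3):0.15,C:0.5):0.1,(D:0.4,E:0.25):0.3);"
  m <- tt_cophenetic(newick)
  set.seed(501)
  noise <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  noise[upper.tri(noise)] <- runif(sum(upper.tri(noise)), -0.03, 0.03)
  noise <- noise + t(noise)
  tr <- estimate_ks_branch_lengths("(((A,B),C),(D,E));", m + noise)
  got <- ape::cophenetic.phylo(tr)
  expect_lt(max(abs(got[rownames(m), colnames(m)] - m)), 0.1)
  expect_true(all(tr$edge.length >= 0))
})

test_that("missing species or distances are reported by name", {
  m <- tt_cophenetic("((A:1,B:1):1,C:2);")
  expect_error(estimate_ks_branch_lengths("((A,B),(C,D));", m), "D")
  m2 <- m; m2["A", "B"] <- m2["B", "A"] <- NA
  expect_error(estimate_ks_branch_lengths("((A,B),C);", m2), "A-B")
  expect_error(estimate_ks_branch_lengths("(A,B,C);", m), "rooted")
})

test_that("half-Ks peaks map to the expected branches", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.3,C:0.5);")
  # half 0.4 falls on A's parent branch (terminal covers [0, 0.2))
  p1 <- map_peak_to_branch(tr, "A", 0.8)
  expect_equal(p1$half_ks, 0.4)
  expect_false(p1$flags$beyond_root)
  expect_equal(tr$edge[p1$branch, 2], ape::Ntip(tr) + 2L) # child = internal node
  # half 0.15 stays on the terminal branch
  p2 <- map_peak_to_branch(tr, "A", 0.3)
  expect_equal(tr$edge[p2$branch, 2], which(tr$tip.label == "A"))
  # boundary value falls rootward
  p3 <- map_peak_to_branch(tr, "A", 0.4)
  expect_equal(tr$edge[p3$branch, 2], ape::Ntip(tr) + 2L)
  # beyond the root depth
  p4 <- map_peak_to_branch(tr, "A", 1.2)
  expect_true(p4$flags$beyond_root)
  expect_true(is.na(p4$branch))
  expect_error(map_peak_to_branch(tr, "Z", 0.5), "unknown tip")
})

test_that("CI endpoints map independently and spanning is flagged", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.3,C:0.5);")
  p <- map_peak_to_branch(tr, "A", 0.35, ci95 = c(0.3, 0.9))
  expect_equal(p$ci95_half, c(0.15, 0.45))
  expect_true(p$flags$ci_spans_nodes)
  p2 <- map_peak_to_branch(tr, "A", 0.6, ci95 = c(0.5, 0.7))
  expect_false(p2$flags$ci_spans_nodes)
})

test_that("mapped depth is monotone in the peak value", {
  tr <- ape::read.tree(text = "(((A:0.1,B:0.1):0.2,C:0.3):0.2,D:0.5);")
  peaks <- seq(0.02, 0.98, by = 0.04)
  branches <- vapply(peaks, function(k) {
    p <- map_peak_to_branch(tr, "A", k)
    if (p$flags$beyond_root) Inf else {
      # index of the branch along the tip-to-root walk
      node <- which(tr$tip.label == "A"); i <- 0
      repeat {
        e <- which(tr$edge[, 2] == node); i <- i + 1
        if (e == p$branch) break
        node <- tr$edge[e, 1]
      }
      i
    }
  }, 0)
  expect_true(all(diff(branches) >= 0))
})

test_that("shared versus independent classification respects the CI", {
  s <- classify_shared(c(1.2, 1.4), 1.0, "A", "B")
  expect_equal(s$verdict, "shared")
  expect_equal(s$margin, 0.2)
  i <- classify_shared(c(0.5, 0.8), 1.0, "A", "B")
  expect_equal(i$verdict, "independent")
  expect_equal(i$margin, -0.2)
  u <- classify_shared(c(0.9, 1.1), 1.0, "A", "B")
  expect_equal(u$verdict, "unresolved")
  expect_warning(m <- classify_shared(c(NA, NA), 1.0), "missing WGD CI")
  expect_equal(m$verdict, "unresolved")
})

test_that("synthesis groups same-branch overlapping placements into one event", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.3,C:0.5);")
  pa <- map_peak_to_branch(tr, "A", 0.7, ci95 = c(0.6, 0.8))
  pb <- map_peak_to_branch(tr, "B", 0.72, ci95 = c(0.62, 0.82))
  ev <- multi_lineage_synthesis(list(pa, pb))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_supporting, 2L)
  expect_true(ev$shared)
  expect_equal(ev$ci_lo, 0.3)
  expect_equal(ev$ci_hi, 0.41)
  # non-overlapping CIs on the same branch stay distinct events
  pc <- map_peak_to_branch(tr, "A", 0.9, ci95 = c(0.88, 0.92))
  ev2 <- multi_lineage_synthesis(list(pa, pc))
  expect_equal(nrow(ev2), 2)
  expect_true(all(!ev2$shared))
  # beyond-root placements are reported separately
  pd <- map_peak_to_branch(tr, "C", 1.4)
  ev3 <- multi_lineage_synthesis(list(pa, pd))
  expect_true(any(ev3$beyond_root))
  expect_error(multi_lineage_synthesis(list()), "at least one")
})

test_that("placements and events round-trip to disk", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.3,C:0.5);")
  pa <- map_peak_to_branch(tr, "A", 0.7, ci95 = c(0.6, 0.8))
  ev <- multi_lineage_synthesis(list(pa))
  d <- withr::local_tempdir()
  write_placements(list(pa), file.path(d, "pl.tsv"))
  write_event_table(ev, file.path(d, "ev.json"))
  write_annotated_tree(tr, ev, file.path(d, "tree.nwk"))
  back <- utils::read.delim(file.path(d, "pl.tsv"))
  expect_equal(back$peak_ks, 0.7)
  js <- jsonlite::read_json(file.path(d, "ev.json"))
  expect_equal(js[[1]]$event_id, "E01")
  nwk <- readLines(file.path(d, "tree.nwk"))
  expect_true(grepl("WGD=E01", nwk))
})
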