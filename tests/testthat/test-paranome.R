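mat_from_pairs <- function(genes, pairs) {
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  diag(m) <- 0
  for (p in pairs) m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  m
}

test_that("complete-linkage splitting separates saturated subfamilies", {
  m <- mat_from_pairs(c("A", "B", "C"),
                      list(list("A", "B", 0.3), list("A", "C", 4),
                           list("B", "C", 6)))
  sp <- lapply(split_subfamilies(m, cutoff = 5), sort)
  expect_setequal(sp, list(c("A", "B"), "C"))
  # all below cutoff -> one subfamily
  m2 <- mat_from_pairs(c("A", "B", "C"),
                       list(list("A", "B", 0.3), list("A", "C", 1),
                            list("B", "C", 1.2)))
  expect_length(split_subfamilies(m2, cutoff = 5), 1)
  # a missing entry counts as beyond the cutoff, so no 3-member subfamily
  m3 <- mat_from_pairs(c("A", "B", "C"),
                       list(list("A", "B", 0.3), list("B", "C", 0.4)))
  expect_true(all(lengths(split_subfamilies(m3, cutoff = 5)) <= 2))
  expect_error(split_subfamilies(m, cutoff = 0), "positive")
})

test_that("duplication trees recover average-linkage node heights", {
  m <- mat_from_pairs(c("A", "B", "C"),
                      list(list("A", "B", 0.2), list("A", "C", 1.0),
                           list("B", "C", 1.2)))
  nodes <- build_duplication_tree(m)
  expect_length(nodes, 2)
  heights <- sort(vapply(nodes, `[[`, 0, "node_ks"))
  expect_equal(heights, c(0.2, 1.1))
  w <- weight_duplications(nodes, m)
  expect_equal(nrow(w), 3)
  expect_equal(sum(w$weight), 2) # n - 1 duplication events
  expect_setequal(w$weight, c(1, 0.5, 0.5))
  expect_error(build_duplication_tree(mat_from_pairs(
    c("A", "B", "C"), list(list("A", "B", 0.2)))), "missing")
})

test_that("each duplication node contributes exactly unit weight", {
  # 4-member ultrametric family: ((A,B),(C,D)) with heights 0.2, 0.4, 1.0
  m <- mat_from_pairs(c("A", "B", "C", "D"),
                      list(list("A", "B", 0.2), list("C", "D", 0.4),
                           list("A", "C", 1.0), list("A", "D", 1.0),
                           list("B", "C", 1.0), list("B", "D", 1.0)))
  nodes <- build_duplication_tree(m)
  w <- weight_duplications(nodes, m)
  expect_equal(nrow(w), 6)
  expect_equal(sum(w$weight), 3)
  per_node <- tapply(w$weight, w$node_id, sum)
  expect_true(all(abs(per_node - 1) < 1e-12))
  deep <- w[w$ks == 1.0, ]
  expect_equal(nrow(deep), 4)
  expect_true(all(deep$weight == 0.25))
})

test_that("weight conservation holds for random ultrametric families", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    genes <- sprintf("g%02d", 1:n)
    fam <- wgdplacer:::.assemble_family(genes, sort(runif(n - 1, 0.1, 3)),
                                        sprintf("F%02d.", rep))
    pairs <- lapply(seq_len(nrow(fam)), function(i)
      list(fam$gene_a[i], fam$gene_b[i], fam$ks[i]))
    m <- mat_from_pairs(genes, pairs)
    nodes <- build_duplication_tree(m)
    w <- weight_duplications(nodes, m)
    expect_equal(sum(w$weight), n - 1)
    expect_true(all(abs(tapply(w$weight, w$node_id, sum) - 1) < 1e-12))
  }
})

test_that("clustering output is invariant to member input order", {
  m <- mat_from_pairs(c("A", "B", "C", "D"),
                      list(list("A", "B", 0.2), list("C", "D", 0.4),
                           list("A", "C", 1.0), list("A", "D", 1.0),
                           list("B", "C", 1.0), list("B", "D", 1.0)))
  perm <- c("D", "B", "A", "C")
  w1 <- weight_duplications(build_duplication_tree(m), m)
  m2 <- m[perm, perm]
  w2 <- weight_duplications(build_duplication_tree(m2), m2)
  key <- function(w) {
    k <- paste(pmin(w$gene_a, w$gene_b), pmax(w$gene_a, w$gene_b))
    o <- order(k)
    data.frame(key = k[o], ks = w$ks[o], weight = w$weight[o])
  }
  expect_equal(key(w1), key(w2))
})

test_that("build_distribution conserves n - 1 weight per family", {
  cfg <- tt_two_wgd_config(seed = 21, n_wgd = 200, n_ssd = 200)
  ds <- simulate_paranome(cfg, "A")
  fams <- split(ds$family_table$gene_id, ds$family_table$family_id)
  dist <- build_distribution(fams, ds$ks_table, ks_range = c(0, 5))
  per_fam <- tapply(dist$weight, dist$family_id, sum)
  sizes <- lengths(fams)[names(per_fam)]
  expect_true(all(abs(per_fam - (sizes - 1)) < 1e-9))
  expect_s3_class(dist, "ks_distribution")
})

test_that("out-of-range values are excluded and logged", {
  fams <- list(F1 = c("a", "b"), F2 = c("c", "d"), F3 = c("e", "f"))
  tab <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                    ks = c(0.5, 0.01, 4.5))
  dist <- build_distribution(fams, tab, ks_range = c(0.05, 4))
  expect_equal(nrow(dist), 1)
  expect_equal(dist$ks, 0.5)
  expect_equal(unname(attr(dist, "log")["excluded_range"]), 2L)
  expect_error(build_distribution(list(F1 = c("a", "b")),
                                  data.frame(gene_a = "a", gene_b = "b",
                                             ks = 0.01)),
               "outside the Ks range")
})

test_that("anchor pairs are flagged and unmatched anchors are reported", {
  fams <- list(F1 = c("a", "b"), F2 = c("c", "d"))
  tab <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "d"), ks = c(0.5, 0.7))
  anch <- data.frame(gene_a = c("b", "x"), gene_b = c("a", "y"))
  expect_warning(dist <- build_distribution(fams, tab, anchors = anch),
                 "anchor")
  expect_true(dist$anchor[dist$gene_a == "a"])
  expect_false(dist$anchor[dist$gene_a == "c"])
  expect_equal(unname(attr(dist, "log")["anchors_unmatched"]), 1L)
})

test_that("distributions round-trip through TSV", {
  fams <- list(F1 = c("a", "b"))
  tab <- data.frame(gene_a = "a", gene_b = "b", ks = 0.5)
  dist <- build_distribution(fams, tab)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(dist, f)
  back <- read_distribution(f)
  expect_equal(back$ks, dist$ks)
  expect_equal(back$weight, dist$weight)
})
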