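two_tip_cfg <- function(..., seed = 1) {
  simulation_config("(A:1,B:1);", c(A = 0.5, B = 0.5), ..., seed = seed)
}

test_that("config validation rejects inconsistent study conditions", {
  expect_error(simulation_config("(A:1,B:1);", c(A = 0.5), seed = 1),
               "cover every tip")
  expect_error(simulation_config("(A:1,B:1);", c(A = -1, B = 0.5), seed = 1),
               "strictly positive")
  expect_error(two_tip_cfg(wgd_events = list(list(branch = "Z", age = 0.5,
                                                  sigma_ks = 0, n_pairs = 10))),
               "branch id not found")
  expect_error(two_tip_cfg(ssd = list(n_pairs = 10, decay_rate = -1)),
               "decay_rate")
})

test_that("zero-spread WGD pairs sit exactly at twice rate times age", {
  cfg <- two_tip_cfg(wgd_events = list(list(branch = "A", age = 0.8,
                                            sigma_ks = 0, n_pairs = 100)),
                     ssd = list(n_pairs = 0, decay_rate = 1))
  ds <- simulate_paranome(cfg, "A")
  expect_equal(nrow(ds$ks_table), 100)
  expect_true(all(ds$ks_table$ks == 2 * 0.5 * 0.8))
  expect_true(all(ds$truth$origin == "WGD-1"))
})

test_that("SSD-only background has the configured exponential mean", {
  cfg <- two_tip_cfg(ssd = list(n_pairs = 10000, decay_rate = 1.0), seed = 5)
  ds <- simulate_paranome(cfg, "A")
  expect_equal(nrow(ds$ks_table), 10000)
  expect_lt(abs(mean(ds$ks_table$ks) - 1.0), 0.03)
})

test_that("two-WGD paranomes are bimodal at the true ages", {
  cfg <- tt_two_wgd_config(seed = 11)
  ds <- simulate_paranome(cfg, "A")
  wgd1 <- ds$ks_table$ks[ds$truth$origin == "WGD-1"]
  wgd2 <- ds$ks_table$ks[ds$truth$origin == "WGD-2"]
  # dense-grid KDE oracle per component
  expect_lt(abs(kde_mode(wgd1) - 0.5), 0.05)
  expect_lt(abs(kde_mode(wgd2) - 0.8), 0.05)
  d <- stats::density(ds$ks_table$ks, bw = 0.03, from = 0, to = 2, n = 1024)
  pk <- oracle_find_peaks(d$y, w = 25)
  modes <- d$x[pk][order(d$y[pk], decreasing = TRUE)][1:2]
  expect_lt(abs(min(modes) - 0.5), 0.05)
  expect_lt(abs(max(modes) - 0.8), 0.05)
})

test_that("datasets are reproducible and truth covers every emitted pair", {
  cfg <- tt_two_wgd_config(seed = 3, n_wgd = 50, n_ssd = 50)
  a <- simulate_paranome(cfg, "A")
  b <- simulate_paranome(cfg, "A")
  expect_identical(a, b)
  expect_equal(nrow(a$truth), nrow(a$ks_table))
  expect_setequal(paste(a$truth$gene_a, a$truth$gene_b),
                  paste(a$ks_table$gene_a, a$ks_table$gene_b))
  # every gene in the Ks table appears in the family table
  expect_true(all(c(a$ks_table$gene_a, a$ks_table$gene_b) %in%
                    a$family_table$gene_id))
  # anchors are a subset of WGD-origin pairs
  akey <- paste(a$anchor_pairs$gene_a, a$anchor_pairs$gene_b)
  wkey <- paste(a$truth$gene_a, a$truth$gene_b)[grepl("WGD", a$truth$origin)]
  expect_true(all(akey %in% wkey))
})

test_that("unknown focal species and empty requests are errors", {
  cfg <- two_tip_cfg(ssd = list(n_pairs = 10, decay_rate = 1))
  expect_error(simulate_paranome(cfg, "Z"), "unknown focal species")
  cfg0 <- two_tip_cfg()
  expect_error(simulate_paranome(cfg0, "A"), "zero pairs")
})

test_that("larger families carry self-consistent duplication histories", {
  cfg <- two_tip_cfg(ssd = list(n_pairs = 600, decay_rate = 1),
                     family_size = list(type = "uniform", min = 2, max = 8),
                     seed = 9)
  ds <- simulate_paranome(cfg, "A")
  sizes <- table(ds$family_table$family_id)
  expect_true(any(sizes > 2))
  # per family: number of duplication nodes equals size - 1
  nodes_per_fam <- tapply(ds$truth$node_id, ds$truth$family_id,
                          function(x) length(unique(x)))
  expect_equal(unname(nodes_per_fam[names(sizes)]), unname(sizes) - 1L,
               ignore_attr = TRUE)
  # pairwise Ks is ultrametric within a family: for any three genes the two
  # largest pairwise values are equal (checked on a sample of families)
  fams <- names(sizes[sizes >= 3])[1:5]
  lut <- stats::setNames(ds$ks_table$ks,
                         paste(ds$ks_table$gene_a, ds$ks_table$gene_b))
  get_ks <- function(a, b) {
    v <- lut[paste(a, b)]
    if (is.na(v)) v <- lut[paste(b, a)]
    unname(v)
  }
  for (f in fams) {
    g <- ds$family_table$gene_id[ds$family_table$family_id == f]
    tri <- utils::combn(g, 3)
    for (k in seq_len(ncol(tri))) {
      d3 <- sort(c(get_ks(tri[1, k], tri[2, k]), get_ks(tri[1, k], tri[3, k]),
                   get_ks(tri[2, k], tri[3, k])))
      expect_equal(d3[2], d3[3])
    }
  }
})

test_that("noise-free ortholog samples obey the additive location law", {
  cfg <- simulation_config("((A:1,B:1)ab:1,C:2);", c(A = 0.5, B = 0.5, C = 0.5),
                           ortholog_sampling = list(n_pairs = 100, noise_sd = 0),
                           seed = 2)
  s <- simulate_ortholog_ks(cfg, "A", "B")
  expect_true(all(s$values == 1.0))
  expect_equal(s$d_a, 0.5)
  expect_equal(s$d_b, 0.5)
  # asymmetric rates on sister terminal branches
  cfg2 <- simulation_config("(A:0.5,B:0.5);", c(A = 1.8, B = 0.6),
                            ortholog_sampling = list(n_pairs = 50, noise_sd = 0),
                            seed = 2)
  s2 <- simulate_ortholog_ks(cfg2, "A", "B")
  expect_true(all(s2$values == 1.2))
  expect_equal(s2$d_a, 0.9)
  expect_equal(s2$d_b, 0.3)
  expect_error(simulate_ortholog_ks(cfg, "A", "A"), "must differ")
})

test_that("noisy ortholog samples have their KDE mode at the true location", {
  cfg <- simulation_config("(A:1,B:1);", c(A = 0.7, B = 0.4),
                           ortholog_sampling = list(n_pairs = 5000, noise_sd = 0.1),
                           seed = 8)
  s <- simulate_ortholog_ks(cfg, "A", "B")
  expect_lt(abs(kde_mode(s$values) - s$location), 0.02)
})

test_that("evolved codon pairs are identical at Ks 0 and refused at saturation", {
  p0 <- evolve_codon_pair(0, 30, seed = 4)
  expect_identical(p0$a, p0$b)
  expect_equal(nchar(p0$a), 90)
  expect_error(evolve_codon_pair(10, 100), "saturation")
  # reproducibility
  expect_identical(evolve_codon_pair(0.4, 100, seed = 7),
                   evolve_codon_pair(0.4, 100, seed = 7))
})

test_that("synthetic datasets round-trip to disk", {
  cfg <- tt_two_wgd_config(seed = 3, n_wgd = 30, n_ssd = 30)
  ds <- simulate_paranome(cfg, "A")
  d <- withr::local_tempdir()
  write_synthetic_dataset(ds, d)
  expect_true(all(file.exists(file.path(d, c("families.tsv", "ks_table.tsv",
                                             "anchor_pairs.tsv", "truth.json")))))
  back <- utils::read.delim(file.path(d, "ks_table.tsv"))
  expect_equal(nrow(back), nrow(ds$ks_table))
})
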