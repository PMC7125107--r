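# Shared fixtures and independent oracles used across test files.

# Standard genetic code as a plain lookup, built independently of the
# package's internals (Biostrings is the common source of truth).
.tt_code <- Biostrings::GENETIC_CODE

# Brute-force NG86 oracle: explicit site enumeration and explicit recursive
# path enumeration, written naively so it shares no code with the estimator.
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  cv <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in bases) {
      if (b == cv[pos]) next
      alt <- cv; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (.tt_code[[alt]] == "*") next
      valid <- valid + 1
      if (.tt_code[[alt]] == .tt_code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

oracle_paths <- function(c1, c2) {
  # all orderings of the differing positions; drop orderings through stops
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  dpos <- which(v1 != v2)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  sds <- c(); nds <- c()
  for (ord in perms(dpos)) {
    cur <- v1; sd <- 0; nd <- 0; okpath <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- v2[p]
      if (.tt_code[[paste(nxt, collapse = "")]] == "*") { okpath <- FALSE; break }
      if (.tt_code[[paste(cur, collapse = "")]] == .tt_code[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (okpath) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (length(sds) == 0) return(NULL)
  c(sd = mean(sds), nd = mean(nds))
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(ca)) {
    if (.tt_code[[ca[i]]] == "*" || .tt_code[[cb[i]]] == "*") next
    d <- oracle_paths(ca[i], cb[i])
    if (is.null(d)) next
    sa <- oracle_sites(ca[i]); sb <- oracle_sites(cb[i])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
    used <- used + 1
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       ps = unname(ps), pn = unname(pn),
       ks = if (ps >= 0.75) NA_real_ else unname(-0.75 * log(1 - 4 * ps / 3)),
       n_codons = used)
}

# A 20-codon alphabet (fixed, one codon per amino acid) for oracle panels
tt_codon_alphabet <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
                       "AAA", "CTT", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT",
                       "ACT", "GTT", "TGG", "TAT")

# Brute-force peak definition mirroring the documented window rule
oracle_find_peaks <- function(h, w = 3) {
  n <- length(h)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    ok <- TRUE
    for (j in seq(max(1, i - w), min(n, i + w))) {
      if (j == i) next
      if (j < i && h[j] >= h[i]) ok <- FALSE
      if (j > i && h[j] > h[i]) ok <- FALSE
    }
    if (ok) out <- c(out, i)
  }
  out
}

# Small additive Ks matrix from a tree with known branch lengths
tt_cophenetic <- function(newick) {
  tr <- ape::read.tree(text = newick)
  ape::cophenetic.phylo(tr)
}

# Canonical two-WGD study configuration (true Ks peaks at 0.5 and 0.8)
tt_two_wgd_config <- function(seed, n_wgd = 2000, n_ssd = 1000, sigma = 0.08) {
  simulation_config(
    "((A:1,B:1)ab:1,(C:1.5,D:1.5)cd:0.5)r;",
    c(A = 0.5, B = 0.5, C = 0.5, D = 0.5),
    wgd_events = list(
      list(branch = "A", age = 0.5, sigma_ks = sigma, n_pairs = n_wgd),
      list(branch = "A", age = 0.8, sigma_ks = sigma, n_pairs = n_wgd)),
    ssd = list(n_pairs = n_ssd, decay_rate = 1.0),
    seed = seed)
}
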