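# Pairwise Ks/Ka estimation from in-frame codon sequences: the counting
# estimator of Nei & Gojobori (1986) with Jukes-Cantor multiple-hit
# correction, plus import/export of precomputed Ks tables.

.ks_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.ks_env$code)) {
    code <- Biostrings::GENETIC_CODE
    .ks_env$code <- code
    .ks_env$sense <- names(code)[code != "*"]
  }
  .ks_env$code
}

.bases <- c("A", "C", "G", "T")

#' Synonymous and nonsynonymous site counts for one codon
#'
#' For each codon position, the three single-nucleotide alternatives are
#' classified as synonymous or nonsynonymous under the standard genetic code;
#' alternatives that create a stop codon are excluded from the position's
#' denominator. The position contributes the synonymous fraction to `s`, and
#' `n = 3 - s`, so `s + n = 3` for every sense codon.
#'
#' @param codon A single 3-letter string over `A`, `C`, `G`, `T`; must not be
#'   a stop codon.
#' @return Named numeric vector `c(s = , n = )` of fractional synonymous and
#'   nonsynonymous sites.
#' @examples
#' count_sites("GGT") # glycine: third position fully synonymous -> s = 1
#' count_sites("ATG") # methionine: no synonymous neighbours -> s = 0
#' @export
count_sites <- function(codon) {
  code <- .genetic_code()
  if (!is.character(codon) || length(codon) != 1L)
    stop("`codon` must be a single 3-letter string")
  codon <- toupper(codon)
  if (!codon %in% names(code))
    stop("not a valid codon over ACGT: ", codon)
  if (code[[codon]] == "*")
    stop("stop codon has no site counts: ", codon)
  cv <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    alts <- .bases[.bases != cv[pos]]
    neigh <- vapply(alts, function(b) {
      x <- cv
      x[pos] <- b
      paste(x, collapse = "")
    }, character(1))
    aa <- code[neigh]
    keep <- aa != "*"
    if (any(keep))
      s <- s + sum(aa[keep] == code[[codon]]) / sum(keep)
  }
  c(s = s, n = 3 - s)
}

# site-count lookup for all sense codons, built lazily
.site_table <- function() {
  if (is.null(.ks_env$sites)) {
    .genetic_code()
    .ks_env$sites <- t(vapply(.ks_env$sense, count_sites, c(s = 0, n = 0)))
  }
  .ks_env$sites
}

# Synonymous/nonsynonymous differences between two codons, averaged over all
# shortest mutational paths that avoid stop codons. Returns c(sd, nd) or NULL
# when every path is blocked by a stop.
.codon_pair_diffs <- function(c1, c2) {
  if (is.null(.ks_env$pair_cache)) .ks_env$pair_cache <- new.env(parent = emptyenv())
  key <- if (c1 <= c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .ks_env$pair_cache[[key]]
  if (!is.null(hit)) return(if (length(hit) == 0) NULL else hit)
  code <- .genetic_code()
  paths <- function(v1, v2) {
    # returns c(sum_sd, sum_nd, n_paths) over stop-free shortest paths
    dpos <- which(v1 != v2)
    if (length(dpos) == 0L) return(c(0, 0, 1))
    acc <- c(0, 0, 0)
    from <- paste(v1, collapse = "")
    for (p in dpos) {
      w <- v1
      w[p] <- v2[p]
      mid <- paste(w, collapse = "")
      if (code[[mid]] == "*") next
      sub <- paths(w, v2)
      if (sub[3] == 0) next
      syn_step <- code[[from]] == code[[mid]]
      acc <- acc + c(sub[1] + if (syn_step) sub[3] else 0,
                     sub[2] + if (syn_step) 0 else sub[3],
                     sub[3])
    }
    acc
  }
  res <- paths(strsplit(c1, "", fixed = TRUE)[[1]], strsplit(c2, "", fixed = TRUE)[[1]])
  out <- if (res[3] == 0) NULL else c(sd = res[1] / res[3], nd = res[2] / res[3])
  .ks_env$pair_cache[[key]] <- if (is.null(out)) numeric(0) else out
  out
}

.split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Estimate Ks and Ka for one in-frame codon sequence pair
#'
#' Counting estimator: fractional synonymous (S) and nonsynonymous (N) sites
#' are averaged over the two sequences; observed synonymous/nonsynonymous
#' differences are counted per codon, averaging over all shortest mutational
#' paths between differing codons (paths through stop codons are excluded;
#' codons with no stop-free path are dropped). The observed proportions
#' `ps = Sd/S` and `pn = Nd/N` are corrected for multiple hits with the
#' Jukes-Cantor formula `K = -(3/4) log(1 - (4/3) p)`. Proportions at or
#' above 3/4 are saturated and the corresponding distance is undefined (`NA`).
#'
#' Codons containing non-ACGT symbols, gaps, or in-frame stops in either
#' sequence are excluded pairwise before counting; the exclusion count is
#' reported.
#'
#' @param seq_a,seq_b Character strings (or objects coercible via
#'   `as.character`) of equal length, a multiple of 3, pre-aligned in frame.
#' @return Object of class `ks_estimate`: a list with `ks`, `ka`, `S`, `N`,
#'   `Sd`, `Nd`, `ps`, `pn`, `n_codons`, `n_excluded`, and logical `flags`
#'   (`saturated_s`, `saturated_n`).
#' @examples
#' a <- paste(rep("GGT", 10), collapse = "")
#' b <- paste(c(rep("GGT", 9), "GGC"), collapse = "")
#' ng86_ks(a, b)$ks # 0.1073
#' @export
ng86_ks <- function(seq_a, seq_b) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (length(a) != 1L || length(b) != 1L)
    stop("each sequence must be a single string")
  if (nchar(a) != nchar(b))
    stop("sequence lengths differ (", nchar(a), " vs ", nchar(b), ")")
  if (nchar(a) %% 3L != 0L)
    stop("sequence length is not a multiple of 3")
  if (nchar(a) == 0L)
    stop("empty sequences")
  code <- .genetic_code()
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  ok <- ca %in% .ks_env$sense & cb %in% .ks_env$sense
  n_excluded <- sum(!ok)
  ca <- ca[ok]
  cb <- cb[ok]
  sites <- .site_table()
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; n_used <- 0L
  for (i in seq_along(ca)) {
    d <- if (ca[i] == cb[i]) c(sd = 0, nd = 0) else .codon_pair_diffs(ca[i], cb[i])
    if (is.null(d)) { # all shortest paths blocked by stops
      n_excluded <- n_excluded + 1L
      next
    }
    S <- S + (sites[ca[i], "s"] + sites[cb[i], "s"]) / 2
    N <- N + (sites[ca[i], "n"] + sites[cb[i], "n"]) / 2
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop("no comparable codons after filtering; estimate undefined")
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  sat_s <- ps >= 0.75
  sat_n <- pn >= 0.75
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  structure(list(
    ks = if (sat_s) NA_real_ else jc(ps),
    ka = if (sat_n) NA_real_ else jc(pn),
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
    n_codons = n_used, n_excluded = n_excluded,
    flags = list(saturated_s = sat_s, saturated_n = sat_n)
  ), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("Ks = %s, Ka = %s  (S = %.2f, N = %.2f, %d codons, %d excluded)\n",
              format(x$ks, digits = 4), format(x$ka, digits = 4),
              x$S, x$N, x$n_codons, x$n_excluded))
  if (x$flags$saturated_s) cat("  synonymous distance saturated (ps >= 3/4)\n")
  if (x$flags$saturated_n) cat("  nonsynonymous distance saturated (pn >= 3/4)\n")
  invisible(x)
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read and write pairwise Ks tables
#'
#' Tab-separated with a header; columns `gene_a`, `gene_b`, `ks` and
#' optionally `ka`. Pair order is insignificant: duplicated unordered pairs
#' are an error.
#'
#' @param path File path.
#' @return `read_ks_table`: a data frame with columns `gene_a`, `gene_b`,
#'   `ks` (and `ka` when present).
#' @export
read_ks_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_a", "gene_b", "ks")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ks table ", path, " lacks required column(s): ", paste(miss, collapse = ", "))
  if (any(df$ks < 0, na.rm = TRUE)) stop("negative Ks values in ", path)
  key <- .pair_key(df$gene_a, df$gene_b)
  if (anyDuplicated(key)) stop("duplicated unordered gene pairs in ", path)
  df
}

#' @rdname read_ks_table
#' @param ks_table Data frame as returned by [read_ks_table()].
#' @export
write_ks_table <- function(ks_table, path) {
  utils::write.table(ks_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' Record ids are truncated at the first whitespace.
#'
#' @param path FASTA file of in-frame CDS.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_cds_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Pairwise Ks matrix for one gene family
#'
#' Builds the symmetric all-vs-all Ks matrix for the family members, either
#' by looking pairs up in a precomputed Ks table or by running [ng86_ks()]
#' on supplied coding sequences. Saturated or missing pairs are `NA` and
#' listed in the `missing` attribute.
#'
#' @param members Character vector of gene ids (length >= 2).
#' @param ks_table Optional data frame with `gene_a`, `gene_b`, `ks`.
#' @param cds Optional named character vector of in-frame CDS covering the
#'   members (used when `ks_table` is `NULL`).
#' @return Symmetric numeric matrix with zero diagonal, `NA` for undefined
#'   entries, and attribute `missing` (data frame gene_a/gene_b/reason).
#' @export
family_ks_matrix <- function(members, ks_table = NULL, cds = NULL) {
  members <- as.character(members)
  if (length(members) < 2L) stop("singleton family: need >= 2 members")
  if (anyDuplicated(members)) stop("duplicated gene ids within family")
  n <- length(members)
  m <- matrix(NA_real_, n, n, dimnames = list(members, members))
  diag(m) <- 0
  missing <- list()
  if (!is.null(ks_table)) {
    lut <- stats::setNames(ks_table$ks, .pair_key(ks_table$gene_a, ks_table$gene_b))
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    gi <- members[i]; gj <- members[j]
    val <- NA_real_; reason <- NULL
    if (!is.null(ks_table)) {
      val <- unname(lut[.pair_key(gi, gj)])
      if (is.na(val)) reason <- "no table entry"
    } else if (!is.null(cds)) {
      if (!gi %in% names(cds) || !gj %in% names(cds)) {
        reason <- "missing CDS"
      } else {
        est <- ng86_ks(cds[[gi]], cds[[gj]])
        val <- est$ks
        if (is.na(val)) reason <- "saturated"
      }
    } else {
      stop("provide either `ks_table` or `cds`")
    }
    m[i, j] <- m[j, i] <- val
    if (!is.null(reason))
      missing[[length(missing) + 1L]] <- data.frame(gene_a = gi, gene_b = gj,
                                                    reason = reason)
  }
  attr(m, "missing") <- if (length(missing)) do.call(rbind, missing) else
    data.frame(gene_a = character(0), gene_b = character(0), reason = character(0))
  m
}
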