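# Gap policy: "complete_deletion" drops every column containing a gap
# before analysis (the convention behind the headline diversity table);
# "pairwise" keeps all columns and excludes incomparable sites per pair.
# N is treated as missing and excluded pairwise under both policies.

gapfree_columns <- function(mat) {
  which(colSums(mat == "-") == 0L)
}

# number of distinct non-N characters per column, vectorised
column_allele_counts <- function(mat) {
  nall <- integer(ncol(mat))
  for (ch in ALLELES) nall <- nall + (colSums(mat == ch) > 0L)
  nall
}

apply_gap_policy <- function(mat, gap_policy = c("complete_deletion", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  if (gap_policy == "complete_deletion")
    mat <- mat[, gapfree_columns(mat), drop = FALSE]
  mat
}

# Pairwise difference counts (and comparable-site counts) between all rows.
# Differences require both characters non-N (and, under pairwise policy,
# non-gap); under complete_deletion the matrix is pre-filtered.
pairwise_diffs <- function(mat, gap_policy = "complete_deletion") {
  mat <- apply_gap_policy(mat, gap_policy)
  n <- nrow(mat)
  d <- matrix(0, n, n)
  comp <- matrix(0, n, n)
  variable <- which(column_allele_counts(mat) > 1L)
  ok_all <- mat != "N" & mat != "-"
  # comparable sites: start from columns where both are informative
  comp[] <- tcrossprod(ok_all * 1)
  for (j in variable) {
    col <- mat[, j]
    ok <- ok_all[, j]
    ne <- outer(col, col, "!=") & outer(ok, ok, "&")
    d <- d + ne
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(mat)
  attr(d, "comparable") <- comp
  attr(d, "L_analyzed") <- ncol(mat)
  d
}

#' Collapse aligned sequences into distinct haplotypes
#'
#' Under `complete_deletion`, identity is tested on gap-free columns only
#' (two sequences differing solely at a gap column merge); under
#' `pairwise`, the full gapped strings are compared, so indels distinguish
#' haplotypes.
#'
#' @param aln [mito_alignment()]
#' @param gap_policy see above.
#' @return `haplotype_set`: `seq` (k x L matrix of representatives over the
#'   full region), `counts`, `membership` (sequence id -> haplotype index),
#'   `n`, `k`, and the alignment `meta`.
#' @export
collapse_haplotypes <- function(aln, gap_policy = c("complete_deletion", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  if (n_seq(aln) == 0L) stop_mitopop("empty alignment")
  key_mat <- apply_gap_policy(aln$seq, gap_policy)
  keys <- apply(key_mat, 1L, paste, collapse = "")
  idx <- match(keys, unique(keys))
  k <- max(idx)
  counts <- tabulate(idx, k)
  first <- match(seq_len(k), idx)
  membership <- stats::setNames(idx, rownames(aln$seq))
  structure(list(seq = aln$seq[first, , drop = FALSE],
                 counts = counts,
                 membership = membership,
                 ids = paste0("H", seq_len(k)),
                 n = n_seq(aln), k = k, meta = aln$meta),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", x$k, "distinct haplotypes from", x$n, "sequences\n")
  invisible(x)
}

#' Segregating sites and total mutations
#'
#' @param aln [mito_alignment()]
#' @param gap_policy gap handling.
#' @return list `(S, eta)`: S counts columns with >= 2 distinct non-missing
#'   nucleotides; eta adds (alleles - 1) per column, counting multi-allelic
#'   columns once per extra allele.
#' @export
segregating_sites <- function(aln, gap_policy = c("complete_deletion", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  mat <- apply_gap_policy(aln$seq, gap_policy)
  nall <- column_allele_counts(mat)
  S <- sum(nall >= 2L)
  eta <- sum(pmax(nall - 1L, 0L))
  list(S = S, eta = eta)
}

#' Haplotype diversity
#'
#' Hd = n(1 - sum p_i^2)/(n - 1), the probability that two randomly drawn
#' haplotypes differ, with small-sample correction.
#'
#' @param hs [collapse_haplotypes()] result.
#' @export
haplotype_diversity <- function(hs) {
  n <- hs$n
  if (n < 2L) stop_mitopop("haplotype diversity needs n >= 2")
  p <- hs$counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity per site
#'
#' Mean pairwise difference fraction. Under `complete_deletion` the common
#' denominator is the gap-free column count; under `pairwise` each pair is
#' scored over its own comparable sites and the per-pair per-site fractions
#' are averaged.
#'
#' @inheritParams segregating_sites
#' @export
nucleotide_diversity <- function(aln, gap_policy = c("complete_deletion", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  n <- n_seq(aln)
  if (n < 2L) stop_mitopop("nucleotide diversity needs n >= 2")
  d <- pairwise_diffs(aln$seq, gap_policy)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  if (gap_policy == "complete_deletion") {
    L <- attr(d, "L_analyzed")
    if (L == 0L) stop_mitopop("no analyzable sites after gap removal")
    mean(d[pairs]) / L
  } else {
    comp <- attr(d, "comparable")
    if (any(comp[pairs] == 0)) stop_mitopop("a pair has no comparable sites")
    mean(d[pairs] / comp[pairs])
  }
}

#' Assemble the per-fragment diversity summary
#'
#' One row of the diversity table: sample size (haplotypes including
#' heteroplasmic minors), analyzed length, segregating sites S, total
#' mutations eta, distinct haplotypes k, haplotype diversity Hd and
#' nucleotide diversity pi.
#'
#' @inheritParams segregating_sites
#' @export
diversity_summary <- function(aln, gap_policy = c("complete_deletion", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  hs <- collapse_haplotypes(aln, gap_policy)
  seg <- segregating_sites(aln, gap_policy)
  L <- if (gap_policy == "complete_deletion")
    length(gapfree_columns(aln$seq)) else aln_length(aln)
  data.frame(n = n_seq(aln), L_analyzed = L, S = seg$S, eta = seg$eta,
             k = hs$k, Hd = haplotype_diversity(hs),
             pi = nucleotide_diversity(aln, gap_policy))
}
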