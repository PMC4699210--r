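# Tajima's D, Fu's FS and their significance machinery.

#' Tajima's test constants for a sample of size n
#' @param n sample size.
#' @return list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop_mitopop("need n >= 2")
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from_summaries <- function(S, k_hat, const) {
  if (S < 1L) return(NA_real_)
  (k_hat - S / const$a1) / sqrt(const$e1 * S + const$e2 * S * (S - 1))
}

# Beta-approximation p-value (two-sided) for Tajima's D: D rescaled to its
# support [Dmin, Dmax] follows a beta with mean 0 and variance 1.
tajima_beta_p <- function(D, n, const) {
  dmin <- (2 / n - 1 / const$a1) / sqrt(const$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / const$a1) / sqrt(const$e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  if (alpha <= 0 || beta <= 0) return(NA_real_)
  u <- (D - dmin) / (dmax - dmin)
  u <- min(max(u, 0), 1)
  lower <- stats::pbeta(u, beta, alpha)
  min(1, 2 * min(lower, 1 - lower))
}

#' Tajima's D from an alignment
#'
#' D = (k_hat - S/a1) / sqrt(e1 S + e2 S (S - 1)) with k_hat the mean
#' pairwise difference count; a negative D reflects an excess of rare
#' variants (expansion or purifying selection), a positive D an excess of
#' intermediate frequencies. Significance is assessed by Tajima's beta
#' approximation (`p_beta`); a coalescent-simulation p can be added with
#' [coalescent_null()].
#'
#' @param aln [mito_alignment()]
#' @param gap_policy gap handling (see [segregating_sites()]).
#' @return list: `D`, `p_beta`, `n`, `S`, `eta`, `k_hat`, `constants`;
#'   S = 0 yields `D = NA` (not applicable, never reported as 0).
#' @export
tajimas_d <- function(aln, gap_policy = "complete_deletion") {
  n <- n_seq(aln)
  if (n < 4L) stop_mitopop("Tajima's D needs n >= 4")
  seg <- segregating_sites(aln, gap_policy)
  d <- pairwise_diffs(aln$seq, gap_policy)
  k_hat <- mean(d[upper.tri(d)])
  const <- tajima_constants(n)
  if (seg$S == 0L)
    return(list(D = NA_real_, p_beta = NA_real_, n = n, S = 0L,
                eta = seg$eta, k_hat = k_hat, constants = const))
  D <- tajima_d_from_summaries(seg$S, k_hat, const)
  list(D = D, p_beta = tajima_beta_p(D, n, const), n = n, S = seg$S,
       eta = seg$eta, k_hat = k_hat, constants = const)
}

# log unsigned Stirling numbers of the first kind, row n: log |s(n, k)|,
# k = 1..n. All recurrence terms are positive, so log-space accumulation is
# numerically stable for the sample sizes used here.
log_stirling_row <- function(n) {
  row <- 0   # n = 1: |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in 1:(n - 1L)) {
    prev <- c(-Inf, row, -Inf)     # pad k = 0 and k = m+1
    new <- numeric(m + 1L)
    for (k in 1:(m + 1L)) {
      t1 <- log(m) + prev[k + 1L]  # m * |s(m, k)|
      t2 <- prev[k]                # |s(m, k-1)|
      mx <- max(t1, t2)
      new[k] <- if (is.infinite(mx)) -Inf else mx + log(exp(t1 - mx) + exp(t2 - mx))
    }
    row <- new
  }
  row
}

fu_fs_from_summaries <- function(n, theta, k_obs, lst = log_stirling_row(n)) {
  if (theta <= 0) return(NA_real_)
  lpoch <- sum(log(theta + 0:(n - 1)))
  lp <- lst + (1:n) * log(theta) - lpoch
  sprime <- sum(exp(lp[k_obs:n]))
  sprime <- min(max(sprime, 0), 1)
  if (k_obs <= 1L || sprime >= 1 - 1e-14 || sprime <= 0) return(NA_real_)
  log(sprime / (1 - sprime))
}

#' Fu's FS from an alignment
#'
#' With theta estimated by the mean pairwise difference count, S' is the
#' Ewens-sampling probability of observing at least the sampled number of
#' distinct haplotypes; FS = ln(S'/(1 - S')). Strongly negative values
#' indicate an excess of haplotypes relative to neutrality (expansion or
#' hitchhiking).
#'
#' @inheritParams tajimas_d
#' @return list: `FS`, `S_prime`, `n`, `k_hat`, `k_obs`; `k_hat = 0` or a
#'   single haplotype yields not-applicable (`NA`).
#' @export
fus_fs <- function(aln, gap_policy = "complete_deletion") {
  n <- n_seq(aln)
  if (n < 3L) stop_mitopop("Fu's FS needs n >= 3")
  d <- pairwise_diffs(aln$seq, gap_policy)
  k_hat <- mean(d[upper.tri(d)])
  hs <- collapse_haplotypes(
    structure(list(seq = apply_gap_policy(aln$seq, gap_policy),
                   meta = aln$meta), class = "mito_alignment"),
    "pairwise")
  k_obs <- hs$k
  lst <- log_stirling_row(n)
  lpoch <- if (k_hat > 0) sum(log(k_hat + 0:(n - 1))) else NA
  sprime <- if (k_hat > 0)
    min(max(sum(exp(lst + (1:n) * log(k_hat) - lpoch)[k_obs:n]), 0), 1)
  else NA_real_
  FS <- fu_fs_from_summaries(n, k_hat, k_obs, lst)
  list(FS = FS, S_prime = sprime, n = n, k_hat = k_hat, k_obs = k_obs)
}

#' Sliding-window Tajima's D scan
#'
#' Computes D on each full window of `window` columns advanced by `step`;
#' truncated terminal windows are dropped and windows with S < `min_S` are
#' marked skipped. P-values are the raw beta-approximation values, without
#' multiple-testing correction.
#'
#' @inheritParams tajimas_d
#' @param window,step window length and step in alignment columns.
#' @param min_S minimum segregating sites for a window to be scored.
#' @return data.frame: `start`, `end`, `S`, `D`, `p_beta`, `skipped`.
#' @export
sliding_window_d <- function(aln, window = 100L, step = 25L, min_S = 1L,
                             gap_policy = "complete_deletion") {
  L <- aln_length(aln)
  if (L < window) stop_mitopop("alignment shorter than one window")
  starts <- seq(1L, L - window + 1L, by = step)
  rows <- lapply(starts, function(s) {
    sub <- extract_region(structure(aln, class = "mito_alignment"),
                          region_spec("w", s, s + window - 1L))
    seg <- segregating_sites(sub, gap_policy)
    if (seg$S < min_S)
      return(data.frame(start = s, end = s + window - 1L, S = seg$S,
                        D = NA_real_, p_beta = NA_real_, skipped = TRUE))
    td <- tajimas_d(sub, gap_policy)
    data.frame(start = s, end = s + window - 1L, S = td$S, D = td$D,
               p_beta = td$p_beta, skipped = FALSE)
  })
  do.call(rbind, rows)
}

#' Tajima's relative rate test
#'
#' Counts sites where sequence A alone differs from the outgroup (m_a) and
#' where B alone differs (m_b); chi2 = (m_a - m_b)^2/(m_a + m_b) on 1 df
#' tests rate equality of the two lineages.
#'
#' @param seq_a,seq_b,outgroup aligned sequences (strings or character
#'   vectors of equal length).
#' @return list: `m_a`, `m_b`, `chi2`, `p` (`NA` when m_a + m_b = 0).
#' @export
relative_rate_test <- function(seq_a, seq_b, outgroup) {
  a <- as_ref_vector(seq_a); b <- as_ref_vector(seq_b)
  o <- as_ref_vector(outgroup)
  if (length(a) != length(b) || length(b) != length(o))
    stop_mitopop("sequences must be aligned to equal length")
  ok <- a %in% BASES & b %in% BASES & o %in% BASES
  m_a <- sum(ok & a != o & b == o)
  m_b <- sum(ok & b != o & a == o)
  if (m_a + m_b == 0L)
    return(list(m_a = m_a, m_b = m_b, chi2 = NA_real_, p = NA_real_))
  chi2 <- (m_a - m_b)^2 / (m_a + m_b)
  list(m_a = m_a, m_b = m_b, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
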