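# Mismatch distributions: observed pairwise-difference spectra, the
# equilibrium (constant-size) expectation, the Rogers-Harpending sudden
# growth-decline expectation, and least-squares model fitting.

#' Observed mismatch distribution
#'
#' Relative frequency of pairwise difference counts over all C(n,2)
#' sequence pairs.
#'
#' @param aln [mito_alignment()]
#' @param gap_policy gap handling for difference counts.
#' @param i_max report the distribution up to this difference count
#'   (default: observed maximum).
#' @return data.frame: `differences` (0..i_max), `frequency`; attribute
#'   `n_pairs`.
#' @export
mismatch_observed <- function(aln, gap_policy = "complete_deletion",
                              i_max = NULL) {
  if (n_seq(aln) < 2L) stop_mitopop("need n >= 2")
  d <- pairwise_diffs(aln$seq, gap_policy)
  v <- d[upper.tri(d)]
  if (is.null(i_max)) i_max <- max(v)
  freq <- tabulate(pmin(v, i_max) + 1L, i_max + 1L) / length(v)
  out <- data.frame(differences = 0:i_max, frequency = freq)
  attr(out, "n_pairs") <- length(v)
  out
}

#' Equilibrium mismatch curve for a constant-size population
#'
#' F_i = theta^i / (1 + theta)^(i+1), the geometric distribution of
#' pairwise differences under the infinite-sites constant-size coalescent.
#'
#' @param theta scaled population parameter (mean pairwise differences).
#' @param i_max last difference count reported.
#' @export
mismatch_expected_constant <- function(theta, i_max) {
  if (theta < 0) stop_mitopop("theta must be >= 0")
  i <- 0:i_max
  if (theta == 0) return(as.numeric(i == 0L))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Sudden growth-decline mismatch curve (Rogers-Harpending)
#'
#' The expected mismatch distribution for a population at equilibrium theta0
#' that changed suddenly to theta1 at time tau (in mutational units 2ut)
#' before the present:
#' F_i = Fhat_i(theta1) + exp(-tau (theta1 + 1)/theta1) *
#'       sum_{j<=i} tau^j/j! (Fhat_{i-j}(theta0) - Fhat_{i-j}(theta1)).
#' Reduces to the equilibrium curve of theta0 at tau = 0 and of theta1 as
#' tau grows large; covers both growth (theta1 > theta0) and decline.
#'
#' @param theta0,theta1 pre- and post-change population parameters.
#' @param tau time since the size change in 2ut units.
#' @param i_max last difference count reported.
#' @export
mismatch_expected_expansion <- function(theta0, theta1, tau, i_max) {
  if (theta0 < 0 || theta1 < 0 || tau < 0) stop_mitopop("parameters must be >= 0")
  f1 <- mismatch_expected_constant(theta1, i_max)
  if (tau == 0) return(mismatch_expected_constant(theta0, i_max))
  if (theta1 == 0) return(f1)
  f0 <- mismatch_expected_constant(theta0, i_max)
  decay <- exp(-tau * (theta1 + 1) / theta1)
  if (decay == 0) return(f1)
  pois <- exp((0:i_max) * log(tau) - lgamma((0:i_max) + 1))
  conv <- vapply(0:i_max, function(i) {
    j <- 0:i
    sum(pois[j + 1L] * (f0[i - j + 1L] - f1[i - j + 1L]))
  }, 1)
  f1 + decay * conv
}

# count well-separated modes of a mismatch distribution: local maxima of
# the lightly smoothed curve, tall enough, at least min_separation apart
# with a real valley between them.
count_mismatch_modes <- function(frequency, min_separation = 50L,
                                 min_height_frac = 0.05,
                                 valley_ratio = 0.5) {
  f <- as.numeric(frequency)
  n <- length(f)
  if (n < 3L) return(as.integer(any(f > 0)))
  sm <- stats::filter(c(f[1L], f, f[n]), rep(1 / 3, 3))[2:(n + 1L)]
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  peaks <- peaks[sm[peaks] >= min_height_frac * max(sm)]
  if (!length(peaks)) return(0L)
  accepted <- integer(0)
  for (p in peaks[order(sm[peaks], decreasing = TRUE)]) {
    ok <- TRUE
    for (a in accepted) {
      rng <- sort(c(a, p))
      valley <- min(sm[rng[1L]:rng[2L]])
      if (abs(a - p) < min_separation ||
          valley > valley_ratio * min(sm[a], sm[p])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, p)
  }
  length(accepted)
}

#' Is a mismatch distribution bimodal at deep separation?
#'
#' TRUE when at least two local modes separated by `min_separation`
#' differences (with an intervening valley) exist -- the signature of two
#' deeply diverged lineages in a pooled sample.
#'
#' @param mismatch [mismatch_observed()] result or frequency vector.
#' @param min_separation minimum distance between modes.
#' @export
is_bimodal <- function(mismatch, min_separation = 50L) {
  f <- if (is.data.frame(mismatch)) mismatch$frequency else mismatch
  count_mismatch_modes(f, min_separation) >= 2L
}

#' Does a mismatch distribution retain a high-difference mode?
#'
#' The pooled two-lineage mismatch distribution has a mode at the
#' between-lineage difference scale; per-group distributions lose it. This
#' checks for a local mode at or beyond `min_position` differences.
#'
#' @inheritParams is_bimodal
#' @param min_position smallest difference count that counts as "high".
#' @export
has_high_mode <- function(mismatch, min_position = 100L) {
  f <- if (is.data.frame(mismatch)) mismatch$frequency else as.numeric(mismatch)
  n <- length(f)
  if (n <= min_position) return(FALSE)
  sm <- stats::filter(c(f[1L], f, f[n]), rep(1 / 3, 3))[2:(n + 1L)]
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  any(peaks >= min_position + 1L & sm[peaks] >= 0.05 * max(sm))
}

#' Observed site-frequency spectrum
#'
#' @param aln [mito_alignment()]
#' @param gap_policy gap handling.
#' @return folded SFS: counts of minority-allele multiplicities 1..floor(n/2).
#' @export
site_frequency_spectrum <- function(aln, gap_policy = "complete_deletion") {
  mat <- apply_gap_policy(aln$seq, gap_policy)
  n <- nrow(mat)
  xi <- numeric(n %/% 2L)
  variable <- which(column_allele_counts(mat) > 1L)
  for (j in variable) {
    col <- mat[, j]; col <- col[col != "N"]
    tb <- sort(table(col), decreasing = TRUE)
    for (a in seq_along(tb)[-1L]) {
      m <- min(tb[a], length(col) - tb[a])
      if (m >= 1L) xi[m] <- xi[m] + 1L
    }
  }
  xi
}

folded_constant_sfs <- function(theta, n) {
  i <- seq_len(n %/% 2L)
  theta * (1 / i + 1 / (n - i)) / (1 + (i == n - i))
}

# mean folded SFS under sudden growth-decline, by coalescent simulation
# with a fixed internal stream so the least-squares objective is smooth in
# expectation and reproducible
folded_expansion_sfs <- function(theta0, theta1, tau, n, reps = 100L, seed = 1L) {
  set.seed(as.integer(seed))
  acc <- numeric(n %/% 2L)
  for (r in seq_len(reps)) {
    gen <- sim_genealogy(n, theta1 = theta1, theta0 = theta0, tau = tau)
    counts <- drop_mutations(gen, theta = 1)
    if (!length(counts)) next
    m <- pmin(counts, n - counts)
    m <- m[m >= 1L]
    acc <- acc + tabulate(m, n %/% 2L)
  }
  acc / reps
}

#' Fit demographic models to a mismatch distribution or SFS
#'
#' Nonlinear least squares over the expected mismatch curve (objective
#' "mismatch") or the expected folded site-frequency spectrum (objective
#' "sfs"; the growth-decline expectation is obtained by coalescent
#' simulation at the candidate parameters). Multi-start optimisation with
#' bounds theta in [0, 10 k_hat], tau in [0, 50]; the random starts are
#' supplemented with informed ones placed at the observed wave position.
#' The growth-decline family nests the constant model, so the preferred
#' model is chosen by the lower Gaussian least-squares BIC, which penalises
#' the extra parameters.
#'
#' @param observed [mismatch_observed()] output (or frequency vector) for
#'   the mismatch objective; a folded SFS count vector for "sfs".
#' @param model "constant", "growth_decline" or "both".
#' @param objective "mismatch" or "sfs".
#' @param n sample size (required for "sfs").
#' @param n_starts multi-start count for the 3-parameter model.
#' @param seed integer seed (start points; sfs simulation stream).
#' @param reps_sfs simulation replicates per sfs objective evaluation.
#' @param evidence_threshold BIC margin required to prefer growth-decline
#'   over the nested constant model.
#' @return data.frame of `demographic_fit` rows: model, theta0, theta1,
#'   tau, SSE, BIC, preferred.
#' @export
fit_demographic_model <- function(observed, model = c("both", "constant",
                                                      "growth_decline"),
                                  objective = c("mismatch", "sfs"),
                                  n = NULL, n_starts = 10L, seed = 1L,
                                  reps_sfs = 100L, evidence_threshold = 15) {
  model <- match.arg(model)
  objective <- match.arg(objective)
  if (objective == "mismatch") {
    f <- if (is.data.frame(observed)) observed$frequency else as.numeric(observed)
    if (!length(f) || all(f == 0)) stop_mitopop("empty observed distribution")
    f <- c(f, numeric(5L))               # tail room beyond observed maximum
    i_max <- length(f) - 1L
    k_hat <- sum((0:i_max) * f) / sum(f)
    sse_const <- function(th) sum((f - mismatch_expected_constant(th, i_max))^2)
    sse_exp <- function(p) sum((f - mismatch_expected_expansion(
      p[1L], p[2L], p[3L], i_max))^2)
    m_pts <- length(f)
  } else {
    if (is.null(n)) stop_mitopop("objective 'sfs' needs the sample size n")
    xi <- as.numeric(observed)
    k_hat <- max(sum(xi) / sum(1 / seq_len(max(n - 1L, 1L))), 1e-3)
    sse_const <- function(th) sum((xi - folded_constant_sfs(th, n))^2)
    sse_exp <- function(p) sum((xi - folded_expansion_sfs(
      p[1L], p[2L], p[3L], n, reps = reps_sfs,
      seed = derive_seed(seed, 99L)))^2)
    m_pts <- length(xi)
  }
  hi <- max(10 * k_hat, 1)
  out <- list()
  if (model %in% c("both", "constant")) {
    op <- stats::optimize(sse_const, c(0, hi))
    out$constant <- data.frame(model = "constant", theta0 = op$minimum,
                               theta1 = op$minimum, tau = 0,
                               SSE = op$objective,
                               BIC = m_pts * log(op$objective / m_pts + 1e-300) +
                                 log(m_pts))
  }
  if (model %in% c("both", "growth_decline")) {
    set.seed(as.integer(seed))
    wave <- if (objective == "mismatch") max(which.max(f) - 1, 0.5) else k_hat
    starts <- rbind(
      c(0.5, hi, min(wave, 50)),             # strong growth, wave at mode
      c(k_hat, k_hat / 10, min(k_hat, 50)),  # decline
      c(k_hat, k_hat, 1),                    # near-constant
      cbind(stats::runif(n_starts, 0, hi),
            stats::runif(n_starts, 0, hi),
            stats::runif(n_starts, 0, 50)))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      op <- try(stats::optim(starts[s, ], sse_exp, method = "L-BFGS-B",
                             lower = c(0, 1e-6, 0), upper = c(hi, hi, 50)),
                silent = TRUE)
      if (inherits(op, "try-error")) next
      if (is.null(best) || op$value < best$value) best <- op
    }
    if (is.null(best)) stop_mitopop("growth-decline optimisation failed on all starts")
    out$growth_decline <- data.frame(
      model = "growth_decline", theta0 = best$par[1L], theta1 = best$par[2L],
      tau = best$par[3L], SSE = best$value,
      BIC = m_pts * log(best$value / m_pts + 1e-300) + 3 * log(m_pts))
  }
  fits <- do.call(rbind, out)
  if (nrow(fits) == 2L) {
    gd_wins <- (fits$BIC[fits$model == "constant"] -
                fits$BIC[fits$model == "growth_decline"]) > evidence_threshold
    fits$preferred <- if (gd_wins) fits$model == "growth_decline"
                      else fits$model == "constant"
  } else fits$preferred <- TRUE
  rownames(fits) <- NULL
  class(fits) <- c("demographic_fit", "data.frame")
  fits
}
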