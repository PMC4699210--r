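# Kingman coalescent machinery.
#
# Time convention: pairwise coalescence rate 1/theta(s), per-lineage mutation
# rate 1/2 per unit of s. Under constant theta this gives E[pairwise
# differences] = theta and E[S] = theta * sum(1/(1:(n-1))), i.e. the usual
# scaled-mutation parameterisation without carrying N and u separately.
# theta epochs are measured backwards from the present: theta1 applies for
# s < tau, theta0 earlier (sudden growth-decline with change at tau).

#' Simulate one Kingman genealogy as branch segments
#'
#' Each segment is a branch of the genealogy carrying the set of sampled
#' tips that descend from it, plus its length; mutations dropped on a
#' segment are shared by exactly its tip set.
#'
#' @param n sample size (tips).
#' @param theta1 scaled population parameter of the most recent epoch.
#' @param theta0 parameter of the ancestral epoch (defaults to `theta1`,
#'   i.e. constant size).
#' @param tau epoch-change time in mutational units (2ut); ignored when the
#'   two thetas are equal.
#' @param genealogy "kingman" or "star" (all tips joined to the root at the
#'   same depth, the limiting genealogy of a strong sudden expansion).
#' @return list with `tipsets` (list of integer vectors), `lengths`
#'   (numeric), `n`.
#' @export
sim_genealogy <- function(n, theta1 = 1, theta0 = theta1, tau = Inf,
                          genealogy = c("kingman", "star")) {
  genealogy <- match.arg(genealogy)
  n <- check_count(n, "n")
  if (n < 2L) stop_mitopop("need n >= 2 tips")
  if (genealogy == "star") {
    # tip depth = theta1 keeps E[pairwise differences] = theta1, as in the
    # constant-size case; all mutations become singletons
    return(list(tipsets = as.list(seq_len(n)),
                lengths = rep(theta1, n), n = n))
  }
  tips <- as.list(seq_len(n))
  birth <- numeric(n)
  tipsets <- vector("list", 2L * n - 2L)
  lengths <- numeric(2L * n - 2L)
  nseg <- 0L
  t <- 0
  k <- n
  while (k > 1L) {
    # piecewise-exponential waiting time across the epoch boundary
    repeat {
      th <- if (t < tau) theta1 else theta0
      rate <- choose(k, 2) / th
      w <- stats::rexp(1L, rate)
      if (t < tau && t + w > tau) { t <- tau } else { t <- t + w; break }
    }
    pair <- sample.int(k, 2L)
    for (i in pair) {
      nseg <- nseg + 1L
      tipsets[[nseg]] <- tips[[i]]
      lengths[nseg] <- t - birth[i]
    }
    merged <- sort(c(tips[[pair[1L]]], tips[[pair[2L]]]))
    keep <- setdiff(seq_len(k), pair)
    tips <- c(tips[keep], list(merged))
    birth <- c(birth[keep], t)
    k <- k - 1L
  }
  list(tipsets = tipsets[seq_len(nseg)], lengths = lengths[seq_len(nseg)], n = n)
}

#' Drop mutations on a simulated genealogy
#'
#' Infinite-sites mutation placement: either exactly `fixed_S` mutations
#' multinomially by branch length (Hudson's fixed-S scheme) or a Poisson
#' number with rate theta/2 per lineage per unit time.
#'
#' @param gen output of [sim_genealogy()].
#' @param fixed_S exact mutation count, or `NULL`.
#' @param theta scaled mutation parameter when `fixed_S` is `NULL`; for the
#'   two-epoch genealogies of [sim_genealogy()] use `theta = 1` so that the
#'   epoch thetas keep their mismatch-units meaning.
#' @return integer vector of descendant-set sizes, with attribute `tipsets`.
#' @export
drop_mutations <- function(gen, fixed_S = NULL, theta = NULL) {
  L <- sum(gen$lengths)
  if (!is.null(fixed_S)) {
    S <- check_count(fixed_S, "fixed_S")
  } else {
    if (is.null(theta)) stop_mitopop("give fixed_S or theta")
    S <- stats::rpois(1L, theta * L / 2)
  }
  if (S == 0L) {
    out <- integer(0)
    attr(out, "tipsets") <- list()
    return(out)
  }
  seg <- sample.int(length(gen$lengths), S, replace = TRUE, prob = gen$lengths)
  tipsets <- gen$tipsets[seg]
  out <- vapply(tipsets, length, 1L)
  attr(out, "tipsets") <- tipsets
  out
}

# Summary statistics computable directly from mutation descendant sets.
coal_stats <- function(counts, n) {
  S <- length(counts)
  khat <- if (S == 0L) 0 else sum(counts * (n - counts)) / choose(n, 2)
  tipsets <- attr(counts, "tipsets")
  # distinct haplotypes via random hashing of mutation membership
  sig <- numeric(n)
  if (S > 0L) {
    h <- stats::runif(S)
    for (m in seq_len(S)) sig[tipsets[[m]]] <- sig[tipsets[[m]]] + h[m]
  }
  list(S = S, k_hat = khat, k_obs = length(unique(signif(sig, 12))))
}

#' Coalescent null distributions for Tajima's D and Fu's FS
#'
#' Simulates constant-size Kingman genealogies, drops mutations under the
#' chosen conditioning, and returns the simulated statistics together with
#' one-sided p-values for observed values (small D / small FS indicate an
#' excess of rare variants). p-values use the +1 convention (the observed
#' replicate is counted), so p ranges over [1/(reps+1), 1].
#'
#' @param n sample size.
#' @param conditioning list with either `fixed_S` (mutation count) or
#'   `theta`.
#' @param reps replicates (the headline analyses use 16000; calibration
#'   checks use fewer).
#' @param seed integer seed.
#' @param D_obs,FS_obs optional observed statistics to score.
#' @return list with vectors `D`, `FS` and (when observations are given)
#'   `p_coal_D`, `p_coal_FS`.
#' @export
coalescent_null <- function(n, conditioning, reps = 16000L, seed = 1L,
                            D_obs = NULL, FS_obs = NULL) {
  reps <- check_count(reps, "reps")
  if (reps < 100L) stop_mitopop("reps must be >= 100")
  if (n < 4L) stop_mitopop("need n >= 4")
  set.seed(as.integer(seed))
  lst <- log_stirling_row(n)
  const <- tajima_constants(n)
  D <- FS <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    gen <- sim_genealogy(n, theta1 = 1)
    counts <- drop_mutations(gen, fixed_S = conditioning$fixed_S,
                             theta = conditioning$theta)
    st <- coal_stats(counts, n)
    if (st$S > 0L) D[r] <- tajima_d_from_summaries(st$S, st$k_hat, const)
    if (st$k_hat > 0) FS[r] <- fu_fs_from_summaries(n, st$k_hat, st$k_obs, lst)
  }
  out <- list(D = D, FS = FS, reps = reps, seed = seed)
  if (!is.null(D_obs))
    out$p_coal_D <- (1 + sum(D <= D_obs, na.rm = TRUE)) / (sum(!is.na(D)) + 1)
  if (!is.null(FS_obs))
    out$p_coal_FS <- (1 + sum(FS <= FS_obs, na.rm = TRUE)) / (sum(!is.na(FS)) + 1)
  out
}

#' Simulate a pairwise-difference sample under a demographic model
#'
#' Draws one genealogy under constant size or sudden growth-decline and
#' returns the pairwise difference counts of the sample, the raw material of
#' a mismatch distribution.
#'
#' @inheritParams sim_genealogy
#' @return integer matrix (n x n) of pairwise difference counts.
#' @export
sim_pairwise_differences <- function(n, theta1, theta0 = theta1, tau = Inf) {
  gen <- sim_genealogy(n, theta1 = theta1, theta0 = theta0, tau = tau)
  counts <- drop_mutations(gen, theta = 1)
  tipsets <- attr(counts, "tipsets")
  d <- matrix(0L, n, n)
  for (ts in tipsets) {
    z <- integer(n); z[ts] <- 1L
    d <- d + outer(z, 1L - z) + outer(1L - z, z)
  }
  d
}
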