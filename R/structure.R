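# Between-group differentiation: Tamura-Nei (1993) distances, AMOVA-based
# PhiST with label permutation, Nei's dXY, and the Hudson-Boos-Kaplan
# permutation tests of subdivision (K_S, K_S*, Z, Z*). Permutations move
# individuals, not haplotypes: a heteroplasmic bird's two haplotypes always
# carry the same label.

tn93_core <- function(gA, gC, gG, gT, P1, P2, Q, pdist) {
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  # a transition class with no possible changes (k = 0) and none observed
  # contributes nothing; otherwise a non-positive log argument = saturation
  z1 <- !is.finite(w1) & P1 == 0
  z2 <- !is.finite(w2) & P2 == 0
  ok1 <- z1 | (is.finite(w1) & w1 > 0)
  ok2 <- z2 | (is.finite(w2) & w2 > 0)
  ok3 <- is.finite(w3) & w3 > 0
  t1 <- ifelse(z1, 0, -k1 * log(pmax(w1, 1e-300)))
  t2 <- ifelse(z2, 0, -k2 * log(pmax(w2, 1e-300)))
  t3 <- -k3 * log(pmax(w3, 1e-300))
  d <- t1 + t2 + t3
  saturated <- !(ok1 & ok2 & ok3) | !is.finite(d)
  d[saturated] <- pdist[saturated]
  attr(d, "saturated") <- saturated
  d
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Uses the observed base frequencies of the pair's comparable (both A/C/G/T)
#' sites and the two transition classes (A<->G, C<->T). When a logarithm
#' argument is non-positive (saturation) the uncorrected p-distance is
#' returned with a warning.
#'
#' @param seq_a,seq_b equal-length sequences (strings or character vectors).
#' @return distance in substitutions per site.
#' @export
tn93_distance <- function(seq_a, seq_b) {
  a <- as_ref_vector(seq_a); b <- as_ref_vector(seq_b)
  if (length(a) != length(b)) stop_mitopop("sequences differ in length")
  ok <- a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n == 0L) stop_mitopop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  cnt <- (table(factor(a, BASES)) + table(factor(b, BASES))) / (2 * n)
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / n
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / n
  diffs <- sum(a != b) / n
  Q <- diffs - P1 - P2
  d <- tn93_core(cnt["A"], cnt["C"], cnt["G"], cnt["T"], P1, P2, Q, diffs)
  if (attr(d, "saturated")[1L])
    warning("TN93 saturated; returning p-distance")
  as.numeric(d)
}

# All-pairs TN93 distance matrix via matrix products.
tn93_matrix <- function(mat) {
  n <- nrow(mat)
  M <- lapply(BASES, function(b) (mat == b) * 1)
  names(M) <- BASES
  ok <- Reduce(`+`, M)
  comp <- tcrossprod(ok)
  counts <- lapply(BASES, function(b)
    tcrossprod(M[[b]], ok) + tcrossprod(ok, M[[b]]))
  names(counts) <- BASES
  matches <- Reduce(`+`, lapply(BASES, function(b) tcrossprod(M[[b]])))
  P1n <- tcrossprod(M$A, M$G) + tcrossprod(M$G, M$A)
  P2n <- tcrossprod(M$C, M$T) + tcrossprod(M$T, M$C)
  diffs <- comp - matches
  if (any(comp[upper.tri(comp)] == 0))
    stop_mitopop("a sequence pair has no comparable sites")
  P1 <- P1n / comp; P2 <- P2n / comp
  pd <- diffs / comp
  Q <- pd - P1 - P2
  gA <- counts$A / (2 * comp); gC <- counts$C / (2 * comp)
  gG <- counts$G / (2 * comp); gT <- counts$T / (2 * comp)
  d <- tn93_core(gA, gC, gG, gT, P1, P2, Q, pd)
  sat <- attr(d, "saturated")
  d <- matrix(d, n, n, dimnames = list(rownames(mat), rownames(mat)))
  diag(d) <- 0
  if (any(sat[upper.tri(sat)]))
    warning("TN93 saturated for some pairs; p-distance used there")
  d
}

# permutation machinery: individuals carry their 1-2 haplotype rows
individual_rows <- function(meta) {
  split(seq_len(nrow(meta)), meta$individual)
}

row_groups <- function(meta, partition) {
  g <- partition[meta$individual]
  if (any(is.na(g))) stop_mitopop("partition is missing individuals")
  g
}

#' AMOVA-based PhiST between two groups with permutation test
#'
#' Squared TN93 distances enter the sums of squares (the distance-matrix
#' AMOVA convention); PhiST = sigma2_among / (sigma2_among + sigma2_within).
#' Significance is the proportion of individual-label permutations with
#' PhiST at least the observed value, observed included (+1 convention).
#'
#' @param aln [mito_alignment()]
#' @param partition named vector individual -> group (two groups, each with
#'   >= 2 sequences).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param squared use squared distances in the SSDs (default).
#' @return list: `phi_st`, `p_value`, `sigma_among`, `sigma_within`,
#'   `n_perm`, `seed`.
#' @export
pairwise_phist <- function(aln, partition, n_perm = 1000L, seed = 1L,
                           squared = TRUE) {
  d <- tn93_matrix(aln$seq)
  D2 <- if (squared) d^2 else d
  g <- row_groups(aln$meta, partition)
  phi_from_rows <- function(g) {
    n <- length(g)
    grps <- sort(unique(g))
    if (length(grps) != 2L) stop_mitopop("need exactly two groups")
    ng <- tabulate(factor(g, grps))
    if (any(ng < 2L)) stop_mitopop("each group needs >= 2 sequences")
    ssd_tot <- sum(D2[upper.tri(D2)]) / n
    ssd_w <- 0
    for (gr in grps) {
      x <- as.numeric(g == gr)
      ssd_w <- ssd_w + (x %*% D2 %*% x)[1L] / (2 * sum(x))
    }
    ssd_a <- ssd_tot - ssd_w
    ms_w <- ssd_w / (n - 2)              # sigma2 within
    n_c <- n - sum(ng^2) / n             # / (G - 1) with G = 2
    s2a <- (ssd_a / 1 - ms_w) / n_c
    list(phi = s2a / (s2a + ms_w), s2a = s2a, s2w = ms_w)
  }
  ob <- phi_from_rows(g)
  obs <- ob$phi
  set.seed(as.integer(seed))
  inds <- names(partition)
  ge <- sum(vapply(seq_len(n_perm), function(i) {
    perm <- stats::setNames(sample(partition), inds)
    phi_from_rows(row_groups(aln$meta, perm))$phi >= obs
  }, NA))
  list(phi_st = obs, p_value = (1 + ge) / (n_perm + 1),
       sigma_among = ob$s2a, sigma_within = ob$s2w,
       n_perm = n_perm, seed = seed)
}

#' Average between-group substitutions per site (Nei's dXY)
#'
#' Mean over all between-group sequence pairs of the per-site difference
#' fraction (uncorrected), complete-deletion gap handling by default.
#'
#' @inheritParams pairwise_phist
#' @param gap_policy gap handling.
#' @export
dxy <- function(aln, partition, gap_policy = "complete_deletion") {
  g <- row_groups(aln$meta, partition)
  grps <- sort(unique(g))
  if (length(grps) != 2L) stop_mitopop("need exactly two groups")
  d <- pairwise_diffs(aln$seq, gap_policy)
  i1 <- which(g == grps[1L]); i2 <- which(g == grps[2L])
  if (gap_policy == "complete_deletion") {
    L <- attr(d, "L_analyzed")
    mean(d[i1, i2]) / L
  } else {
    comp <- attr(d, "comparable")
    mean(d[i1, i2] / comp[i1, i2])
  }
}

#' Hudson-Boos-Kaplan tests of population subdivision
#'
#' With K_ij the pairwise difference counts: K_S is the weighted mean of
#' within-group average pairwise differences (weights n_g(n_g-1)); K_S* the
#' same on ln(1 + K_ij); Z the weighted mean of within-group mean ranks of
#' K_ij among all pairs, Z* on ln(rank). Small values indicate subdivision;
#' significance is Pr(statistic <= observed) over individual-label
#' permutations (+1 convention).
#'
#' @inheritParams pairwise_phist
#' @param gap_policy gap handling for difference counts.
#' @return list with `K_S`, `K_S_star`, `Z`, `Z_star`, their p-values,
#'   `n_perm`, `seed`.
#' @export
hudson_test_suite <- function(aln, partition, n_perm = 1000L, seed = 1L,
                              gap_policy = "complete_deletion") {
  K <- pairwise_diffs(aln$seq, gap_policy)
  n <- nrow(K)
  LK <- log1p(K)
  ut <- upper.tri(K)
  R <- matrix(0, n, n)
  R[ut] <- rank(K[ut])
  R <- R + t(R)
  LR <- matrix(0, n, n)
  LR[ut] <- log(rank(K[ut]))
  LR <- LR + t(LR)
  g_obs <- row_groups(aln$meta, partition)
  grps <- sort(unique(g_obs))
  if (length(grps) != 2L) stop_mitopop("need exactly two groups")
  stats_from_rows <- function(g) {
    ng <- vapply(grps, function(gr) sum(g == gr), 1)
    if (any(ng < 2)) stop_mitopop("each group needs >= 2 sequences")
    w <- ng * (ng - 1); w <- w / sum(w)
    one <- function(M) {
      means <- vapply(seq_along(grps), function(k) {
        x <- as.numeric(g == grps[k])
        (x %*% M %*% x)[1L] / (ng[k] * (ng[k] - 1))
      }, 1)
      sum(w * means)
    }
    c(K_S = one(K), K_S_star = one(LK), Z = one(R), Z_star = one(LR))
  }
  obs <- stats_from_rows(g_obs)
  set.seed(as.integer(seed))
  inds <- names(partition)
  le <- numeric(4)
  for (i in seq_len(n_perm)) {
    perm <- stats::setNames(sample(partition), inds)
    le <- le + (stats_from_rows(row_groups(aln$meta, perm)) <= obs)
  }
  p <- (1 + le) / (n_perm + 1)
  list(K_S = obs[["K_S"]], K_S_star = obs[["K_S_star"]],
       Z = obs[["Z"]], Z_star = obs[["Z_star"]],
       p_K_S = p[[1]], p_K_S_star = p[[2]], p_Z = p[[3]], p_Z_star = p[[4]],
       n_perm = n_perm, seed = seed)
}
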