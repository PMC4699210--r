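# Brute-force oracles: deliberately plain loop implementations, independent
# of the package's vectorised code paths.

rand_aln <- function(n, L, n_var = max(2L, L %/% 10L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, each = n), n, L,
                dimnames = list(paste0("s", seq_len(n)), NULL))
  for (j in sample.int(L, min(n_var, L))) {
    carriers <- sample.int(n, sample.int(n - 1L, 1L))
    mat[carriers, j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1L)
  }
  mito_alignment(mat)
}

bf_pair_diffs <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cnt <- 0
    for (s in seq_len(ncol(mat))) {
      a <- mat[i, s]; b <- mat[j, s]
      if (a != "N" && b != "N" && a != "-" && b != "-" && a != b)
        cnt <- cnt + 1
    }
    d[i, j] <- d[j, i] <- cnt
  }
  d
}

bf_pi <- function(mat) {
  keep <- c()
  for (s in seq_len(ncol(mat))) if (!any(mat[, s] == "-")) keep <- c(keep, s)
  m2 <- mat[, keep, drop = FALSE]
  d <- bf_pair_diffs(m2)
  n <- nrow(m2)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) { tot <- tot + d[i, j]; np <- np + 1 }
  tot / np / ncol(m2)
}

bf_S_eta <- function(mat) {
  S <- 0; eta <- 0
  for (s in seq_len(ncol(mat))) {
    if (any(mat[, s] == "-")) next
    al <- unique(mat[, s]); al <- al[al != "N"]
    if (length(al) >= 2) { S <- S + 1; eta <- eta + length(al) - 1 }
  }
  c(S = S, eta = eta)
}

bf_hd <- function(mat) {
  keep <- c()
  for (s in seq_len(ncol(mat))) if (!any(mat[, s] == "-")) keep <- c(keep, s)
  keys <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  n <- length(keys)
  p <- as.numeric(table(keys)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

bf_tajima_d <- function(mat) {
  n <- nrow(mat)
  se <- bf_S_eta(mat)
  S <- se[["S"]]
  if (S == 0) return(NA_real_)
  d <- bf_pair_diffs(mat[, colSums(mat == "-") == 0, drop = FALSE])
  khat <- mean(d[upper.tri(d)])
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact unsigned Stirling numbers of the first kind for small n
bf_stirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (m in 1:n) for (k in 1:m)
    s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
  s[n + 1, 2:(n + 1)]
}

bf_fu_fs <- function(mat) {
  n <- nrow(mat)
  keep <- colSums(mat == "-") == 0
  d <- bf_pair_diffs(mat[, keep, drop = FALSE])
  theta <- mean(d[upper.tri(d)])
  if (theta <= 0) return(NA_real_)
  keys <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  k_obs <- length(unique(keys))
  if (k_obs <= 1) return(NA_real_)
  st <- bf_stirling(n)
  denom <- prod(theta + 0:(n - 1))
  pk <- st * theta^(1:n) / denom
  sp <- sum(pk[k_obs:n])
  if (sp >= 1 - 1e-14 || sp <= 0) return(NA_real_)
  log(sp / (1 - sp))
}

bf_phist <- function(d, groups) {
  n <- length(groups)
  grps <- sort(unique(groups))
  d2 <- d^2
  ssd_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ssd_tot <- ssd_tot + d2[i, j]
  ssd_tot <- ssd_tot / n
  ssd_w <- 0
  for (g in grps) {
    idx <- which(groups == g)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
    ssd_w <- ssd_w + acc / length(idx)
  }
  ng <- sapply(grps, function(g) sum(groups == g))
  ms_w <- ssd_w / (n - length(grps))
  nc <- (n - sum(ng^2) / n) / (length(grps) - 1)
  s2a <- ((ssd_tot - ssd_w) / (length(grps) - 1) - ms_w) / nc
  s2a / (s2a + ms_w)
}

bf_dxy <- function(mat, groups) {
  keep <- colSums(mat == "-") == 0
  m2 <- mat[, keep, drop = FALSE]
  d <- bf_pair_diffs(m2)
  grps <- sort(unique(groups))
  i1 <- which(groups == grps[1]); i2 <- which(groups == grps[2])
  tot <- 0; np <- 0
  for (i in i1) for (j in i2) { tot <- tot + d[i, j]; np <- np + 1 }
  tot / np / ncol(m2)
}

# two-tailed Fisher exact p by hypergeometric enumeration
bf_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- sapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimum spanning tree cost by exhaustive enumeration (k <= 7)
bf_mst_cost <- function(D) {
  k <- nrow(D)
  if (k <= 1) return(0)
  pairs <- t(utils::combn(k, 2))
  best <- Inf
  for (sel in utils::combn(nrow(pairs), k - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    comp <- seq_len(k)
    for (r in seq_len(nrow(e))) {
      a <- comp[e[r, 1]]; b <- comp[e[r, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1) {
      cost <- sum(D[e])
      if (cost < best) best <- cost
    }
  }
  best
}

# small synthetic scenario used by several test files
small_params <- function(seed = 1, ...) {
  defaults <- list(genome_length = 2500L, n_group1 = 8L, n_group2 = 5L,
                   n_diagnostic = 12L, n_diagnostic_indels = 2L,
                   theta_within = 3, coverage_mean = 150, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

group_subalignment <- function(aln, individuals) {
  keep <- aln$meta$individual %in% individuals
  structure(list(seq = aln$seq[keep, , drop = FALSE],
                 meta = aln$meta[keep, , drop = FALSE]),
            class = "mito_alignment")
}
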