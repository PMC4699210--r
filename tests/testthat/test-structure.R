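test_that("TN93 distance agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(51)
  for (r in 1:10) {
    L <- 400L
    x <- sample(c("A", "C", "G", "T"), L, TRUE)
    y <- x
    idx <- sample(L, 25)
    y[idx] <- vapply(x[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    d_pkg <- tn93_distance(x, y)
    d_ape <- as.numeric(ape::dist.dna(
      ape::as.DNAbin(matrix(tolower(rbind(x, y)), 2, L)), model = "TN93"))
    expect_equal(d_pkg, d_ape, tolerance = 1e-10)
  }
  expect_equal(tn93_distance("ACGT", "ACGT"), 0)
})

test_that("TN93 reduces to Jukes-Cantor under symmetric change patterns", {
  # equal base composition; one substitution of every unordered type
  x <- c("A","G","C","T","A","C","G","T","A","T","C","G",
         rep(c("A","C","G","T"), 27))
  y <- c("G","A","T","C","C","A","T","G","T","A","G","C",
         rep(c("A","C","G","T"), 27))
  p <- mean(x != y)
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(tn93_distance(x, y), jc, tolerance = 1e-10)
})

test_that("saturated pairs fall back to the p-distance with a warning", {
  set.seed(53)
  x <- sample(c("A", "C", "G", "T"), 100, TRUE)
  y <- vapply(x, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  expect_warning(d <- tn93_distance(x, y), "saturated")
  expect_equal(d, mean(x != y))
  expect_error(tn93_distance("NNN", "ACG"), "comparable")
})

test_that("PhiST is exactly 1 with zero within-group variance", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 93), rep("G", 7)), collapse = "")
  aln <- mito_alignment(c(a = s1, b = s1, c = s2, d = s2))
  part <- stats::setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  ph <- suppressWarnings(pairwise_phist(aln, part, n_perm = 50, seed = 1))
  expect_equal(ph$phi_st, 1)
  expect_gte(ph$p_value, 1 / 51)
  expect_lte(ph$p_value, 1)
})

test_that("PhiST matches a brute-force AMOVA on small samples", {
  set.seed(55)
  for (r in 1:20) {
    n <- sample(4:8, 1)
    aln <- rand_aln(n, 60, n_var = sample(4:9, 1))
    groups <- c(rep(1, 2), rep(2, n - 2))[sample(n)]
    while (min(table(groups)) < 2) groups <- sample(c(1, 2), n, TRUE)
    part <- stats::setNames(groups, rownames(aln$seq))
    d <- suppressWarnings(mitopop:::tn93_matrix(aln$seq))
    expect_equal(
      suppressWarnings(pairwise_phist(aln, part, n_perm = 10, seed = 1))$phi_st,
      bf_phist(d, groups), tolerance = 1e-10)
    expect_equal(dxy(aln, part), bf_dxy(aln$seq, groups), tolerance = 1e-12)
  }
})

test_that("dxy reproduces direct pair values and exceeds within-group pi", {
  s1 <- paste(rep("A", 1000), collapse = "")
  s2 <- paste(c(rep("A", 993), rep("T", 7)), collapse = "")
  aln <- mito_alignment(c(a = s1, b = s2))
  part <- stats::setNames(c(1, 2), c("a", "b"))
  expect_equal(dxy(aln, part), 0.007)
  p <- small_params(seed = 57)
  tr <- simulate_two_lineage_population(p)
  d <- dxy(tr$alignment, tr$group_labels)
  within_pi <- mean(c(
    nucleotide_diversity(group_subalignment(tr$alignment,
      names(tr$group_labels)[tr$group_labels == 1])),
    nucleotide_diversity(group_subalignment(tr$alignment,
      names(tr$group_labels)[tr$group_labels == 2]))))
  expect_gt(d, within_pi)
})

test_that("Hudson statistics behave at the extremes and are deterministic", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 90), rep("G", 10)), collapse = "")
  aln <- mito_alignment(c(a = s1, b = s1, c = s1, d = s2, e = s2, f = s2))
  part <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  h <- hudson_test_suite(aln, part, n_perm = 200, seed = 1)
  expect_equal(h$K_S, 0)       # no within-group variation at all
  expect_gte(h$p_K_S, 1 / 201)
  h2 <- hudson_test_suite(aln, part, n_perm = 200, seed = 1)
  expect_identical(h[c("p_K_S", "p_K_S_star", "p_Z", "p_Z_star")],
                   h2[c("p_K_S", "p_K_S_star", "p_Z", "p_Z_star")])
  expect_error(hudson_test_suite(aln, stats::setNames(c(1, 2, 2, 2, 2, 2),
                                                      letters[1:6]), 10, 1),
               ">= 2")
})

test_that("strong subdivision gives the minimal permutation p-values", {
  p <- small_params(seed = 59)
  tr <- simulate_two_lineage_population(p)
  h <- hudson_test_suite(tr$alignment, tr$group_labels, n_perm = 99, seed = 2)
  expect_equal(h$p_K_S, 1 / 100)
  expect_equal(h$p_Z, 1 / 100)
  ph <- pairwise_phist(tr$alignment, tr$group_labels, n_perm = 99, seed = 2)
  expect_equal(ph$p_value, 1 / 100)
  expect_gt(ph$phi_st, 0.5)
})

test_that("heteroplasmic minors permute jointly with their individual", {
  p <- small_params(seed = 61, het_rate = 1, n_group1 = 4L, n_group2 = 4L)
  tr <- inject_heteroplasmy(simulate_two_lineage_population(p))
  # runs without error despite 1-2 haplotypes per individual, and the
  # partition has one label per individual, not per haplotype
  ph <- pairwise_phist(tr$alignment, tr$group_labels, n_perm = 50, seed = 3)
  expect_true(is.finite(ph$phi_st))
  expect_equal(length(tr$group_labels),
               length(unique(tr$alignment$meta$individual)))
})
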