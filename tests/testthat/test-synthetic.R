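test_that("zero within-group mutation leaves only diagnostic variation", {
  p <- small_params(seed = 5, theta_within = 0, n_diagnostic = 5,
                    n_diagnostic_indels = 0)
  tr <- simulate_two_lineage_population(p)
  g1 <- tr$alignment$seq[tr$alignment$meta$group == 1, ]
  g2 <- tr$alignment$seq[tr$alignment$meta$group == 2, ]
  expect_true(all(g1 == rep(g1[1, ], each = nrow(g1))))
  expect_true(all(g2 == rep(g2[1, ], each = nrow(g2))))
  expect_equal(unname(bf_S_eta(tr$alignment$seq)[["S"]]), 5)
})

test_that("diagnostic sites are disjoint and counted exactly, minors included", {
  p <- small_params(seed = 2)
  tr0 <- simulate_two_lineage_population(p)
  tr <- inject_heteroplasmy(tr0)
  dg <- count_diagnostic_mutations(tr$alignment, tr$group_labels)
  expect_equal(dg$n_sites, 12L)
  expect_equal(dg$n_snv, 10L)
  expect_equal(dg$n_indel, 2L)
  # injections land only on previously invariant positions
  expect_length(intersect(tr$het_truth$position,
                          tr0$truth_variants$position), 0L)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- inject_heteroplasmy(simulate_two_lineage_population(small_params(seed = 7)))
  b <- inject_heteroplasmy(simulate_two_lineage_population(small_params(seed = 7)))
  expect_identical(a$alignment$seq, b$alignment$seq)
  expect_identical(a$het_truth, b$het_truth)
  pa <- simulate_pileups(a)
  pb <- simulate_pileups(b)
  expect_identical(pa, pb)
  c_ <- simulate_two_lineage_population(small_params(seed = 8))
  expect_false(identical(a$alignment$seq, c_$alignment$seq))
})

test_that("heteroplasmy injection respects rate extremes and records truth", {
  p0 <- small_params(seed = 3, het_rate = 0)
  tr0 <- simulate_two_lineage_population(p0)
  tr0b <- inject_heteroplasmy(tr0)
  expect_equal(nrow(tr0b$het_truth), 0L)
  expect_identical(tr0b$alignment$seq, tr0$alignment$seq)

  p1 <- small_params(seed = 3, het_rate = 1, max_het_sites_per_individual = 1L,
                     n_group1 = 3L, n_group2 = 2L)
  tr1 <- inject_heteroplasmy(simulate_two_lineage_population(p1))
  expect_equal(nrow(tr1$het_truth), 5L)
  expect_equal(sum(tr1$alignment$meta$is_minor), 5L)
  # each minor differs from its major exactly at its het sites
  for (ind in tr1$het_truth$individual) {
    d <- which(tr1$alignment$seq[ind, ] != tr1$alignment$seq[paste0(ind, "m"), ])
    expect_equal(sort(d), sort(tr1$het_truth$position[tr1$het_truth$individual == ind]))
  }
})

test_that("heteroplasmy rate matches its Bernoulli target across seeds", {
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    p <- small_params(seed = 400 + s, genome_length = 800L)
    tr <- inject_heteroplasmy(simulate_two_lineage_population(p))
    hits <- hits + length(unique(tr$het_truth$individual))
    total <- total + 13L
  }
  band <- qbinom(c(0.0025, 0.9975), total, 0.25)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("pileups reflect true alleles, mixtures, errors and coverage", {
  p <- small_params(seed = 9, base_error_rate = 0, het_rate = 0,
                    genome_length = 600L)
  tr <- simulate_two_lineage_population(p)
  pl <- simulate_pileups(tr)
  one <- pl[[1]]
  counts <- as.matrix(one[paste0(c("A", "C", "G", "T", "gap"), "_fwd")]) +
    as.matrix(one[paste0(c("A", "C", "G", "T", "gap"), "_rev")])
  expect_true(all(rowSums(counts > 0) <= 1))  # error-free: one allele per site

  # heteroplasmic site: observed minor fraction within 3 binomial SDs
  ph <- small_params(seed = 10, het_rate = 1, coverage_mean = 500,
                     genome_length = 600L, n_group1 = 4L, n_group2 = 2L,
                     het_maf_range = c(0.4, 0.4),
                     max_het_sites_per_individual = 1L)
  trh <- inject_heteroplasmy(simulate_two_lineage_population(ph))
  plh <- simulate_pileups(trh)
  for (r in seq_len(nrow(trh$het_truth))) {
    ind <- trh$het_truth$individual[r]; pos <- trh$het_truth$position[r]
    row <- plh[[ind]][pos, ]
    cnt <- as.matrix(row[paste0(c("A", "C", "G", "T", "gap"), "_fwd")]) +
      as.matrix(row[paste0(c("A", "C", "G", "T", "gap"), "_rev")])
    cov <- sum(cnt)
    minor <- cnt[1, match(trh$het_truth$minor_allele[r], c("A", "C", "G", "T", "-"))]
    expect_lt(abs(minor / cov - 0.4), 3 * sqrt(0.4 * 0.6 / cov))
  }

  # zero coverage: empty pileups, caller reports no-call everywhere
  p0 <- small_params(seed = 11, coverage_mean = 0, genome_length = 300L)
  tr0 <- simulate_two_lineage_population(p0)
  pl0 <- simulate_pileups(tr0)
  cc <- call_pileup(pl0[[1]])
  expect_true(all(cc$status == "no_call_low_coverage"))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(simulation_params(n_diagnostic = 50, genome_length = 40),
               "exceeds")
  expect_error(simulation_params(n_diagnostic_indels = 5, n_diagnostic = 3),
               "exceeds")
  expect_error(simulation_params(het_maf_range = c(0.2, 0.8)), "maf_range")
  expect_error(caller_params(gross_maf_min = 0.01, micro_maf_max = 0.02))
  expect_error(network_params(snp_weight = 0))
})

test_that("between-lineage divergence sits at the sub-1% scale", {
  vals <- vapply(1:10, function(s) {
    tr <- simulate_two_lineage_population(simulation_params(seed = 500 + s))
    dxy(tr$alignment, tr$group_labels)
  }, 1)
  expect_gte(mean(vals), 0.006)
  expect_lte(mean(vals), 0.009)
})
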