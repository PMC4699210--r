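test_that("Tajima's D matches direct arithmetic on random alignments", {
  set.seed(71)
  for (r in 1:30) {
    aln <- rand_aln(sample(4:8, 1), sample(30:100, 1), n_var = sample(2:8, 1))
    got <- tajimas_d(aln)
    expect_equal(got$D, bf_tajima_d(aln$seq), tolerance = 1e-12)
  }
})

test_that("D is signed by the site-frequency balance and NA without variation", {
  # all variants at frequency one half: positive D
  half <- mito_alignment(c(a = "AAAA", b = "AAAA", c = "TTTT", d = "TTTT"))
  expect_gt(tajimas_d(half)$D, 0)
  # singletons only: negative D
  sing <- mito_alignment(c(a = "AAAAAA", b = "CAAAAA", c = "ATAAAA",
                           d = "AAGAAA", e = "AAATAA", f = "AAAACA"))
  expect_lt(tajimas_d(sing)$D, 0)
  inv <- mito_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  res <- tajimas_d(inv)
  expect_true(is.na(res$D))
  expect_equal(res$S, 0L)
})

test_that("Fu's FS matches exhaustive Ewens enumeration", {
  aln3 <- mito_alignment(c(a = "AAAA", b = "AAAT", c = "AAAT"))
  fs <- fus_fs(aln3)
  expect_equal(fs$FS, bf_fu_fs(aln3$seq), tolerance = 1e-10)
  set.seed(73)
  for (r in 1:20) {
    aln <- rand_aln(sample(3:8, 1), 50, n_var = sample(2:6, 1))
    expect_equal(fus_fs(aln)$FS, bf_fu_fs(aln$seq), tolerance = 1e-10)
  }
  # a single haplotype is not applicable
  one <- mito_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_true(is.na(fus_fs(one)$FS))
})

test_that("many distinct haplotypes at small theta drive FS strongly negative", {
  n <- 12
  seqs <- vapply(seq_len(n), function(i) {
    s <- rep("A", 40); s[i] <- "T"; paste(s, collapse = "")
  }, "")
  names(seqs) <- paste0("s", seq_len(n))
  fs <- fus_fs(mito_alignment(seqs))
  expect_lt(fs$FS, -3)
})

test_that("the coalescent null is centred, deterministic and +1-converted", {
  cn <- coalescent_null(20, list(fixed_S = 40), reps = 400, seed = 5,
                        D_obs = -5, FS_obs = 0)
  expect_equal(cn$p_coal_D, 1 / 401)       # observed below every simulation
  cn2 <- coalescent_null(20, list(fixed_S = 40), reps = 400, seed = 5,
                         D_obs = -5, FS_obs = 0)
  expect_identical(cn$D, cn2$D)
  expect_identical(cn$p_coal_FS, cn2$p_coal_FS)
  expect_lt(abs(mean(cn$D, na.rm = TRUE)), 0.3)
  cn3 <- coalescent_null(20, list(theta = 5), reps = 200, seed = 6)
  expect_true(all(is.finite(cn3$D) | is.na(cn3$D)))
})

test_that("beta-approximation critical region is near nominal under the null", {
  n <- 50
  cn <- coalescent_null(n, list(fixed_S = 60), reps = 1500, seed = 7)
  const <- tajima_constants(n)
  # lower 5% critical value of the beta approximation (one-sided)
  crit <- stats::uniroot(function(d)
    mitopop:::tajima_beta_p(d, n, const) - 0.10, c(-2.2, 0))$root
  frac <- mean(cn$D < crit, na.rm = TRUE)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("sliding windows step correctly and skip invariant windows", {
  aln <- rand_aln(6, 200, n_var = 30, seed = 9)
  scan <- sliding_window_d(aln, window = 100, step = 25)
  expect_equal(scan$start, c(1L, 26L, 51L, 76L, 101L))
  expect_equal(scan$end, scan$start + 99L)
  inv <- rand_aln(6, 200, n_var = 0, seed = 10)
  scan0 <- sliding_window_d(inv, window = 100, step = 25)
  expect_true(all(scan0$skipped))
  # windows dominated by singletons score negative D
  seqs <- c(a = paste(rep("A", 120), collapse = ""))
  for (i in 2:10) {
    s <- rep("A", 120); s[i * 3] <- "T"
    seqs[paste0("s", i)] <- paste(s, collapse = "")
  }
  scan_neg <- sliding_window_d(mito_alignment(seqs), window = 100, step = 25)
  expect_true(all(scan_neg$D[!scan_neg$skipped] < 0))
})

test_that("the relative rate test counts lineage-specific changes", {
  a <- rep("A", 40); b <- rep("A", 40); o <- rep("A", 40)
  a[1:10] <- "T"        # 10 changes on lineage a
  b[11:12] <- "G"       # 2 on lineage b
  rr <- relative_rate_test(a, b, o)
  expect_equal(rr$m_a, 10L)
  expect_equal(rr$m_b, 2L)
  expect_equal(rr$chi2, 64 / 12, tolerance = 1e-12)
  expect_equal(rr$p, stats::pchisq(64 / 12, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(rr$p, 4), 0.0209)
  b2 <- rep("A", 40); b2[11:20] <- "C"   # matched change counts
  a2 <- rep("A", 40); a2[1:10] <- "T"
  eq <- relative_rate_test(a2, b2, o)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  none <- relative_rate_test(o, o, o)
  expect_true(is.na(none$p))
})

test_that("equal-rate lineages rarely reject rate constancy", {
  set.seed(77)
  rej <- 0L
  for (r in 1:30) {
    o <- sample(c("A", "C", "G", "T"), 600, TRUE)
    mut <- function(s, k) {
      idx <- sample(length(s), k)
      s[idx] <- vapply(s[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      s
    }
    a <- mut(o, 15); b <- mut(o, 15)
    p <- relative_rate_test(a, b, o)$p
    if (!is.na(p) && p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 4L)  # close to the nominal 5% level
})

test_that("MKT arithmetic, Fisher p and minor-haplotype invariance hold", {
  row_bal <- mitopop:::mkt_row("g", list(Pn = 5, Ps = 5, Dn = 5, Ds = 5,
                                         sites_s = 100, sites_n = 300), FALSE)
  expect_equal(row_bal$alpha, 0)
  expect_equal(row_bal$p, 1)
  row_neg <- mitopop:::mkt_row("g", list(Pn = 10, Ps = 5, Dn = 1, Ds = 5,
                                         sites_s = 100, sites_n = 300), FALSE)
  expect_equal(row_neg$alpha, -9)
  # Fisher p against hypergeometric enumeration
  set.seed(79)
  for (r in 1:20) {
    tb <- sample(0:12, 4, TRUE)
    if (sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0) next
    row <- mitopop:::mkt_row("g", list(Pn = tb[1], Ps = tb[2], Dn = tb[3],
                                       Ds = tb[4], sites_s = 100,
                                       sites_n = 300), FALSE)
    expect_equal(row$p, bf_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
  expect_equal(mitopop:::mkt_row("g", list(Pn = 2, Ps = 10, Dn = 8, Ds = 1,
                                           sites_s = 100, sites_n = 300),
                                 FALSE)$p,
               bf_fisher_p(2, 10, 8, 1), tolerance = 1e-10)
})

test_that("MKT on synthetic lineages: divergence is minor-invariant and
           alpha is partition-consistent", {
  p <- small_params(seed = 81, genome_length = 16702L, theta_within = 10)
  tr <- inject_heteroplasmy(simulate_two_lineage_population(p))
  ann <- synthetic_annotation()
  res_with <- mkt(tr$alignment, tr$group_labels, ann)
  res_without <- mkt(tr$alignment, tr$group_labels, ann,
                     include_minors = FALSE)
  expect_equal(res_with$Dn_raw, res_without$Dn_raw)
  expect_equal(res_with$Ds_raw, res_without$Ds_raw)
  ml <- res_with[res_with$gene == "multilocus", ]
  per_gene <- res_with[res_with$gene != "multilocus", ]
  expect_equal(ml$Pn, sum(per_gene$Pn))
  expect_equal(ml$Ds_raw, sum(per_gene$Ds_raw))
  # Jukes-Cantor correction inflates divergence counts
  expect_gte(ml$Dn, ml$Dn_raw)
  expect_gte(ml$Ds, ml$Ds_raw)
})
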