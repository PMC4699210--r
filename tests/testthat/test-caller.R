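pileup_row <- function(counts_fwd, counts_rev, q = 33, pos = 1L) {
  nm <- c("A", "C", "G", "T", "gap")
  df <- data.frame(individual = "x", pos = pos)
  for (i in 1:5) {
    df[[paste0(nm[i], "_fwd")]] <- counts_fwd[i]
    df[[paste0(nm[i], "_rev")]] <- counts_rev[i]
  }
  for (i in 1:5)
    df[[paste0("meanQ_", nm[i])]] <-
      if (counts_fwd[i] + counts_rev[i] > 0) q else NA_real_
  df
}

test_that("coverage below the minimum yields no call", {
  cc <- call_site(pileup_row(c(2, 0, 0, 0, 0), c(1, 0, 0, 0, 0)))
  expect_equal(cc$status, "no_call_low_coverage")
  cc0 <- call_site(pileup_row(rep(0, 5), rep(0, 5)))
  expect_equal(cc0$status, "no_call_low_coverage")
})

test_that("a deep 60/40 mixture is called heteroplasmic with high posterior", {
  cc <- call_site(pileup_row(c(150, 100, 0, 0, 0), c(150, 100, 0, 0, 0)),
                  ref_allele = "A")
  expect_equal(cc$status, "called")
  expect_equal(cc$zygosity, "heteroplasmic")
  expect_equal(cc$allele1, "A"); expect_equal(cc$allele2, "C")
  expect_equal(cc$frac2, 0.4)
  expect_gt(cc$posterior, 0.95)
})

test_that("a single discordant read consistent with error calls homoplasmic", {
  cc <- call_site(pileup_row(c(250, 1, 0, 0, 0), c(249, 0, 0, 0, 0)),
                  ref_allele = "A")
  expect_equal(cc$zygosity, "homoplasmic")
  expect_equal(cc$allele1, "A")
  expect_equal(cc$status, "called")
})

test_that("a variant allele on one strand only is strand-filtered", {
  cc <- call_site(pileup_row(c(225, 50, 0, 0, 0), c(225, 0, 0, 0, 0)),
                  ref_allele = "A")
  expect_equal(cc$status, "no_call_strand")
  expect_equal(cc$zygosity, "homoplasmic")
  expect_equal(cc$allele1, "A")
  # without the requirement the same pileup calls heteroplasmic
  cc2 <- call_site(pileup_row(c(225, 50, 0, 0, 0), c(225, 0, 0, 0, 0)),
                   caller_params(require_both_strands = FALSE),
                   ref_allele = "A")
  expect_equal(cc2$zygosity, "heteroplasmic")
})

test_that("posterior for the true state is monotone in coverage", {
  post_at <- function(cov) {
    half <- round(cov * c(0.3, 0.2))
    call_site(pileup_row(c(half[1], half[2], 0, 0, 0),
                         c(half[1], half[2], 0, 0, 0)))$posterior
  }
  p <- sapply(c(10, 30, 100, 300, 1000), post_at)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("heteroplasmy classes follow the MAF thresholds", {
  mk <- function(maf) {
    n2 <- round(1000 * maf); n1 <- 1000 - n2
    call_site(pileup_row(c(n1 / 2, n2 / 2, 0, 0, 0), c(n1 / 2, n2 / 2, 0, 0, 0)),
              caller_params(posterior_threshold = 0.51))
  }
  expect_equal(classify_heteroplasmy(mk(0.22))$class, "gross")
  expect_equal(classify_heteroplasmy(mk(0.01))$class, "micro")
  expect_equal(classify_heteroplasmy(mk(0.10))$class, "indeterminate")
  hom <- call_site(pileup_row(c(100, 0, 0, 0, 0), c(100, 0, 0, 0, 0)))
  expect_error(classify_heteroplasmy(hom), "heteroplasmic")
})

test_that("error-free deep pileups recover the simulated truth exactly", {
  p <- small_params(seed = 13, base_error_rate = 0, genome_length = 1500L,
                    n_diagnostic = 8L, n_diagnostic_indels = 1L)
  tr <- inject_heteroplasmy(simulate_two_lineage_population(p))
  pl <- simulate_pileups(tr)
  vt <- call_variants(pl, tr$ref)
  tv <- tr$truth_variants
  expect_equal(vt$position, tv$position)
  expect_equal(vt$ref, tv$ref)
  expect_equal(vt$alt, tv$alt)
  expect_equal(vt$type, tv$type)
  expect_equal(vt$zygosity, tv$zygosity)
  # phased haplotypes identical to the true alignment
  aln2 <- assemble_haplotypes(pl, tr$ref)
  expect_identical(aln2$seq[rownames(tr$alignment$seq), ], tr$alignment$seq)
})

test_that("numt-flagged positions are excluded from segregating totals", {
  p <- small_params(seed = 13, base_error_rate = 0, genome_length = 1500L,
                    n_diagnostic = 8L, n_diagnostic_indels = 1L)
  tr <- simulate_two_lineage_population(p)
  pl <- simulate_pileups(tr)
  bad <- tr$truth_variants$position[3]
  vt <- call_variants(pl, tr$ref, numt_exclude = bad)
  expect_true(vt$excluded[vt$position == bad])
  expect_equal(vt$reason[vt$position == bad], "numt_ambiguous")
  expect_equal(sum(!vt$excluded), nrow(tr$truth_variants) - 1L)
})

test_that("adjacent same-haplotype substitutions merge into one MNV", {
  L <- 200L
  ref <- strsplit(paste(rep("ACGT", 50), collapse = ""), "")[[1]]
  hap <- ref
  hap[50] <- "T"; hap[51] <- "C"   # ref at 50,51 is C,G
  mk_pileup <- function(hapv) {
    cnt_f <- matrix(0L, L, 5); cnt_r <- matrix(0L, L, 5)
    idx <- match(hapv, c("A", "C", "G", "T", "-"))
    cnt_f[cbind(1:L, idx)] <- 50L; cnt_r[cbind(1:L, idx)] <- 50L
    df <- data.frame(individual = "i1", pos = 1:L)
    nm <- c("A", "C", "G", "T", "gap")
    for (i in 1:5) { df[[paste0(nm[i], "_fwd")]] <- cnt_f[, i]
                     df[[paste0(nm[i], "_rev")]] <- cnt_r[, i] }
    for (i in 1:5) df[[paste0("meanQ_", nm[i])]] <-
      ifelse(cnt_f[, i] + cnt_r[, i] > 0, 33, NA_real_)
    df
  }
  vt <- call_variants(list(i1 = mk_pileup(hap)), paste(ref, collapse = ""))
  expect_equal(nrow(vt), 1L)
  expect_equal(vt$type, "MNV")
  expect_equal(vt$position, 50L)
  expect_equal(vt$ref, "CG")
  expect_equal(vt$alt, "TC")
})

test_that("phasing builds major/minor haplotypes and flags conflicts", {
  ref <- strsplit(paste(rep("A", 30), collapse = ""), "")[[1]]
  mkcall <- function(pos, a1, a2, f1) {
    data.frame(pos = pos, coverage = 500, status = "called",
               zygosity = ifelse(is.na(a2), "homoplasmic", "heteroplasmic"),
               allele1 = a1, allele2 = a2, frac1 = f1, frac2 = 1 - f1,
               posterior = 0.999, meanQ1 = 33, meanQ2 = 33,
               stringsAsFactors = FALSE)
  }
  # one het site: two haplotypes differing exactly there
  calls1 <- mkcall(5, "A", "G", 0.7)
  ph1 <- phase_intraindividual_haplotypes(calls1, ref)
  expect_equal(which(ph1$major != ph1$minor), 5L)
  expect_equal(ph1$minor[5], "G")
  # two het sites with non-reference minors: minor carries both
  calls2 <- rbind(mkcall(5, "A", "G", 0.7), mkcall(9, "A", "T", 0.7))
  ph2 <- phase_intraindividual_haplotypes(calls2, ref)
  expect_equal(which(ph2$major != ph2$minor), c(5L, 9L))
  # minority = reference at one of two sites: frequency_conflict, excluded
  calls3 <- rbind(mkcall(5, "A", "G", 0.7), mkcall(9, "T", "A", 0.7))
  ph3 <- phase_intraindividual_haplotypes(calls3, ref)
  expect_true(ph3$het_sites$conflict[ph3$het_sites$pos == 9])
  expect_false(ph3$het_sites$conflict[ph3$het_sites$pos == 5])
  expect_equal(which(ph3$major != ph3$minor), 5L)
  # no het site: single haplotype
  ph0 <- phase_intraindividual_haplotypes(mkcall(5, "G", NA, 1), ref)
  expect_null(ph0$minor)
  expect_equal(ph0$major[5], "G")
})

test_that("the contamination screen flags exact mixtures and clears genuine hets", {
  p <- small_params(seed = 17, het_rate = 0, genome_length = 1200L)
  tr <- simulate_two_lineage_population(p)
  aln <- tr$alignment
  # a genuine single-site heteroplasmic individual is clean
  het1 <- data.frame(individual = "G1_01", position = 7L)
  rep1 <- screen_contamination(aln, het1)
  expect_false(rep1$flagged)
  # a 70:30 mixture of two sampled haplotypes is flagged
  a <- aln$seq["G1_01", ]; b <- aln$seq["G2_01", ]
  mix_sites <- which(a != b)
  hetmix <- data.frame(individual = "G1_01", position = mix_sites)
  repmix <- screen_contamination(aln, hetmix)
  expect_true(repmix$flagged)
  expect_equal(repmix$matched_id, "G2_01")
  # no heteroplasmic individuals: empty report
  rep0 <- screen_contamination(aln, data.frame(individual = character(0),
                                               position = integer(0)))
  expect_equal(nrow(rep0), 0L)
})

test_that("a mixed-sample pileup is called heteroplasmic and then flagged", {
  p <- small_params(seed = 19, het_rate = 0, genome_length = 1200L,
                    coverage_mean = 400)
  tr <- simulate_two_lineage_population(p)
  pl <- simulate_pileups(tr)
  # contaminate G1_01 with 30% of G2_01's genome
  a <- tr$alignment$seq["G1_01", ]; b <- tr$alignment$seq["G2_01", ]
  diff_sites <- which(a != b)   # includes the diagnostic indel columns
  pile <- pl$G1_01
  for (s in diff_sites) {
    tot <- sum(pile[s, 3:12])
    keep <- round(tot * 0.7); move <- tot - keep
    ia <- match(a[s], c("A", "C", "G", "T", "-")); ib <- match(b[s], c("A", "C", "G", "T", "-"))
    pile[s, paste0(c("A", "C", "G", "T", "gap")[ia], c("_fwd"))] <- ceiling(keep / 2)
    pile[s, paste0(c("A", "C", "G", "T", "gap")[ia], c("_rev"))] <- floor(keep / 2)
    pile[s, paste0(c("A", "C", "G", "T", "gap")[ib], c("_fwd"))] <- ceiling(move / 2)
    pile[s, paste0(c("A", "C", "G", "T", "gap")[ib], c("_rev"))] <- floor(move / 2)
    pile[s, paste0("meanQ_", c("A", "C", "G", "T", "gap")[ib])] <- 33
  }
  hc <- heteroplasmy_calls(list(G1_01 = pile), tr$ref)
  hc <- hc[hc$class == "gross", ]
  expect_setequal(hc$position, diff_sites)
  scr <- screen_contamination(tr$alignment,
                              data.frame(individual = "G1_01",
                                         position = hc$position))
  expect_true(scr$flagged)
  expect_equal(scr$matched_id, "G2_01")
})
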