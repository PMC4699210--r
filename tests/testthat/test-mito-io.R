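test_that("FASTA round trip preserves sequences and labels join correctly", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT-A", ">b", "ACGTTA", ">c", "ACTTTA"), fa)
  labs <- data.frame(id = c("a", "b", "c"), group = c(1L, 1L, 2L))
  aln <- read_alignment(fa, labels = labs)
  expect_equal(n_seq <- nrow(aln$seq), 3L)
  expect_equal(aln$meta$group, c(1L, 1L, 2L))
  out <- tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_identical(read_alignment(out)$seq, aln$seq)

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTACG"), ragged)
  expect_error(read_alignment(ragged), "ragged")
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_alignment(dup), "duplicate")
})

test_that("region extraction slices, validates bounds and is idempotent", {
  aln <- rand_aln(4, 50, seed = 1)
  full <- extract_region(aln, region_spec("full", 1, 50))
  expect_identical(full$seq, aln$seq)
  r <- region_spec("mid", 11, 30)
  sub <- extract_region(aln, r)
  expect_equal(ncol(sub$seq), 20L)
  again <- extract_region(sub, region_spec("all", 1, 20))
  expect_identical(again$seq, sub$seq)
  expect_error(extract_region(aln, region_spec("oob", 40, 60)), "bounds")
})

test_that("minor haplotypes are dropped exactly when invariant in the region", {
  p <- small_params(seed = 4, het_rate = 1, max_het_sites_per_individual = 1L,
                    n_group1 = 6L, n_group2 = 4L, genome_length = 1000L)
  tr <- inject_heteroplasmy(simulate_two_lineage_population(p))
  aln <- tr$alignment
  n_minors <- sum(aln$meta$is_minor)
  expect_equal(n_minors, 10L)
  # fragments tiling the genome: retained-minor counts sum to the total
  tiles <- list(region_spec("t1", 1, 250), region_spec("t2", 251, 500),
                region_spec("t3", 501, 750), region_spec("t4", 751, 1000))
  retained <- vapply(tiles, function(t)
    sum(extract_region(aln, t, drop_invariant_minors = TRUE)$meta$is_minor), 1L)
  expect_equal(sum(retained), n_minors)
  # a minor whose het site is outside a region disappears from it
  hp <- tr$het_truth$position[1]
  ind <- tr$het_truth$individual[1]
  away <- if (hp > 500) region_spec("away", 1, 400) else region_spec("away", 601, 1000)
  sub <- extract_region(aln, away, drop_invariant_minors = TRUE)
  expect_false(paste0(ind, "m") %in% sub$meta$id)
})

test_that("vertebrate mitochondrial translation honours the code and frameshift", {
  plus <- list(name = "g", start = 1, end = 6, strand = "+", kind = "protein",
               frameshift_pos = NA)
  expect_equal(as.character(translate_gene("ATGTGA", plus)), "MW")
  expect_equal(as.character(translate_gene("ATAAGA", plus)), "M*")  # ATA=Met, AGA=stop
  expect_warning(
    out <- translate_gene("AGAATG", plus), "internal stop")
  expect_true(attr(out, "internal_stop"))
  # frameshifted 10-base gene translates 3 codons from the 9 remaining bases
  fs <- list(name = "nd3", start = 1, end = 10, strand = "+", kind = "protein",
             frameshift_pos = 4)
  expect_equal(nchar(translate_gene("ATGCAAATGA", fs)), 3L)
  # base 4 ("C") skipped: ATG AAA TGA -> M K W (TGA is Trp here)
  expect_equal(as.character(translate_gene("ATGCAAATGA", fs)), "MKW")
  # minus strand reverse-complements first
  minus <- list(name = "g", start = 1, end = 6, strand = "-", kind = "protein",
                frameshift_pos = NA)
  expect_equal(as.character(translate_gene("TCACAT", minus)), "MW")
})

test_that("site effects classify against the codon context", {
  ann <- gene_annotation(data.frame(
    name = c("g1", "dloop"), start = c(1L, 13L), end = c(12L, 20L),
    strand = "+", kind = c("protein", "D-loop")))
  ctx <- "TTTATGAAACCCGGGTTTAA"
  expect_equal(classify_site_effect(c("T", "C"), 3, ann, ctx), "synonymous")
  expect_equal(classify_site_effect(c("A", "G"), 4, ann, ctx), "nonsynonymous")
  expect_equal(classify_site_effect(c("A", "C"), 15, ann, ctx), "noncoding")
  expect_error(classify_site_effect(c("A", "-"), 3, ann, ctx), "nucleotide")
  expect_error(classify_site_effect(c("A", "C"), 2, ann, "T-TATGAAACCCGGGTTTAA"),
               "gap")
})

test_that("synonymous codon mutants translate identically", {
  set.seed(21)
  g <- list(name = "g", start = 1, end = 30, strand = "+", kind = "protein",
            frameshift_pos = NA)
  for (rep in 1:20) {
    nt <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    p1 <- suppressWarnings(translate_gene(nt, g))
    ann <- gene_annotation(data.frame(name = "g", start = 1L, end = 30L,
                                      strand = "+", kind = "protein"))
    pos <- sample(30, 1)
    cur <- substring(nt, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), cur)) {
      if (classify_site_effect(c(cur, alt), pos, ann, nt) == "synonymous") {
        mut <- nt; substring(mut, pos, pos) <- alt
        expect_equal(as.character(suppressWarnings(translate_gene(mut, g))),
                     as.character(p1))
      }
    }
  }
})

test_that("annotations validate coordinates and codon structure", {
  expect_error(gene_annotation(data.frame(name = "g", start = 5L, end = 3L,
                                          strand = "+", kind = "protein")),
               "interval")
  expect_error(gene_annotation(data.frame(name = "g", start = 1L, end = 10L,
                                          strand = "+", kind = "protein")),
               "divisible")
  ann <- synthetic_annotation(16702L)
  expect_true(all(ann$end <= 16702L))
  expect_equal(sum(ann$kind == "protein"), 13L)
  expect_equal(sum(!is.na(ann$frameshift_pos)), 1L)
})
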