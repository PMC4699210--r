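#!/usr/bin/env Rscript
# Stage 4: between-lineage differentiation (PhiST on TN93 distances, dXY,
# Hudson permutation tests), per-group neutrality statistics (Tajima's D
# with beta and coalescent significance, Fu's FS), the sliding-window D
# scan, McDonald-Kreitman tests, and Tajima's relative rate test.

library(mitopop)

seed <- 1L
aln <- read_alignment("results/called_haplotypes.fasta",
                      labels = "results/called_labels.tsv")
annotation <- synthetic_annotation(ncol(aln$seq))
part_tab <- read.delim("results/network_partition.tsv")
partition <- setNames(part_tab$group, part_tab$individual)

phi <- pairwise_phist(aln, partition, n_perm = 1000, seed = seed)
hud <- hudson_test_suite(aln, partition, n_perm = 1000, seed = seed + 1L)
d_xy <- dxy(aln, partition)
struct <- data.frame(
  statistic = c("PhiST", "PhiST_p", "dXY", "K_S", "K_S_p", "K_S_star",
                "K_S_star_p", "Z", "Z_p", "Z_star", "Z_star_p"),
  value = c(phi$phi_st, phi$p_value, d_xy, hud$K_S, hud$p_K_S,
            hud$K_S_star, hud$p_K_S_star, hud$Z, hud$p_Z, hud$Z_star,
            hud$p_Z_star))
write.table(struct, "results/structure.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PhiST = %.3f (p = %.4g), dXY = %.5f; Hudson p-values all %.4g\n",
            phi$phi_st, phi$p_value, d_xy, max(hud$p_K_S, hud$p_Z)))

group_aln <- function(g) {
  keep <- aln$meta$individual %in% names(partition)[partition == g]
  structure(list(seq = aln$seq[keep, , drop = FALSE],
                 meta = aln$meta[keep, , drop = FALSE]),
            class = "mito_alignment")
}
neut <- list()
for (nm in c("group1", "group2", "pooled")) {
  sub <- if (nm == "pooled") aln else group_aln(as.integer(substr(nm, 6, 6)))
  td <- tajimas_d(sub)
  fs <- fus_fs(sub)
  cn <- coalescent_null(td$n, list(fixed_S = td$S), reps = 2000,
                        seed = seed + 10L, D_obs = td$D, FS_obs = fs$FS)
  neut[[nm]] <- data.frame(group = nm, n = td$n, S = td$S, D = td$D,
                           p_beta = td$p_beta, p_coal_D = cn$p_coal_D,
                           FS = fs$FS, p_coal_FS = cn$p_coal_FS)
  cat(sprintf("%-7s n=%3d S=%3d  D=%6.2f (beta p=%.3f, coal p=%.3f)  FS=%7.2f (coal p=%.3f)\n",
              nm, td$n, td$S, td$D, td$p_beta, cn$p_coal_D, fs$FS,
              cn$p_coal_FS))
}
write.table(do.call(rbind, neut), "results/neutrality.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

windows <- sliding_window_d(aln, window = 100, step = 25)
write.table(windows, "results/sliding_window_D.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- windows[!windows$skipped & windows$p_beta < 0.05, ]
cat(sprintf("sliding window: %d of %d scored windows depart from neutrality (raw p < 0.05)\n",
            nrow(sig), sum(!windows$skipped)))

mk_with <- mkt(aln, partition, annotation, include_minors = TRUE)
mk_without <- mkt(aln, partition, annotation, include_minors = FALSE)
write.table(mk_with, "results/mkt_with_minors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mk_without, "results/mkt_without_minors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
mlw <- mk_with[mk_with$gene == "multilocus", ]
mlo <- mk_without[mk_without$gene == "multilocus", ]
cat(sprintf("multilocus MKT alpha: %.3f with minors (p = %.3f), %.3f without (p = %.3f)\n",
            mlw$alpha, mlw$p, mlo$alpha, mlo$p))

# relative rate vs a simulated sister-species outgroup
set.seed(seed + 20L)
refv <- strsplit(readLines("results/reference.txt"), "")[[1]]
out <- refv
mut <- sample(length(refv), 250L)
out[mut] <- vapply(refv[mut], function(b)
  sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
consensus <- function(sub) apply(sub$seq, 2, function(col)
  names(sort(table(col), decreasing = TRUE))[1])
rr <- relative_rate_test(consensus(group_aln(1L)), consensus(group_aln(2L)), out)
cat(sprintf("relative rate test: m1=%d m2=%d chi2=%.2f p=%.3f\n",
            rr$m_a, rr$m_b, rr$chi2, rr$p))
write.table(data.frame(m_a = rr$m_a, m_b = rr$m_b, chi2 = rr$chi2, p = rr$p),
            "results/relative_rate.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
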