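#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-lineage bobwhite-style mitogenome
# panel (66 birds, 16,702 bp, 103 diagnostic mutations, ~25% heteroplasmic)
# and write the ground truth. Later stages re-derive the pileups from the
# same seed, so nothing bulky needs to be stored.

library(mitopop)

seed <- 1L
dir.create("results", showWarnings = FALSE)

params <- simulation_params(seed = seed)
truth <- inject_heteroplasmy(simulate_two_lineage_population(params))

write_alignment(truth$alignment, "results/true_haplotypes.fasta",
                labels_path = "results/labels.tsv")
write.table(truth$truth_variants, "results/truth_variants.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$het_truth, "results/truth_heteroplasmies.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(truth$ref, "results/reference.txt")

cat(sprintf("simulated %d individuals (%d + %d), %d true variants\n",
            length(truth$group_labels), params$n_group1, params$n_group2,
            nrow(truth$truth_variants)))
cat(sprintf("heteroplasmic individuals: %d (%d events, MAF %.2f-%.2f)\n",
            length(unique(truth$het_truth$individual)),
            nrow(truth$het_truth),
            min(truth$het_truth$minor_fraction),
            max(truth$het_truth$minor_fraction)))
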