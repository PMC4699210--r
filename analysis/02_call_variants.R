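#!/usr/bin/env Rscript
# Stage 2: regenerate the strand-split pileups (deterministic under the
# stage-1 seed), run the probabilistic caller, classify heteroplasmies,
# phase intra-individual haplotypes, and screen for contamination.

library(mitopop)

seed <- 1L
dir.create("results", showWarnings = FALSE)

params <- simulation_params(seed = seed)
truth <- inject_heteroplasmy(simulate_two_lineage_population(params))
pileups <- simulate_pileups(truth)
annotation <- synthetic_annotation(params$genome_length)

calls <- call_all_individuals(pileups, truth$ref)
variants <- call_variants(NULL, truth$ref, calls = calls,
                          annotation = annotation)
write.table(as.data.frame(variants), "results/variants.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_vcf(variants, "results/variants.vcf")

hets <- heteroplasmy_calls(NULL, truth$ref, calls = calls)
write.table(hets, "results/heteroplasmies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

labels <- truth$alignment$meta[!truth$alignment$meta$is_minor,
                               c("individual", "group", "subspecies")]
aln <- assemble_haplotypes(NULL, truth$ref, calls = calls, labels = labels)
write_alignment(aln, "results/called_haplotypes.fasta",
                labels_path = "results/called_labels.tsv")

gross <- hets[hets$class == "gross", ]
screen <- screen_contamination(aln, gross)
write.table(screen, "results/contamination_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_seg <- sum(!variants$excluded)
cat(sprintf("called %d variant rows (%d segregating after exclusions)\n",
            nrow(variants), n_seg))
cat(sprintf("gross heteroplasmies: %d in %d individuals (MAF %.1f%%-%.1f%%)\n",
            nrow(gross), length(unique(gross$individual)),
            100 * min(gross$maf), 100 * max(gross$maf)))
cat(sprintf("contamination signatures: %d of %d heteroplasmic birds\n",
            sum(screen$flagged), nrow(screen)))
truth_key <- paste(truth$het_truth$individual, truth$het_truth$position)
called_key <- paste(gross$individual, gross$position)
cat(sprintf("caller sensitivity on injected heteroplasmy: %.3f, false gross: %d\n",
            mean(truth_key %in% called_key),
            length(setdiff(called_key, truth_key))))
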