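# mitopop

Complete-mitogenome population genomics with heteroplasmy-aware variant
calling, for the kind of study where a few dozen individuals of a
non-model vertebrate are sequenced to deep coverage and the question is
whether their maternal lineages are structured — and whether the short
mitochondrial fragments traditionally used for such surveys would have
told the same story.

The package grew out of a northern bobwhite-style analysis design: ~53
mitogenomes of ~16.7 kb split into two divergent maternal lineages
(separated by ~103 diagnostic mutations, average divergence under 1%),
about a quarter of individuals carrying moderate-to-high-frequency
heteroplasmy (minor-allele fractions 0.2–0.47), and hundreds-fold
strand-split read coverage. A ground-truthed synthetic generator
reproduces these conditions so that every stage of the pipeline is
testable without any sequence downloads.

## What it computes

* **Variant and heteroplasmy calling** from per-site, per-strand allele
  counts: a 15-state Bayesian site model (4 homoplasmic bases + gap, 10
  heteroplasmic pairs with the mixture fraction integrated out), minimum
  coverage 4, posterior ≥ 0.95, variant alleles required on both strands.
  Heteroplasmies are classified gross (MAF ≥ 0.20) vs micro (≤ 0.02),
  intra-individual haplotypes are phased under the two-genome mixture
  model, and a contamination screen compares each individual's
  heteroplasmic site set against all pairwise haplotype difference sets.
* **Diversity**: segregating sites S, total mutations η, distinct
  haplotypes k, haplotype diversity Hd = n(1 − Σp²)/(n − 1), nucleotide
  diversity π, with DnaSP-style complete-deletion gap handling.
* **Median-joining networks** (Bandelt–Forster–Röhl) with the
  conventional SNP/indel character weights 10/20, quasi-median vectors,
  and an automated two-lineage cut of the network backbone plus
  diagnostic ("torso") mutation counts.
* **Structure**: AMOVA-based Φ<sub>ST</sub> on Tamura–Nei (1993)
  distances with individual-level permutation, Nei's d<sub>XY</sub>, and
  the Hudson K<sub>S</sub>, K<sub>S</sub>*, Z, Z* permutation tests.
* **Neutrality and selection**: Tajima's D (beta-approximation and
  fixed-S coalescent significance, global and 100-bp/25-bp sliding
  windows), Fu's F<sub>S</sub> via the exact Ewens sampling distribution,
  standard and multilocus McDonald–Kreitman tests with Jukes–Cantor
  correction under the vertebrate mitochondrial code, and Tajima's
  relative rate test.
* **Demography**: observed mismatch distributions, the equilibrium
  geometric curve F̂ᵢ = θⁱ/(1+θ)^(i+1), the Rogers–Harpending sudden
  growth–decline family Fᵢ(τ, θ₀, θ₁), least-squares fits and
  conservative (BIC-evidence) model comparison.
* **The fragment-comparison experiment**: every statistic per region
  (353-bp partial D-loop, complete D-loop, full mitogenome), showing how
  haplotypes collapse and demographic signal degrades as the fragment
  shrinks.

## A worked example

```r
library(mitopop)

params <- simulation_params(seed = 1)      # the study-scale defaults
truth  <- inject_heteroplasmy(simulate_two_lineage_population(params))
truth$alignment
#> mito_alignment: 86 sequences x 16702 columns; 20 heteroplasmic minor haplotypes

hs   <- collapse_haplotypes(truth$alignment, "pairwise")
part <- partition_two_groups(hs, "network_cut")
all(part == truth$group_labels[names(part)])
#> [1] TRUE

unlist(count_diagnostic_mutations(truth$alignment, part))
#> n_sites   n_snv n_indel
#>     103     101       2
round(dxy(truth$alignment, part), 5)
#> [1] 0.00798
round(diversity_summary(truth$alignment), 4)
#>    n L_analyzed   S eta  k    Hd    pi
#> 1 86      16700 297 297 58 0.985 0.004
```

The 66 simulated birds (plus 20 phased heteroplasmic minor haplotypes)
fall into two lineages that the network cut recovers exactly; the 103
diagnostic mutations (101 SNVs, 2 indels) define the network torso; the
lineages sit 0.8% apart while nearly every full-length haplotype is
unique (Hd = 0.985). Extracting a 353-bp control-region fragment from the
same alignment collapses those ~58 haplotypes to a handful and turns the
bimodal mismatch distribution unimodal — the information-loss phenomenon
the package is built to measure.

The `analysis/` directory holds the full narrative workflow as numbered
drivers (`01_simulate.R` … `06_fragment_comparison.R`); each is a thin
script over the package functions that prints what it found and writes
its tables under `results/`. A YAML-driven end-to-end run is available as
`run_from_config(system.file("extdata", "example_config.yaml",
package = "mitopop"), output_dir = "results/run")`.

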