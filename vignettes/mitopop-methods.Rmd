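---
title: "Models and methods behind mitopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitopop implements a complete-mitogenome population-genomics workflow for
small vertebrate panels: probabilistic variant and heteroplasmy calling
from per-site read counts, intra-individual haplotype phasing, diversity
and network statistics, tests of population structure, neutrality and
selection, mismatch-distribution demography, and the experiment the
package exists for — quantifying how much of this signal short
mitochondrial fragments (partial or complete control region) lose relative
to the full mitogenome. A ground-truthed synthetic-data generator stands in
for sequenced reads, so every stage is testable end to end.

This vignette explains the models, the tunable parameters, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The synthetic two-lineage panel

`simulate_two_lineage_population()` generates one haplotype per individual
for a panel with deep maternal structure:

* Two lineages fixed for disjoint alleles at `n_diagnostic` positions
  (default 103, of which 2 are single-position gap characters). Each
  diagnostic mutation is assigned to one lineage at random: that lineage is
  fixed for the derived allele, the other keeps the ancestral state, so
  divergence accrues on both branches and the two lineages evolve at equal
  rates — which is what makes Tajima's relative rate test come out
  non-significant on this panel, as it should.
* Within-lineage polymorphism from an independent constant-size Kingman
  coalescent per group (pairwise coalescence rate $1/\theta$, per-lineage
  mutation rate $1/2$ in mismatch units, so `theta_within` *is* the
  expected within-group mean pairwise difference count). Mutations follow
  the infinite-sites model on previously untouched positions: every
  variable column is biallelic and diagnostic columns stay disjoint after
  all later steps.
* Defaults: 49 + 17 individuals, 16,702 bp, `theta_within = 20`. With 103
  diagnostic mutations this puts the between-lineage divergence
  $d_{XY} = (103 + 2\theta)/L \approx 0.008$ substitutions/site — the
  sub-1% scale at which two mitochondrial lineages look like putative
  subspecies. The per-seed value fluctuates by roughly $\pm 0.002$ because
  the whole panel shares two genealogies.

`inject_heteroplasmy()` makes a Bernoulli(0.25) subset of individuals
heteroplasmic: one new singleton SNV (or two, with probability 3/13,
mirroring the observed preponderance of single-site heteroplasmies) at
previously invariant positions, with one minor-allele fraction per
individual drawn uniformly from [0.20, 0.47]. The fraction is shared
across an individual's sites because the biology is a mixture of two
intra-individual mitogenome populations, which is also what justifies the
phasing rule below. Each affected individual contributes a minor-flagged
haplotype to the alignment.

`simulate_pileups()` emulates deep strand-split short-read evidence
without simulating reads: per site, coverage is Poisson(500), reads report
the true allele (the minor allele with probability equal to the
individual's minor fraction at heteroplasmic sites), are corrupted to a
uniformly chosen other base with probability $10^{-3}$, and get a strand
by a fair coin. Per-allele mean Phred qualities are Normal(33, 2),
truncated at 2. What the generator does **not** emulate: mapping artefacts,
site-dependent error profiles, quality/error correlation (error reads carry
the same nominal quality as true reads), D-loop hypervariability (mutations
are uniform along the genome, so the real-data phenomenon of a partial
D-loop fragment showing *higher* nucleotide diversity than the whole
molecule is out of reach), numts, and recombination (assumed absent).
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model, not robustness to alignment or
mapping pathology.

## The site caller

`call_pileup()` scores 15 site states — 5 homoplasmic (A, C, G, T, gap)
and the 10 unordered heteroplasmic pairs — from the per-allele counts
$n_x$ and mean-quality error probabilities $e_x = 10^{-Q_x/10}$:

* homoplasmic $b$: reads of $b$ have probability $1 - e_b$, any other
  allele $e_x/4$;
* heteroplasmic $\{a,b\}$: reads of the pair are generated by the
  two-genome mixture with the mixture fraction *integrated out* under a
  uniform prior, giving the Beta marginal
  $B(n_a + 1, n_b + 1)$; other alleles remain error reads.

The marginal likelihood is the load-bearing choice. A heteroplasmic
likelihood that plugs in the observed fraction as a point estimate always
fits better than the homoplasmic state once a single error read appears,
because the extra free parameter absorbs it; the marginal pays the
integration penalty ($\approx \log n$) and lets a 499:1 pileup resolve to
a homoplasmic call while a 300:200 pileup yields a heteroplasmic posterior
indistinguishable from 1.

The prior puts mass `het_prior` (default 0.001) on heteroplasmy, shared by
the 10 pair states. This reflects how rare true heteroplasmic sites are in
one mitogenome (tens of events in $\sim$16,000 sites would already be
extreme) and is what keeps 3–4 clustered error reads — expected at a few
per genome at 500-fold coverage — from being reported as
microheteroplasmy. A uniform state prior is recovered with
`het_prior = 2/3`. Gross-heteroplasmy detection is insensitive to this
choice: at minor fractions above 0.2 and coverage in the hundreds the
likelihood margins are hundreds of log units.

The contract rules are applied in order: coverage < 4 is a no-call; alleles
with mean quality below 20 are masked; a winning state containing a
non-reference allele absent from either strand falls back to the best
state without it (status `no_call_strand`); a winning posterior below 0.95
is `no_call_low_posterior`. Heteroplasmic calls are classified by minor
fraction: gross at $\ge$ 0.20 (every reported real-data event was at 22%
or more), micro at $\le$ 0.02, indeterminate between — indeterminate
rather than silently dropped, so the band is visible downstream.

Consensus and confidence are deliberately different things: the phased
major haplotype takes the maximum-posterior majority allele at every
covered site, *including* sites below the variant-confidence threshold.
Falling back to the reference at low-confidence sites biases haplotypes
toward the reference; at this coverage and error rate it measurably erodes
the diagnostic columns. The 0.95 threshold governs what enters the variant
table and the heteroplasmy list, not the consensus.

Phasing follows the mixture model: the major haplotype takes every
majority allele, the minor haplotype all minority alleles. A site whose
minority allele is the reference, while the individual's other minorities
are alternatives, contradicts a single two-genome mixture; it is flagged
`frequency_conflict` and excluded from phasing. The contamination screen
compares each heteroplasmic individual's site set with its major
haplotype's full difference set against every other sampled haplotype: an
exact match is the signature of a mixed sample rather than biological
heteroplasmy.

## Diversity, networks, structure

Gap handling defaults to complete deletion (columns containing a gap are
dropped) for $S$, $\eta$, $\pi$, $D$ and $F_S$ — the convention of the
standard desktop tools this table format comes from — while haplotype
collapsing for network input keeps gap columns, so indels distinguish
haplotypes. N is missing data and excluded pairwise everywhere.

The median-joining network follows the Bandelt–Forster–Röhl scheme:
iterate the $\varepsilon$-relaxed minimum spanning network under weighted
Hamming distance (SNP columns weight 10, indel columns 20; runs of
adjacent columns with an identical gap pattern are first merged so a
multi-base indel is one event), add quasi-medians (column-wise majority of
triples connected through at least two network edges; a three-way tie
contributes no vector) whenever they reduce the minimum-spanning-tree
cost, and prune median vectors of degree below three. Candidate triples
are processed in lexicographic order because the published algorithm is
order-sensitive and determinism matters more than any particular
tie-break. With $\varepsilon = 0$ the final network contains an MST of the
observed haplotypes, which the tests verify against exhaustive
spanning-tree enumeration on small inputs.

The two-lineage partition is an operationalization of what the original
analysis did by eye: cut the single maximum-weight MST edge
(`network_cut`; ties broken by the smallest differing column index) or,
alternatively, complete-linkage clustering into two groups. Both recover
the simulated lineages in every tested replicate at default conditions.
Diagnostic ("torso") mutations are columns whose allele sets are disjoint
between the two groups, gaps counting as alleles.

Differentiation uses the Tamura–Nei (1993) distance with base frequencies
taken from each pair's comparable sites; a non-positive logarithm argument
(saturation) falls back to the p-distance with a warning. PhiST is the
two-group AMOVA on squared distances — the convention of distance-matrix
AMOVA software — with significance from permuting *individuals* (an
individual's one or two haplotypes always move together, because
individuals, not haplotypes, are the exchangeable units). The Hudson
subdivision statistics $K_S$, $K_S^*$, $Z$, $Z^*$ use the same permutation
unit; small values indicate subdivision and all permutation p-values use
the +1 convention, so they live in $[1/(B+1), 1]$.

## Neutrality, selection, demography

Tajima's $D$ uses the 1989 constants; significance comes from the beta
approximation (two-sided, the statistic rescaled to its support) and from
a constant-size coalescent null with Hudson's fixed-$S$ mutation scheme
(default 16,000 replicates in the headline analyses; the calibration tests
use 2,000, which bounds the Monte-Carlo error on the null mean of $D$ well
below the tested band). Fu's $F_S$ evaluates the Ewens sampling
probability of at least the observed number of distinct haplotypes at
$\theta = \hat k$, with unsigned Stirling numbers of the first kind
accumulated in log space — every recurrence term is positive, so the
accumulation is stable far beyond the sample sizes used here, and the
tests pin it against exact integer enumeration at small $n$. Following the
usual convention, $F_S$ is treated as significant at the nominal 5% level
when its coalescent p-value is at or below 0.02.

The McDonald–Kreitman machinery classifies each variable codon position
against the gene's majority codon under the vertebrate mitochondrial code
(ND3's single-base insertion is handled by skipping the inserted base
before translation): fixed if the two groups share no allele, polymorphic
if variable within either group; codons containing a gap or N in any
included sequence are excluded. Jukes–Cantor correction transforms
per-class divergence *proportions* and rescales to counts, and the
multilocus test sums counts across genes (a per-gene combination would be
an alternative; summed counts is what makes $\alpha$ invariant to how
genes are partitioned). Minor haplotypes contribute polymorphism only, so
$D_n$ and $D_s$ are identical with and without them — asserted on every
synthetic dataset.

Mismatch distributions are compared with two expected curves: the
equilibrium geometric $\hat F_i = \theta^i/(1+\theta)^{i+1}$ and the
Rogers–Harpending sudden growth–decline family
$F_i(\tau,\theta_0,\theta_1)$, which reduces to the $\theta_0$ curve at
$\tau = 0$ and the $\theta_1$ curve as $\tau \to \infty$ and covers both
growth and decline. Fitting is least squares on frequencies (tail extended
five classes past the observed maximum), with bounds
$\theta \in [0, 10\hat k]$, $\tau \in [0, 50]$ and multi-start
optimisation seeded with informed starts at the observed wave position.
Model preference needs care: the growth–decline family nests the constant
model, and a single genealogy makes the observed mismatch wavy enough that
the three-parameter family always gains some fit even on constant-size
data. The richer model is therefore preferred only on strong evidence — a
Gaussian least-squares BIC margin above 15, the conventional
"very strong" grade — which cleanly separates the two regimes in the
model-recovery tests. An SFS objective (expected constant spectrum
$\theta/i$, folded; growth–decline spectrum by coalescent simulation at
the candidate parameters with a fixed internal stream) is provided as the
alternative the original analysis also reports.

Two modality checks express the headline phenomena. Pooled two-lineage
samples are *bimodal at deep separation*: two local modes at least 50
differences apart with a genuine valley (`is_bimodal()`). Per-group
samples *lose the high mode*: no local mode at or beyond 100 differences
(`has_high_mode()`). The second check is deliberately not "unimodal":
deep neutral genealogies within one group routinely produce two low-range
modes 50+ apart, which is irrelevant to the phenomenon of interest — the
disappearance of the between-lineage mode.

## The fragment-comparison experiment

`compare_fragments()` runs every region through extraction (minor-flagged
haplotypes are dropped when invariant within the region, which is why
fragment sample sizes differ), collapsing, the diversity summary, the
partition and the mismatch distribution, and runs the full statistical
battery on the complete genome. The default regions put the D-loop
(1,152 bp) at the 3' end of the synthetic annotation and a 353-bp partial
fragment at offset 400 within it; the historical fragment's exact
coordinates are not a recoverable fact, so the offset is configuration,
not biology. On default synthetic panels the unique-haplotype count
increases strictly from the 353-bp fragment through the complete D-loop to
the full mitogenome, the fragment mismatch distribution is unimodal while
the full-genome one is bimodal, and the fragment-only partition
misassigns individuals in a minority of replicates while the full-genome
partition never does.

## Problem sizes and numerics

The test suite and acceptance script run everything at the study scale —
66 individuals, 16,702 bp, coverage 500 — with replicate counts chosen to
keep the default run in the minutes range: 50 replicates for the
two-lineage recovery and modality rates, 20 for the haplotype-count
monotonicity, 2,000 coalescent replicates for null calibration, 200
label-randomisations with 199 permutations each for p-value uniformity,
and 200 random alignments ($n \le 8$, $L \le 100$) for oracle equivalence
at $10^{-10}$. Degenerate inputs are contracts, not accidents: $S = 0$
yields a not-applicable $D$ (never 0), a single haplotype yields
not-applicable $F_S$, $\alpha$ is not-applicable when $D_n P_s = 0$, and
a wrap-around region is rejected rather than silently linearized.

## Known limitations

* The caller consumes per-allele mean qualities, not per-read qualities;
  with real data a mean masks quality heterogeneity within an allele.
* Indel calling is single-position (the generator's indels are too);
  multi-base indels are out of the caller's scope, though the network
  coding merges multi-column gap runs into one event.
* The generator's uniform mutation placement cannot reproduce localized
  hypervariability, so fragment-level diversity is always a subset of
  full-genome diversity here, unlike real control-region data.
* The beta approximation for $D$ is known to be approximate in the tails;
  both it and the coalescent p-value are always reported, and they can
  disagree.
* Arlequin-style AMOVA options (linear instead of squared distances) and
  the exclusion timing of numt-ambiguous sites are configuration flags,
  because the source conventions are not fully documented.
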