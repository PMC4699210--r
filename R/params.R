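#' Simulation parameters for the two-lineage mitogenome generator
#'
#' Defaults emulate the study conditions the package's fragment-comparison
#' experiment assumes: 53 mitogenomes of 16,702 bp in two maternal lineages
#' separated by 103 diagnostic mutations (101 SNVs, 2 single-position
#' indels), a 49/17 sample split, about a quarter of individuals carrying
#' 1-2 gross heteroplasmic SNVs with minor-allele fractions in [0.20, 0.47],
#' and deep (hundreds-fold) strand-split coverage with quality-dependent
#' base errors.
#'
#' @param genome_length mitogenome length in positions.
#' @param n_group1,n_group2 individuals per lineage.
#' @param n_diagnostic fixed inter-lineage mutations; `n_diagnostic_indels`
#'   of them are single-position gap characters.
#' @param theta_within per-group scaled mutation parameter of the
#'   constant-size coalescent generating within-lineage polymorphism;
#'   equals the expected within-group mean pairwise difference count.
#' @param het_rate fraction of individuals made heteroplasmic.
#' @param het_maf_range interval for the heteroplasmic minor-allele fraction.
#' @param p_two_het_sites probability an affected individual carries
#'   `max_het_sites_per_individual` rather than one heteroplasmic SNV.
#' @param max_het_sites_per_individual cap on heteroplasmic sites per bird.
#' @param coverage_mean mean reads per site (Poisson).
#' @param base_error_rate per-read probability of miscalling to another base.
#' @param quality_mean mean Phred quality of per-allele mean qualities.
#' @param genealogy within-group genealogy: Kingman coalescent (default) or a
#'   star tree emulating sudden demographic expansion.
#' @param seed integer seed; all stages derive their streams from it.
#' @return a validated `simulation_params` list.
#' @export
simulation_params <- function(genome_length = 16702L,
                              n_group1 = 49L, n_group2 = 17L,
                              n_diagnostic = 103L, n_diagnostic_indels = 2L,
                              theta_within = 20,
                              het_rate = 0.25,
                              het_maf_range = c(0.20, 0.47),
                              p_two_het_sites = 3 / 13,
                              max_het_sites_per_individual = 2L,
                              coverage_mean = 500,
                              base_error_rate = 0.001,
                              quality_mean = 33,
                              genealogy = c("kingman", "star"),
                              seed = 1L) {
  genealogy <- match.arg(genealogy)
  p <- list(
    genome_length = check_count(genome_length, "genome_length"),
    n_group1 = check_count(n_group1, "n_group1"),
    n_group2 = check_count(n_group2, "n_group2"),
    n_diagnostic = check_count(n_diagnostic, "n_diagnostic"),
    n_diagnostic_indels = check_count(n_diagnostic_indels, "n_diagnostic_indels"),
    theta_within = theta_within,
    het_rate = het_rate,
    het_maf_range = het_maf_range,
    p_two_het_sites = p_two_het_sites,
    max_het_sites_per_individual = check_count(max_het_sites_per_individual,
                                               "max_het_sites_per_individual"),
    coverage_mean = coverage_mean,
    base_error_rate = base_error_rate,
    quality_mean = quality_mean,
    genealogy = genealogy,
    seed = as.integer(seed)
  )
  if (p$n_diagnostic > p$genome_length)
    stop_mitopop("n_diagnostic exceeds genome_length")
  if (p$n_diagnostic_indels > p$n_diagnostic)
    stop_mitopop("n_diagnostic_indels exceeds n_diagnostic")
  if (!is.numeric(p$theta_within) || p$theta_within < 0)
    stop_mitopop("theta_within must be >= 0")
  if (!is_prob(p$het_rate)) stop_mitopop("het_rate must be in [0, 1]")
  r <- p$het_maf_range
  if (length(r) != 2L || any(r <= 0) || any(r > 0.5) || r[1] > r[2])
    stop_mitopop("het_maf_range must be an interval within (0, 0.5]")
  if (p$coverage_mean < 0) stop_mitopop("coverage_mean must be >= 0")
  if (!is_prob(p$base_error_rate)) stop_mitopop("base_error_rate must be in [0, 1]")
  class(p) <- "simulation_params"
  p
}

#' Variant caller parameters
#'
#' The contract mirrors the probabilistic caller settings the analysis
#' fixes: minimum coverage 4, posterior (variant probability) threshold
#' 0.95, the variant allele required on both strands, and at most two
#' alleles per site. MAF thresholds separate gross heteroplasmy (minor
#' fraction >= `gross_maf_min`) from microheteroplasmy
#' (<= `micro_maf_max`); fractions between the two are indeterminate.
#'
#' @param min_coverage reads required to attempt a call.
#' @param posterior_threshold posterior needed for a confident call.
#' @param require_both_strands require variant alleles on both strands.
#' @param max_alleles alleles retained per site.
#' @param het_prior prior probability that a site is heteroplasmic, shared
#'   equally by the 10 heteroplasmic states (the homoplasmic states share
#'   the rest). The default 0.001 reflects how rare true heteroplasmic
#'   sites are per mitogenome and is what keeps a handful of clustered
#'   error reads from outcompeting a homoplasmic call.
#' @param gross_maf_min minimum minor-allele fraction for gross heteroplasmy.
#' @param micro_maf_max maximum minor-allele fraction for microheteroplasmy.
#' @param min_mean_quality minimum per-allele mean Phred quality.
#' @return a validated `caller_params` list.
#' @export
caller_params <- function(min_coverage = 4L,
                          posterior_threshold = 0.95,
                          require_both_strands = TRUE,
                          max_alleles = 2L,
                          het_prior = 0.001,
                          gross_maf_min = 0.20,
                          micro_maf_max = 0.02,
                          min_mean_quality = 20) {
  p <- list(min_coverage = check_count(min_coverage, "min_coverage"),
            posterior_threshold = posterior_threshold,
            require_both_strands = isTRUE(require_both_strands),
            max_alleles = check_count(max_alleles, "max_alleles"),
            het_prior = het_prior,
            gross_maf_min = gross_maf_min,
            micro_maf_max = micro_maf_max,
            min_mean_quality = min_mean_quality)
  if (!(p$micro_maf_max > 0 && p$micro_maf_max < p$gross_maf_min &&
        p$gross_maf_min <= 0.5))
    stop_mitopop("need 0 < micro_maf_max < gross_maf_min <= 0.5")
  if (!(p$posterior_threshold > 0.5 && p$posterior_threshold <= 1))
    stop_mitopop("posterior_threshold must be in (0.5, 1]")
  if (!is_prob(p$het_prior) || p$het_prior <= 0 || p$het_prior >= 1)
    stop_mitopop("het_prior must be in (0, 1)")
  class(p) <- "caller_params"
  p
}

#' Median-joining network parameters
#'
#' @param snp_weight,indel_weight per-column mutation weights; defaults are
#'   the conventional Network character weights (10 for SNPs, 20 for indels).
#' @param epsilon relaxation of the minimum-spanning-network distance
#'   classes; 0 keeps the network a minimum spanning network.
#' @export
network_params <- function(snp_weight = 10, indel_weight = 20, epsilon = 0) {
  if (snp_weight <= 0 || indel_weight <= 0) stop_mitopop("weights must be > 0")
  if (epsilon < 0) stop_mitopop("epsilon must be >= 0")
  structure(list(snp_weight = snp_weight, indel_weight = indel_weight,
                 epsilon = epsilon),
            class = "network_params")
}
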