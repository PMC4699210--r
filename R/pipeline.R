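# Orchestration of the headline experiment: the partial-fragment vs
# complete-mitogenome comparison, plus the YAML-driven end-to-end run.

#' Compare population inferences across fragment definitions
#'
#' For every region: extract (with the minor-drop rule), collapse,
#' diversity summary, two-group partition and diagnostic-mutation count,
#' and the observed mismatch distribution. For the region named `full`,
#' additionally: PhiST with permutation, the Hudson subdivision suite,
#' Tajima's D and Fu's FS per group and pooled, the sliding-window D scan,
#' McDonald-Kreitman tests (when an annotation is given) and demographic
#' model fits per group.
#'
#' @param aln [mito_alignment()] including phased minor haplotypes.
#' @param regions named list of [region_spec()] (see [default_regions()]).
#' @param annotation optional [gene_annotation()] enabling the MKT.
#' @param partition optional named vector individual -> group; derived from
#'   the full-genome network cut when missing.
#' @param n_perm permutations for PhiST and Hudson tests.
#' @param seed integer seed.
#' @param build_networks also build full median-joining networks (median
#'   vector counts) per region.
#' @param window,step sliding-window scan geometry.
#' @return `analysis_report` list: `per_region`, `partition`, `structure`,
#'   `hudson`, `neutrality`, `windows`, `mkt_with_minors`,
#'   `mkt_without_minors`, `demography`, `provenance`.
#' @export
compare_fragments <- function(aln, regions, annotation = NULL,
                              partition = NULL, n_perm = 1000L, seed = 1L,
                              build_networks = TRUE,
                              window = 100L, step = 25L) {
  if (length(regions) == 0L) stop_mitopop("empty region list")
  full_region <- regions[["full"]] %||% region_spec("full", 1L, aln_length(aln))
  full_aln <- extract_region(aln, full_region, drop_invariant_minors = TRUE)
  hs_full <- collapse_haplotypes(full_aln, "pairwise")
  if (is.null(partition))
    partition <- partition_two_groups(hs_full, "network_cut")

  per_region <- lapply(names(regions), function(rn) {
    sub <- extract_region(aln, regions[[rn]], drop_invariant_minors = TRUE)
    hs <- collapse_haplotypes(sub, "pairwise")
    div <- diversity_summary(sub)
    mm <- mismatch_observed(sub)
    res <- list(region = rn, n = n_seq(sub), diversity = div, k = hs$k,
                mismatch = mm, bimodal = is_bimodal(mm))
    res$partition <- tryCatch(partition_two_groups(hs, "network_cut"),
                              warning = function(w) NULL, error = function(e) NULL)
    if (build_networks && hs$k >= 2L) {
      net <- median_joining_network(hs)
      res$n_median_vectors <- sum(net$is_median)
      res$network <- net
    }
    res
  })
  names(per_region) <- names(regions)

  diag <- count_diagnostic_mutations(full_aln, partition)
  structure_res <- pairwise_phist(full_aln, partition, n_perm = n_perm,
                                  seed = derive_seed(seed, 11L))
  structure_res$d_xy <- dxy(full_aln, partition)
  hudson <- hudson_test_suite(full_aln, partition, n_perm = n_perm,
                              seed = derive_seed(seed, 12L))

  split_aln <- function(g) {
    keep <- which(row_groups(full_aln$meta, partition) == g)
    structure(list(seq = full_aln$seq[keep, , drop = FALSE],
                   meta = full_aln$meta[keep, , drop = FALSE]),
              class = "mito_alignment")
  }
  neutrality <- lapply(list(group1 = split_aln(1L), group2 = split_aln(2L),
                            pooled = full_aln), function(a) {
    td <- tajimas_d(a)
    fs <- fus_fs(a)
    list(n = n_seq(a), D = td$D, p_beta = td$p_beta, S = td$S,
         k_hat = td$k_hat, FS = fs$FS, k_obs = fs$k_obs)
  })
  windows <- sliding_window_d(full_aln, window = window, step = step)

  mkt_with <- mkt_without <- NULL
  if (!is.null(annotation)) {
    mkt_with <- mkt(full_aln, partition, annotation, include_minors = TRUE)
    mkt_without <- mkt(full_aln, partition, annotation, include_minors = FALSE)
  }
  demography <- lapply(list(group1 = split_aln(1L), group2 = split_aln(2L)),
                       function(a) {
    fit_demographic_model(mismatch_observed(a), model = "both",
                          seed = derive_seed(seed, 13L))
  })
  structure(list(per_region = per_region, partition = partition,
                 diagnostic = diag, structure = structure_res,
                 hudson = hudson, neutrality = neutrality,
                 windows = windows, mkt_with_minors = mkt_with,
                 mkt_without_minors = mkt_without, demography = demography,
                 provenance = list(seed = seed, n_perm = n_perm,
                                   timestamp = format(Sys.time()),
                                   package_version =
                                     as.character(utils::packageVersion("mitopop")))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report over", length(x$per_region), "regions\n")
  for (r in x$per_region)
    cat(sprintf("  %-14s n=%3d k=%3d Hd=%.3f pi=%.5f\n", r$region, r$n,
                r$k, r$diversity$Hd, r$diversity$pi))
  cat(sprintf("  diagnostic sites: %d (%d SNV, %d indel)\n",
              x$diagnostic$n_sites, x$diagnostic$n_snv, x$diagnostic$n_indel))
  cat(sprintf("  PhiST = %.3f (p = %.4g), dXY = %.5f\n",
              x$structure$phi_st, x$structure$p_value, x$structure$d_xy))
  invisible(x)
}

config_get <- function(cfg, path, default = NULL, required = FALSE) {
  node <- cfg
  for (p in strsplit(path, "/")[[1]]) {
    if (!is.list(node) || is.null(node[[p]])) {
      if (required) stop_mitopop("config field missing: ", path)
      return(default)
    }
    node <- node[[p]]
  }
  node
}

#' Run the full pipeline from a YAML configuration
#'
#' Schema (version 1): `seed`; either `simulate:` (fields of
#' [simulation_params()]) or `input: {alignment: path, labels: path}`;
#' optional `caller:` ([caller_params()] fields), `regions:
#' {partial_offset, partial_length}`, `n_perm`, `output_dir`.
#' Executes simulate -> pileups -> call -> phase -> compare_fragments and
#' writes FASTA/TSV/VCF/GraphML artifacts plus a run log.
#'
#' @param config path to a YAML file or an equivalent list.
#' @param output_dir overrides the config's output directory.
#' @return the [compare_fragments()] report (invisibly when writing).
#' @export
run_from_config <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_mitopop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  ver <- config_get(cfg, "version", 1L)
  if (!identical(as.integer(ver), 1L)) stop_mitopop("unsupported config version: ", ver)
  seed <- as.integer(config_get(cfg, "seed", 1L))
  out_dir <- output_dir %||% config_get(cfg, "output_dir")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- c(paste("run started", format(Sys.time())),
                 paste("seed", seed),
                 paste("config:", paste(utils::capture.output(utils::str(cfg)),
                                        collapse = " | ")))

  cp_fields <- config_get(cfg, "caller", list())
  cparams <- do.call(caller_params, cp_fields)

  if (!is.null(config_get(cfg, "simulate"))) {
    sp_fields <- config_get(cfg, "simulate", list())
    sp_fields$seed <- seed
    sparams <- do.call(simulation_params, sp_fields)
    truth <- inject_heteroplasmy(simulate_two_lineage_population(sparams))
    pileups <- simulate_pileups(truth)
    reference <- truth$ref
    calls <- call_all_individuals(pileups, reference, cparams)
    labels <- truth$alignment$meta[!truth$alignment$meta$is_minor,
                                   c("individual", "group", "subspecies")]
    aln <- assemble_haplotypes(pileups, reference, cparams, calls = calls,
                               labels = labels)
    genome_length <- sparams$genome_length
  } else {
    aln_path <- config_get(cfg, "input/alignment", required = TRUE)
    if (!file.exists(aln_path)) stop_mitopop("input/alignment not found: ", aln_path)
    labels_path <- config_get(cfg, "input/labels")
    aln <- read_alignment(aln_path, labels = labels_path)
    reference <- paste(aln$seq[1L, ], collapse = "")
    pileups <- NULL; calls <- NULL
    genome_length <- aln_length(aln)
  }
  annotation <- synthetic_annotation(genome_length)
  regions <- default_regions(
    annotation, genome_length,
    partial_offset = config_get(cfg, "regions/partial_offset", 400L),
    partial_length = config_get(cfg, "regions/partial_length", 353L))
  n_perm <- as.integer(config_get(cfg, "n_perm", 1000L))
  report <- compare_fragments(aln, regions, annotation = annotation,
                              n_perm = n_perm, seed = seed)

  if (!is.null(out_dir)) {
    write_alignment(aln, file.path(out_dir, "haplotypes.fasta"),
                    labels_path = file.path(out_dir, "labels.tsv"))
    if (!is.null(calls)) {
      vt <- call_variants(NULL, reference, cparams, calls = calls,
                          annotation = annotation)
      utils::write.table(as.data.frame(vt), file.path(out_dir, "variants.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_vcf(vt, file.path(out_dir, "variants.vcf"))
      hets <- heteroplasmy_calls(NULL, reference, cparams, calls = calls)
      utils::write.table(hets, file.path(out_dir, "heteroplasmies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    div <- do.call(rbind, lapply(report$per_region, function(r)
      cbind(region = r$region, r$diversity)))
    utils::write.table(div, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    full_net <- report$per_region[["full"]]$network
    if (!is.null(full_net))
      write_graphml(full_net, file.path(out_dir, "network.graphml"))
    writeLines(c(log_lines, paste("run finished", format(Sys.time()))),
               file.path(out_dir, "run.log"))
  }
  invisible(report)
}
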