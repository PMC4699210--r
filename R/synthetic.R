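#' Simulate a two-lineage mitogenome population
#'
#' Generates one haplotype per individual: two lineages fixed for disjoint
#' alleles at `n_diagnostic` diagnostic positions (of which
#' `n_diagnostic_indels` are single-position gaps), plus within-lineage
#' polymorphism from an independent constant-size Kingman coalescent per
#' group (infinite-sites mutations on previously unused positions, so every
#' variable column is biallelic and diagnostic columns stay disjoint).
#' Each diagnostic mutation is assigned to one lineage at random: that
#' lineage is fixed for the derived allele and the other retains the
#' ancestral (reference) state, so divergence accrues on both branches as
#' in a real lineage split.
#'
#' @param params [simulation_params()]
#' @return `synthetic_truth`: `alignment` ([mito_alignment()], one sequence
#'   per individual), `truth_variants` (position, ref, alt, type, zygosity,
#'   carrier frequency), `group_labels`, `het_truth` (empty until
#'   [inject_heteroplasmy()]), `ref` (reference haplotype string), `params`.
#' @export
simulate_two_lineage_population <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  L <- params$genome_length
  n1 <- params$n_group1; n2 <- params$n_group2
  ref <- sample(BASES, L, replace = TRUE)

  diag_pos <- sort(sample.int(L, params$n_diagnostic))
  indel_idx <- if (params$n_diagnostic_indels > 0L)
    sort(sample(seq_along(diag_pos), params$n_diagnostic_indels)) else integer(0)
  diag_alt <- vapply(diag_pos, function(p)
    sample(setdiff(BASES, ref[p]), 1L), "")
  diag_alt[indel_idx] <- "-"

  ids <- c(sprintf("G1_%02d", seq_len(n1)), sprintf("G2_%02d", seq_len(n2)))
  groups <- rep(c(1L, 2L), c(n1, n2))
  mat <- matrix(rep(ref, each = n1 + n2), nrow = n1 + n2,
                dimnames = list(ids, NULL))
  # each diagnostic mutation fixes on one lineage drawn at random
  diag_side <- sample(1:2, length(diag_pos), replace = TRUE)
  for (d in seq_along(diag_pos))
    mat[groups == diag_side[d], diag_pos[d]] <- diag_alt[d]

  used <- diag_pos
  variants <- if (length(diag_pos)) {
    data.frame(position = diag_pos, ref = ref[diag_pos],
               alt = diag_alt,
               type = ifelse(diag_alt == "-", "indel", "SNV"),
               zygosity = "homoplasmic",
               frequency = ifelse(diag_side == 1L, n1, n2) / (n1 + n2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = integer(0), ref = character(0), alt = character(0),
               type = character(0), zygosity = character(0),
               frequency = numeric(0), stringsAsFactors = FALSE)
  }
  for (g in 1:2) {
    ng <- if (g == 1L) n1 else n2
    if (ng < 2L || params$theta_within == 0) next
    gen <- sim_genealogy(ng, theta1 = params$theta_within,
                         genealogy = params$genealogy)
    counts <- drop_mutations(gen, theta = 1)
    S <- length(counts)
    if (S == 0L) next
    pool <- setdiff(seq_len(L), used)
    if (S > length(pool)) stop_mitopop("genome too short for mutation load")
    pos <- sample(pool, S)
    used <- c(used, pos)
    tipsets <- attr(counts, "tipsets")
    rows_g <- which(groups == g)
    alt <- character(S)
    for (m in seq_len(S)) {
      alt[m] <- sample(setdiff(BASES, ref[pos[m]]), 1L)
      mat[rows_g[tipsets[[m]]], pos[m]] <- alt[m]
    }
    variants <- rbind(variants, data.frame(
      position = pos, ref = ref[pos], alt = alt, type = "SNV",
      zygosity = "homoplasmic", frequency = counts / (n1 + n2),
      stringsAsFactors = FALSE))
  }
  variants <- variants[order(variants$position), ]
  rownames(variants) <- NULL
  meta <- data.frame(id = ids, individual = ids, group = groups,
                     subspecies = ifelse(groups == 1L, "taylori", "texanus"),
                     ecoregion = NA_character_, is_minor = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(alignment = mito_alignment(mat, meta),
                 truth_variants = variants,
                 group_labels = stats::setNames(groups, ids),
                 het_truth = data.frame(individual = character(0),
                                        position = integer(0),
                                        minor_allele = character(0),
                                        minor_fraction = numeric(0)),
                 ref = paste(ref, collapse = ""),
                 params = params),
            class = "synthetic_truth")
}

#' Inject gross heteroplasmy into a simulated population
#'
#' A Bernoulli(`het_rate`) subset of individuals gains one or
#' `max_het_sites_per_individual` new singleton SNVs at previously
#' invariant positions, with one minor-allele fraction per individual drawn
#' uniformly from `het_maf_range` (the two intra-individual haplotypes are a
#' two-genome mixture, so the fraction is shared across that individual's
#' sites). The alignment gains one minor-flagged haplotype per affected
#' individual, differing from its major exactly at the injected sites.
#'
#' @param truth [simulate_two_lineage_population()] output.
#' @param params [simulation_params()]
#' @export
inject_heteroplasmy <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(params$seed, 1L))
  aln <- truth$alignment
  L <- aln_length(aln)
  inds <- aln$meta$id[!aln$meta$is_minor]
  affected <- inds[stats::runif(length(inds)) < params$het_rate]
  if (length(affected) == 0L) return(truth)
  invariant <- setdiff(seq_len(L), truth$truth_variants$position)
  het <- data.frame(individual = character(0), position = integer(0),
                    minor_allele = character(0), minor_fraction = numeric(0))
  mat <- aln$seq
  extra_seq <- list(); extra_meta <- list()
  for (ind in affected) {
    k <- if (params$max_het_sites_per_individual > 1L &&
             stats::runif(1) < params$p_two_het_sites)
      params$max_het_sites_per_individual else 1L
    if (length(invariant) < k)
      stop_mitopop("no invariant positions left for heteroplasmy injection")
    pos <- sample(invariant, k)
    invariant <- setdiff(invariant, pos)
    maf <- stats::runif(1, params$het_maf_range[1], params$het_maf_range[2])
    major <- mat[ind, pos]
    minor <- vapply(major, function(b) sample(setdiff(BASES, b), 1L), "")
    het <- rbind(het, data.frame(individual = ind, position = pos,
                                 minor_allele = unname(minor),
                                 minor_fraction = maf,
                                 stringsAsFactors = FALSE))
    mrow <- mat[ind, ]
    mrow[pos] <- minor
    extra_seq[[ind]] <- mrow
    mi <- aln$meta[aln$meta$id == ind, ]
    mi$id <- paste0(ind, "m"); mi$is_minor <- TRUE
    extra_meta[[ind]] <- mi
  }
  mat2 <- rbind(mat, do.call(rbind, extra_seq))
  rownames(mat2) <- c(rownames(mat), paste0(affected, "m"))
  meta2 <- rbind(aln$meta, do.call(rbind, extra_meta))
  rownames(meta2) <- NULL
  truth$alignment <- mito_alignment(mat2, NULL)
  truth$alignment$meta <- meta2
  truth$het_truth <- het[order(het$individual, het$position), ]
  rownames(truth$het_truth) <- NULL
  ref <- strsplit(truth$ref, "")[[1]]
  tv <- rbind(truth$truth_variants,
              data.frame(position = het$position, ref = ref[het$position],
                         alt = het$minor_allele, type = "SNV",
                         zygosity = "heteroplasmic",
                         frequency = 1 / nrow(mat2),
                         stringsAsFactors = FALSE))
  tv <- tv[order(tv$position), ]
  rownames(tv) <- NULL
  truth$truth_variants <- tv
  truth$group_labels <- stats::setNames(meta2$group, meta2$id)[
    !duplicated(meta2$individual)]
  names(truth$group_labels) <- meta2$individual[!duplicated(meta2$individual)]
  truth
}

#' Simulate strand-split read-count pileups
#'
#' Per individual and site: coverage ~ Poisson(`coverage_mean`), each read
#' reports the true allele (the minor allele with probability equal to the
#' individual's minor fraction at heteroplasmic sites), is corrupted to a
#' uniformly chosen other base with probability `base_error_rate`, and is
#' assigned a strand Bernoulli(0.5). Per-allele mean qualities are
#' Normal(`quality_mean`, 2) truncated at 2.
#'
#' @param truth [synthetic_truth] (with or without heteroplasmy).
#' @param params [simulation_params()]
#' @return named list of per-individual pileup data.frames with columns
#'   `individual`, `pos`, `<allele>_fwd`, `<allele>_rev`, `meanQ_<allele>`
#'   for alleles A, C, G, T, gap.
#' @export
simulate_pileups <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(params$seed, 2L))
  aln <- truth$alignment
  L <- aln_length(aln)
  err <- params$base_error_rate
  inds <- aln$meta$id[!aln$meta$is_minor]
  out <- vector("list", length(inds))
  names(out) <- inds
  for (ind in inds) {
    major <- aln$seq[ind, ]
    cov <- stats::rpois(L, params$coverage_mean)
    counts <- matrix(0L, L, 5L, dimnames = list(NULL, ALLELES))
    counts[cbind(seq_len(L), match(major, ALLELES))] <- cov
    hrows <- truth$het_truth[truth$het_truth$individual == ind, , drop = FALSE]
    if (nrow(hrows) > 0L) {
      for (r in seq_len(nrow(hrows))) {
        p <- hrows$position[r]
        nm <- stats::rbinom(1L, cov[p], hrows$minor_fraction[r])
        counts[p, major[p]] <- counts[p, major[p]] - nm
        counts[p, hrows$minor_allele[r]] <- counts[p, hrows$minor_allele[r]] + nm
      }
    }
    if (err > 0) {
      for (s in seq_len(5L)) {
        c_s <- counts[, s]
        has <- which(c_s > 0L)
        if (!length(has)) next
        nerr <- stats::rbinom(length(has), c_s[has], err)
        targets <- setdiff(BASES, ALLELES[s])
        counts[has, s] <- counts[has, s] - nerr
        remaining <- nerr
        for (t in seq_along(targets)) {
          take <- if (t == length(targets)) remaining
                  else stats::rbinom(length(has), remaining,
                                     1 / (length(targets) - t + 1))
          counts[has, targets[t]] <- counts[has, targets[t]] + take
          remaining <- remaining - take
        }
      }
    }
    fwd <- matrix(stats::rbinom(5L * L, counts, 0.5), L, 5L)
    rev <- counts - fwd
    q <- matrix(pmax(2, stats::rnorm(5L * L, params$quality_mean, 2)), L, 5L)
    q[counts == 0L] <- NA_real_
    df <- data.frame(individual = ind, pos = seq_len(L))
    for (s in seq_len(5L)) {
      nm <- c("A", "C", "G", "T", "gap")[s]
      df[[paste0(nm, "_fwd")]] <- fwd[, s]
      df[[paste0(nm, "_rev")]] <- rev[, s]
    }
    for (s in seq_len(5L))
      df[[paste0("meanQ_", c("A", "C", "G", "T", "gap")[s])]] <- q[, s]
    out[[ind]] <- df
  }
  out
}

#' Default synthetic mitogenome annotation
#'
#' A deterministic gene layout emulating a galliform mitogenome: two rRNAs,
#' thirteen protein-coding genes (ND3 carrying a single-base frameshift
#' insertion, ND6 on the minus strand) and the D-loop control region at the
#' 3' end.
#'
#' @param genome_length total length; must be >= 16000.
#' @export
synthetic_annotation <- function(genome_length = 16702L) {
  if (genome_length < 16000L) stop_mitopop("genome too short for the layout")
  genes <- list(c("ND1", 957L), c("ND2", 1038L), c("COX1", 1551L),
                c("COX2", 684L), c("ATP8", 165L), c("ATP6", 681L),
                c("COX3", 786L), c("ND3", 352L), c("ND4L", 297L),
                c("ND4", 1377L), c("ND5", 1818L), c("ND6", 522L),
                c("CYTB", 1143L))
  rows <- list(
    data.frame(name = "12S", start = 70L, end = 1040L, strand = "+",
               kind = "rRNA", frameshift_pos = NA_integer_),
    data.frame(name = "16S", start = 1100L, end = 2700L, strand = "+",
               kind = "rRNA", frameshift_pos = NA_integer_))
  at <- 2800L
  for (g in genes) {
    len <- as.integer(g[2])
    fs <- if (g[1] == "ND3") at + 100L else NA_integer_
    rows[[length(rows) + 1L]] <-
      data.frame(name = g[1], start = at, end = at + len - 1L,
                 strand = if (g[1] == "ND6") "-" else "+",
                 kind = "protein", frameshift_pos = fs)
    at <- at + len + 20L
  }
  rows[[length(rows) + 1L]] <-
    data.frame(name = "D-loop", start = genome_length - 1151L,
               end = genome_length, strand = "+", kind = "D-loop",
               frameshift_pos = NA_integer_)
  gene_annotation(do.call(rbind, rows), genome_length)
}

#' Default fragment definitions for the fragment-comparison experiment
#'
#' @param annotation [gene_annotation()] with a D-loop record.
#' @param genome_length alignment length.
#' @param partial_offset 0-based offset of the 353-bp partial fragment
#'   within the D-loop (the historical fragment's exact coordinates are a
#'   configuration choice, not a fixed fact).
#' @param partial_length partial-fragment length (default 353).
#' @return named list of [region_spec()]: `partial_dloop`, `dloop`, `full`.
#' @export
default_regions <- function(annotation, genome_length,
                            partial_offset = 400L, partial_length = 353L) {
  dl <- annotation[annotation$kind == "D-loop", ][1, ]
  ps <- dl$start + partial_offset
  list(partial_dloop = region_spec("partial_dloop", ps, ps + partial_length - 1L),
       dloop = region_spec("dloop", dl$start, dl$end),
       full = region_spec("full", 1L, genome_length))
}

#' Write pileups to TSV (one file per individual or one combined file)
#' @param pileups list from [simulate_pileups()].
#' @param path output TSV path (all individuals stacked).
#' @export
write_pileups <- function(pileups, path) {
  utils::write.table(do.call(rbind, pileups), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stacked pileup TSV back into a per-individual list
#' @param path TSV written by [write_pileups()].
#' @export
read_pileups <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  split(df, df$individual)
}
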