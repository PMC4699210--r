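# Assembly of per-site calls into a population variant table, phased
# haplotype alignments, and a minimal VCF writer.

as_ref_vector <- function(reference) {
  if (length(reference) == 1L && nchar(reference) > 1L)
    strsplit(reference, "")[[1]] else reference
}

#' Run the caller over every individual's pileup
#'
#' Convenience wrapper used by the assembly functions; compute the calls
#' once and pass them via their `calls` argument to avoid re-calling.
#'
#' @inheritParams call_variants
#' @return named list of per-individual [call_pileup()] data.frames.
#' @export
call_all_individuals <- function(pileups, reference, params = caller_params()) {
  refv <- as_ref_vector(reference)
  lapply(pileups, function(p) {
    if (nrow(p) != length(refv) || !all(p$pos == seq_along(refv)))
      stop_mitopop("pileup coordinates do not match the reference")
    call_pileup(p, params, reference = refv)
  })
}

#' Assemble called variants across individuals
#'
#' A position enters the table iff at least one individual carries a called
#' non-reference allele there. Adjacent SNVs carried on the same
#' individual's haplotype at contiguous positions are merged into one MNV
#' row. Positions on the numt-ambiguous exclusion list are retained but
#' flagged `excluded` and are omitted from downstream segregating-site
#' totals.
#'
#' @param pileups named list of per-individual pileups, or `NULL` when
#'   `calls` is given.
#' @param reference reference sequence (string or character vector).
#' @param params [caller_params()]
#' @param numt_exclude integer positions that cannot be ruled out as numts.
#' @param annotation optional [gene_annotation()] for consequence calls.
#' @param calls optional precomputed [call_pileup()] list.
#' @param merge_mnv merge contiguous same-haplotype SNVs into MNVs.
#' @return `variant_table` data.frame: `position`, `ref`, `alt`, `type`,
#'   `frequency`, `zygosity`, `consequence`, `mean_quality`, `excluded`,
#'   `reason`; attribute `genotypes` holds the per-individual carrier lists.
#' @export
call_variants <- function(pileups, reference, params = caller_params(),
                          numt_exclude = integer(0), annotation = NULL,
                          calls = NULL, merge_mnv = TRUE) {
  refv <- as_ref_vector(reference)
  if (is.null(calls)) calls <- call_all_individuals(pileups, reference, params)
  n_ind <- length(calls)
  per_site <- list()
  for (ind in names(calls)) {
    cc <- calls[[ind]]
    ok <- cc$status == "called"
    hom_alt <- ok & cc$zygosity == "homoplasmic" & cc$allele1 != refv[cc$pos]
    het <- ok & cc$zygosity == "heteroplasmic"
    for (i in which(hom_alt | het)) {
      alts <- setdiff(c(cc$allele1[i], cc$allele2[i]), c(refv[cc$pos[i]], NA))
      if (!length(alts)) next
      per_site[[length(per_site) + 1L]] <- data.frame(
        position = cc$pos[i], individual = ind,
        alt = alts[1L],
        zygosity = cc$zygosity[i],
        mean_quality = mean(c(cc$meanQ1[i], cc$meanQ2[i]), na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(per_site)) {
    out <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0), type = character(0),
                      frequency = numeric(0), zygosity = character(0),
                      consequence = character(0), mean_quality = numeric(0),
                      excluded = logical(0), reason = character(0))
    class(out) <- c("variant_table", "data.frame")
    return(out)
  }
  carriers <- do.call(rbind, per_site)
  rows <- lapply(split(carriers, carriers$position), function(cs) {
    p <- cs$position[1L]
    alts <- sort(unique(cs$alt))
    data.frame(position = p, ref = refv[p], alt = paste(alts, collapse = ","),
               type = if (any(alts == "-") || refv[p] == "-") "indel" else "SNV",
               frequency = nrow(cs) / n_ind,
               zygosity = if (any(cs$zygosity == "heteroplasmic"))
                 "heteroplasmic" else "homoplasmic",
               mean_quality = mean(cs$mean_quality),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$position), ]
  rownames(tab) <- NULL

  if (merge_mnv && nrow(tab) > 1L) {
    tab <- merge_adjacent_mnv(tab, carriers, refv)
  }
  tab$consequence <- NA_character_
  if (!is.null(annotation)) {
    ref_str <- paste(refv, collapse = "")
    for (i in which(tab$type == "SNV")) {
      a1 <- strsplit(tab$alt[i], ",")[[1]][1L]
      if (tab$ref[i] %in% BASES && a1 %in% BASES)
        tab$consequence[i] <- classify_site_effect(
          c(tab$ref[i], a1), tab$position[i], annotation, ref_str)
    }
  }
  tab$excluded <- tab$position %in% numt_exclude
  tab$reason <- ifelse(tab$excluded, "numt_ambiguous", NA_character_)
  attr(tab, "genotypes") <- carriers
  class(tab) <- c("variant_table", "data.frame")
  tab
}

# Merge runs of contiguous positions where one individual carries
# non-reference alleles at every position of the run.
merge_adjacent_mnv <- function(tab, carriers, refv) {
  drop <- logical(nrow(tab))
  i <- 1L
  while (i < nrow(tab)) {
    j <- i
    while (j < nrow(tab) && tab$position[j + 1L] == tab$position[j] + 1L &&
           tab$type[j + 1L] == "SNV" && tab$type[j] %in% c("SNV", "MNV")) {
      run_pos <- tab$position[i:(j + 1L)]
      shared <- Reduce(intersect, lapply(run_pos, function(p)
        carriers$individual[carriers$position == p]))
      if (length(shared) == 0L) break
      j <- j + 1L
    }
    if (j > i) {
      tab$alt[i] <- paste(vapply(tab$alt[i:j],
                                 function(a) strsplit(a, ",")[[1]][1L], ""),
                          collapse = "")
      tab$ref[i] <- paste(refv[tab$position[i:j]], collapse = "")
      tab$type[i] <- "MNV"
      drop[(i + 1L):j] <- TRUE
    }
    i <- j + 1L
  }
  tab <- tab[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Tabulate gross/micro heteroplasmy calls across individuals
#'
#' @inheritParams call_variants
#' @return data.frame: `individual`, `position`, `major_allele`,
#'   `minor_allele`, `maf`, `class`.
#' @export
heteroplasmy_calls <- function(pileups, reference, params = caller_params(),
                               calls = NULL) {
  if (is.null(calls)) calls <- call_all_individuals(pileups, reference, params)
  out <- list()
  for (ind in names(calls)) {
    cc <- calls[[ind]]
    het <- cc[cc$status == "called" & cc$zygosity == "heteroplasmic", ,
              drop = FALSE]
    for (i in seq_len(nrow(het))) {
      cl <- classify_heteroplasmy(het[i, ], params)
      out[[length(out) + 1L]] <- data.frame(
        individual = ind, position = het$pos[i],
        major_allele = het$allele1[i], minor_allele = het$allele2[i],
        maf = cl$maf, class = cl$class, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(individual = character(0), position = integer(0),
                      major_allele = character(0), minor_allele = character(0),
                      maf = numeric(0), class = character(0)))
  do.call(rbind, out)
}

#' Build the phased haplotype alignment from pileups
#'
#' Each individual contributes its major haplotype; individuals with gross
#' heteroplasmy additionally contribute the phased minor haplotype
#' ([phase_intraindividual_haplotypes()]).
#'
#' @inheritParams call_variants
#' @param labels optional metadata data.frame joined by individual id.
#' @return [mito_alignment()]
#' @export
assemble_haplotypes <- function(pileups, reference, params = caller_params(),
                                calls = NULL, labels = NULL) {
  refv <- as_ref_vector(reference)
  if (is.null(calls)) calls <- call_all_individuals(pileups, reference, params)
  seqs <- list(); meta <- list()
  for (ind in names(calls)) {
    ph <- phase_intraindividual_haplotypes(calls[[ind]], refv, params)
    seqs[[ind]] <- ph$major
    meta[[length(meta) + 1L]] <- data.frame(id = ind, individual = ind,
                                            is_minor = FALSE)
    if (!is.null(ph$minor) && any(ph$minor != ph$major)) {
      mid <- paste0(ind, "m")
      seqs[[mid]] <- ph$minor
      meta[[length(meta) + 1L]] <- data.frame(id = mid, individual = ind,
                                              is_minor = TRUE)
    }
  }
  mat <- do.call(rbind, seqs)
  md <- do.call(rbind, meta)
  if (!is.null(labels)) {
    j <- match(md$individual, labels$individual %||% labels$id)
    for (col in intersect(names(labels), c("group", "subspecies", "ecoregion")))
      md[[col]] <- labels[[col]][j]
  }
  aln <- mito_alignment(mat, NULL)
  for (col in names(md)) aln$meta[[col]] <- md[[col]]
  aln
}

#' Write a minimal VCF 4.2 with heteroplasmy as AF
#'
#' @param tab [call_variants()] result.
#' @param path output path.
#' @param chrom CHROM value (mitogenome id).
#' @export
write_vcf <- function(tab, path, chrom = "mitogenome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", chrom, ">"),
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency (heteroplasmic fraction where applicable)\">",
               "##FILTER=<ID=numt_ambiguous,Description=\"Possible nuclear mitochondrial insertion\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(tab))) {
    ref <- tab$ref[i]; alt <- tab$alt[i]
    # VCF has no symbolic single-base gap; encode deletions with anchor base
    if (grepl("-", alt, fixed = TRUE) || grepl("-", ref, fixed = TRUE)) {
      alt <- gsub("-", "*", alt, fixed = TRUE)
      ref <- gsub("-", "*", ref, fixed = TRUE)
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.0f\t%s\tAF=%.4f",
                       chrom, tab$position[i], ref, alt,
                       tab$mean_quality[i],
                       ifelse(tab$excluded[i], tab$reason[i], "PASS"),
                       tab$frequency[i]), con)
  }
  invisible(path)
}
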