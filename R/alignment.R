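#' Gapped mitogenome multiple alignment with per-sequence metadata
#'
#' Sequences are stored as a character matrix over {A,C,G,T,-,N} with one
#' row per haplotype; coordinates are 1-based inclusive alignment columns
#' (the circular genome is handled linearized, regions never wrap). Each
#' individual contributes one sequence, or two when it carries a gross
#' heteroplasmy (the minor-allele haplotype is flagged).
#'
#' @param sequences named character vector of equal-length gapped sequences,
#'   or a character matrix with one row per sequence.
#' @param meta optional data.frame with columns among `id`, `individual`,
#'   `group`, `subspecies`, `ecoregion`, `is_minor`, joined by `id`.
#' @return object of class `mito_alignment` with elements `seq` (matrix)
#'   and `meta`.
#' @export
mito_alignment <- function(sequences, meta = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(rownames(mat))) rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  } else {
    if (is.null(names(sequences)))
      names(sequences) <- paste0("seq", seq_along(sequences))
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop_mitopop("alignment is ragged: sequence lengths ",
                   paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(mat) <- names(sequences)
  }
  ids <- rownames(mat)
  if (anyDuplicated(ids)) stop_mitopop("duplicate sequence ids")
  bad <- setdiff(unique(as.vector(mat)), c(ALLELES, "N"))
  if (length(bad)) stop_mitopop("invalid characters: ", paste(bad, collapse = ""))
  m <- data.frame(id = ids, individual = ids, group = NA_integer_,
                  subspecies = NA_character_, ecoregion = NA_character_,
                  is_minor = FALSE, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    if (!"id" %in% names(meta)) stop_mitopop("labels need an 'id' column")
    j <- match(ids, meta$id)
    for (col in intersect(names(meta), names(m)[-1])) {
      hit <- !is.na(j)
      m[[col]][hit] <- meta[[col]][j[hit]]
    }
    m$is_minor <- isTRUE_vec(m$is_minor)
  }
  structure(list(seq = mat, meta = m), class = "mito_alignment")
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x %in% c("TRUE", "true", "1", "yes", 1)
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("mito_alignment:", nrow(x$seq), "sequences x", ncol(x$seq), "columns;",
      sum(x$meta$is_minor), "heteroplasmic minor haplotypes\n")
  invisible(x)
}

n_seq <- function(aln) nrow(aln$seq)
aln_length <- function(aln) ncol(aln$seq)

#' Read a FASTA alignment with optional label table
#'
#' @param path FASTA file of equal-length (gapped) sequences.
#' @param labels optional TSV path or data.frame with an `id` column and any
#'   of `individual`, `group`, `subspecies`, `ecoregion`, `is_minor`.
#' @return [mito_alignment()]
#' @export
read_alignment <- function(path, labels = NULL) {
  dss <- Biostrings::readBStringSet(path)
  seqs <- as.character(dss)
  if (is.character(labels)) labels <- utils::read.delim(labels, sep = "\t")
  mito_alignment(seqs, meta = labels)
}

#' Write an alignment and its labels
#' @param aln [mito_alignment()]
#' @param path FASTA output path.
#' @param labels_path optional TSV path for the metadata table.
#' @export
write_alignment <- function(aln, path, labels_path = NULL) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  if (!is.null(labels_path))
    utils::write.table(aln$meta, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Define an alignment region (1-based, inclusive)
#' @param name region name.
#' @param start,end first and last alignment column.
#' @export
region_spec <- function(name, start, end) {
  start <- check_count(start, "start"); end <- check_count(end, "end")
  if (start < 1L || end < start) stop_mitopop("invalid region ", name)
  structure(list(name = name, start = start, end = end), class = "region_spec")
}

#' Extract an alignment region
#'
#' Slices columns `start..end`. With `drop_invariant_minors`, any
#' minor-flagged haplotype identical to its individual's major haplotype
#' within the region is removed: a heteroplasmic minor only counts as an
#' extra sampled haplotype when one of its heteroplasmic sites falls inside
#' the fragment, which is what makes fragment sample sizes differ.
#'
#' @param aln [mito_alignment()]
#' @param region [region_spec()]
#' @param drop_invariant_minors remove minors invariant within the region.
#' @export
extract_region <- function(aln, region, drop_invariant_minors = FALSE) {
  if (region$end > aln_length(aln))
    stop_mitopop("region ", region$name, " out of alignment bounds")
  mat <- aln$seq[, region$start:region$end, drop = FALSE]
  meta <- aln$meta
  if (drop_invariant_minors && any(meta$is_minor)) {
    drop <- logical(nrow(mat))
    for (i in which(meta$is_minor)) {
      maj <- which(meta$individual == meta$individual[i] & !meta$is_minor)
      if (length(maj) == 1L && all(mat[i, ] == mat[maj, ])) drop[i] <- TRUE
    }
    mat <- mat[!drop, , drop = FALSE]
    meta <- meta[!drop, , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(seq = mat, meta = meta), class = "mito_alignment")
}

#' Gene annotation table
#'
#' @param df data.frame with columns `name`, `start`, `end`, `strand`
#'   (+/-), `kind` (protein/tRNA/rRNA/D-loop) and optional `frameshift_pos`
#'   (a single inserted base skipped before translation, as in the avian
#'   ND3 frameshift).
#' @param genome_length optional bound check.
#' @export
gene_annotation <- function(df, genome_length = NULL) {
  need <- c("name", "start", "end", "strand", "kind")
  if (!all(need %in% names(df)))
    stop_mitopop("annotation needs columns ", paste(need, collapse = ", "))
  if (!"frameshift_pos" %in% names(df)) df$frameshift_pos <- NA_integer_
  if (any(df$start < 1L) || any(df$end < df$start))
    stop_mitopop("invalid annotation intervals")
  if (!is.null(genome_length) && any(df$end > genome_length))
    stop_mitopop("annotation exceeds genome length")
  for (i in which(df$kind == "protein")) {
    len <- df$end[i] - df$start[i] + 1L - !is.na(df$frameshift_pos[i])
    if (len %% 3L != 0L)
      stop_mitopop("protein gene ", df$name[i],
                   " length not divisible by 3 after frameshift rule")
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a BED-like TSV annotation (1-based inclusive coordinates)
#' @param path TSV with the [gene_annotation()] columns.
#' @export
read_annotation <- function(path) {
  gene_annotation(utils::read.delim(path, sep = "\t",
                                    stringsAsFactors = FALSE))
}
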