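# Vertebrate mitochondrial genetic code (NCBI transl_table=2, SGC1):
# AGA/AGG are stops, ATA = Met, TGA = Trp.
mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("SGC1")
    code
  }
})

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

translate_codons <- function(nt) {
  stopifnot(nchar(nt) %% 3L == 0L)
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  aa <- unname(mito_code()[codons])
  aa[is.na(aa)] <- "X"   # codons containing N or gap
  aa
}

#' Translate a protein-coding mitochondrial gene
#'
#' Translation uses the vertebrate mitochondrial code. If the gene carries a
#' `frameshift_pos` (a single inserted base, as in the avian ND3 gene), that
#' base is skipped before translation; minus-strand genes are
#' reverse-complemented first. An internal stop codon is flagged with a
#' warning marker rather than being fatal.
#'
#' @param seq full-length ungapped nucleotide string the gene coordinates
#'   refer to (may also be exactly the gene sequence if the record spans it).
#' @param gene one row of a [gene_annotation()] table (list or 1-row
#'   data.frame with `start`, `end`, `strand`, `kind`, `frameshift_pos`).
#' @return amino-acid string; attribute `internal_stop` is TRUE when a stop
#'   occurs before the final codon.
#' @export
translate_gene <- function(seq, gene) {
  if (gene$kind != "protein") stop_mitopop("translate_gene needs a protein gene")
  nt <- substr(seq, gene$start, gene$end)
  fs <- gene$frameshift_pos
  if (!is.null(fs) && length(fs) == 1L && !is.na(fs)) {
    k <- fs - gene$start + 1L
    if (k >= 1L && k <= nchar(nt))
      nt <- paste0(substr(nt, 1L, k - 1L), substr(nt, k + 1L, nchar(nt)))
  }
  if (identical(gene$strand, "-")) nt <- revcomp(nt)
  aa <- translate_codons(nt)
  prot <- paste(aa, collapse = "")
  internal <- length(aa) > 1L && any(aa[-length(aa)] == "*")
  if (internal) warning("internal stop codon in ", gene$name %||% "gene")
  structure(prot, internal_stop = internal)
}

# Map an alignment position into (gene row index, codon-relative info) or
# NULL when the position is untranslated.
locate_in_protein <- function(position, annotation) {
  prot <- annotation[annotation$kind == "protein", , drop = FALSE]
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    if (position >= g$start && position <= g$end) {
      fs <- g$frameshift_pos
      has_fs <- !is.na(fs)
      if (has_fs && position == fs) return(NULL)  # the skipped base itself
      if (g$strand == "+") {
        off <- position - g$start - (has_fs && position > fs)
      } else {
        off <- g$end - position - (has_fs && position < fs)
      }
      return(list(gene = g, codon_index = off %/% 3L, codon_pos = off %% 3L))
    }
  }
  NULL
}

# Reconstruct the codon containing `position` from a context haplotype,
# returning the three genome positions (in gene reading order) and bases.
codon_context <- function(position, annotation, context_haplotype) {
  loc <- locate_in_protein(position, annotation)
  if (is.null(loc)) return(NULL)
  g <- loc$gene
  fs <- g$frameshift_pos
  has_fs <- !is.na(fs)
  # translated positions of the gene in reading order
  pos_all <- g$start:g$end
  if (has_fs) pos_all <- pos_all[pos_all != fs]
  if (g$strand == "-") pos_all <- rev(pos_all)
  idx <- loc$codon_index * 3L + 1:3
  pos3 <- pos_all[idx]
  bases <- substring(context_haplotype, pos3, pos3)
  if (g$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  list(gene = g, positions = pos3, bases = bases,
       within = which(pos3 == position))
}

#' Classify a substitution as synonymous, nonsynonymous or noncoding
#'
#' The codon containing the position is read from `context_haplotype`; the
#' two alleles are substituted in turn and the resulting amino acids
#' (vertebrate mitochondrial code) compared.
#'
#' @param alleles character vector of the two alleles (A/C/G/T).
#' @param position 1-based alignment position.
#' @param annotation [gene_annotation()] table.
#' @param context_haplotype ungapped full-length sequence giving the codon
#'   context.
#' @return one of "synonymous", "nonsynonymous", "noncoding".
#' @export
classify_site_effect <- function(alleles, position, annotation,
                                 context_haplotype) {
  if (!all(alleles %in% BASES))
    stop_mitopop("alleles must be nucleotides, got ",
                 paste(alleles, collapse = "/"))
  if (substring(context_haplotype, position, position) == "-")
    stop_mitopop("position ", position, " is a gap in the context haplotype")
  ctx <- codon_context(position, annotation, context_haplotype)
  if (is.null(ctx)) return("noncoding")
  aa <- vapply(alleles, function(a) {
    b <- ctx$bases
    b[ctx$within] <- if (ctx$gene$strand == "-") chartr("ACGT", "TGCA", a) else a
    unname(mito_code()[paste(b, collapse = "")]) %||% "X"
  }, "")
  if (any(is.na(aa)) || any(aa == "X")) return("noncoding")
  if (aa[1] == aa[2]) "synonymous" else "nonsynonymous"
}
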