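# McDonald-Kreitman tests: per-gene and multilocus 2x2 contrasts of
# nonsynonymous/synonymous polymorphism vs fixed divergence between the two
# lineages, with optional Jukes-Cantor correction of the divergence counts.

# translated genome positions of a protein gene in reading order
gene_reading_positions <- function(g) {
  pos <- g$start:g$end
  if (!is.na(g$frameshift_pos)) pos <- pos[pos != g$frameshift_pos]
  if (g$strand == "-") pos <- rev(pos)
  pos
}

codon_aa <- function(codon) {
  a <- unname(mito_code()[codon])
  if (is.na(a)) "X" else a
}

# synonymous site counts for all 64 codons, computed once
syn_sites_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
    tab <<- vapply(codons, function(codon) {
      b <- strsplit(codon, "")[[1]]
      aa0 <- codon_aa(codon)
      s <- 0
      for (p in 1:3) for (x in setdiff(BASES, b[p])) {
        b2 <- b; b2[p] <- x
        if (codon_aa(paste(b2, collapse = "")) == aa0) s <- s + 1 / 3
      }
      s
    }, 1)
    tab
  }
})

codon_syn_sites <- function(codon) {
  if (codon_aa(codon) == "X") return(NA_real_)
  unname(syn_sites_table()[codon])
}

majority_char <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1L]
}

# classify all variable positions of one gene; returns counts and site totals
mkt_gene_counts <- function(mat, g1_rows, g2_rows, gene) {
  pos <- gene_reading_positions(gene)
  sub <- mat[, pos, drop = FALSE]
  if (gene$strand == "-") sub[] <- chartr("ACGT", "TGCA", sub)
  n_codons <- length(pos) %/% 3L
  Pn <- Ps <- Dn <- Ds <- 0L
  sites_s <- 0
  used_codons <- 0L
  nr <- nrow(sub)
  for (ci in seq_len(n_codons)) {
    idx <- (ci - 1L) * 3L + 1:3
    block <- sub[, idx, drop = FALSE]
    if (any(!block %in% BASES)) next   # gap or N anywhere: codon excluded
    invariant <- all(block == rep(block[1L, ], each = nr))
    cons <- if (invariant) paste(block[1L, ], collapse = "")
            else paste(apply(block, 2L, majority_char), collapse = "")
    syn_ci <- codon_syn_sites(cons)
    if (is.na(syn_ci)) next
    used_codons <- used_codons + 1L
    sites_s <- sites_s + syn_ci
    if (invariant) next
    for (p in 1:3) {
      a1 <- unique(block[g1_rows, p]); a2 <- unique(block[g2_rows, p])
      all_a <- unique(c(a1, a2))
      if (length(all_a) < 2L) next
      # the two most frequent alleles define the contrast
      tb <- sort(table(block[, p]), decreasing = TRUE)
      pair <- names(tb)[1:2]
      b_ref <- strsplit(cons, "")[[1]]
      aa <- vapply(pair, function(x) {
        b2 <- b_ref; b2[p] <- x; codon_aa(paste(b2, collapse = ""))
      }, "")
      nonsyn <- aa[1L] != aa[2L]
      if (length(intersect(a1, a2)) == 0L) {
        if (nonsyn) Dn <- Dn + 1L else Ds <- Ds + 1L
      } else if (length(a1) > 1L || length(a2) > 1L) {
        if (nonsyn) Pn <- Pn + 1L else Ps <- Ps + 1L
      }
    }
  }
  list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
       sites_s = sites_s, sites_n = 3 * used_codons - sites_s)
}

jc_transform <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

mkt_row <- function(gene_name, cnt, jc_correct) {
  Dn <- cnt$Dn; Ds <- cnt$Ds
  if (jc_correct) {
    if (cnt$sites_n > 0 && Dn > 0)
      Dn <- jc_transform(cnt$Dn / cnt$sites_n) * cnt$sites_n
    if (cnt$sites_s > 0 && Ds > 0)
      Ds <- jc_transform(cnt$Ds / cnt$sites_s) * cnt$sites_s
  }
  alpha <- if (is.na(Dn) || Dn * cnt$Ps == 0) NA_real_
           else 1 - (Ds * cnt$Pn) / (Dn * cnt$Ps)
  ni <- if (is.na(Ds) || cnt$Ps == 0 || Dn == 0 || Ds == 0) NA_real_
        else (cnt$Pn / cnt$Ps) / (Dn / Ds)
  tb <- matrix(round(c(cnt$Pn, cnt$Ps, Dn, Ds)), 2L, 2L)
  p <- if (any(is.na(tb))) NA_real_ else stats::fisher.test(tb)$p.value
  data.frame(gene = gene_name, Pn = cnt$Pn, Ps = cnt$Ps,
             Dn_raw = cnt$Dn, Ds_raw = cnt$Ds,
             Dn = Dn, Ds = Ds, alpha = alpha, neutrality_index = ni,
             p = p, stringsAsFactors = FALSE)
}

#' Standard and multilocus McDonald-Kreitman tests
#'
#' Per protein-coding gene, each variable codon position is classified as
#' polymorphic (variable within either group) or fixed (the groups share no
#' allele) and as synonymous or nonsynonymous against the gene's majority
#' codon context; codons containing a gap or N in any included sequence are
#' excluded. The multilocus test sums counts across genes. alpha =
#' 1 - (Ds Pn)/(Dn Ps) is the proportion of adaptive substitutions;
#' significance is Fisher's exact two-tailed test of the 2x2 table.
#'
#' @param aln [mito_alignment()] with phased minors.
#' @param partition named vector individual -> group.
#' @param annotation [gene_annotation()]
#' @param genes gene names to test, default all protein genes.
#' @param jc_correct Jukes-Cantor-correct the divergence counts (per-class
#'   divergence proportions are corrected and rescaled to counts).
#' @param include_minors include heteroplasmic minor haplotypes (the test is
#'   run both ways in the headline analysis; minors are singleton
#'   polymorphism, so divergence counts are unchanged).
#' @return data.frame of per-gene rows plus a final `multilocus` row.
#' @export
mkt <- function(aln, partition, annotation, genes = NULL, jc_correct = TRUE,
                include_minors = TRUE) {
  prot <- annotation[annotation$kind == "protein", , drop = FALSE]
  if (!is.null(genes)) prot <- prot[prot$name %in% genes, , drop = FALSE]
  if (nrow(prot) == 0L) stop_mitopop("no protein genes selected")
  keep <- if (include_minors) seq_len(n_seq(aln)) else which(!aln$meta$is_minor)
  mat <- aln$seq[keep, , drop = FALSE]
  g <- partition[aln$meta$individual[keep]]
  if (any(is.na(g))) stop_mitopop("partition is missing individuals")
  grps <- sort(unique(g))
  if (length(grps) != 2L) stop_mitopop("need two nonempty groups")
  g1 <- which(g == grps[1L]); g2 <- which(g == grps[2L])
  rows <- list(); tot <- list(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L,
                              sites_s = 0, sites_n = 0)
  for (i in seq_len(nrow(prot))) {
    cnt <- mkt_gene_counts(mat, g1, g2, prot[i, ])
    rows[[i]] <- mkt_row(prot$name[i], cnt, jc_correct)
    for (f in names(tot)) tot[[f]] <- tot[[f]] + cnt[[f]]
  }
  rows[[length(rows) + 1L]] <- mkt_row("multilocus", tot, jc_correct)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
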