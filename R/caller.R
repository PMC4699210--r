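# Probabilistic per-site calling from strand-split allele counts.
#
# Site states: 5 homoplasmic (A, C, G, T, gap) plus the 10 unordered
# heteroplasmic pairs, flat prior. Reads of allele x are scored with the
# allele's mean-quality error probability e_x = 10^(-meanQ_x/10):
# P(x | homoplasmic b) = 1 - e_x when x == b, else e_x/4. A heteroplasmic
# state {a, b} is scored with the mixture fraction integrated out under a
# uniform prior (a Beta marginal over the two allele counts): this is what
# lets a single error read lose to the homoplasmic state while a genuine
# 20-50% minor wins overwhelmingly, instead of the empirical-fraction
# likelihood that would overfit every stray error read. The reported minor
# fraction is still the observed count fraction. The reported posterior is
# that of the winning state.

STATE_PAIRS <- utils::combn(5L, 2L)

# Vectorised log-likelihoods: counts and err are L x 5 matrices.
state_logliks <- function(counts, err) {
  L <- nrow(counts)
  logE <- log(err / 4)
  term_err <- counts * logE
  term_err[counts == 0L] <- 0
  base_sum <- rowSums(term_err)
  ll <- matrix(-Inf, L, 15L)
  for (b in 1:5) {
    t_hit <- counts[, b] * log1p(-err[, b])
    t_hit[counts[, b] == 0L] <- 0
    ll[, b] <- base_sum - term_err[, b] + t_hit
  }
  for (s in 1:10) {
    a <- STATE_PAIRS[1L, s]; b <- STATE_PAIRS[2L, s]
    tot <- counts[, a] + counts[, b]
    # reads of the pair come from the mixture, others are errors;
    # integral over the uniform mixture fraction = Beta(n_a+1, n_b+1)
    lls <- base_sum - term_err[, a] - term_err[, b] +
      lbeta(counts[, a] + 1, counts[, b] + 1)
    lls[tot == 0L] <- -Inf
    ll[, 5L + s] <- lls
  }
  ll
}

state_alleles <- function(s) {
  if (s <= 5L) s else STATE_PAIRS[, s - 5L]
}

# argmax + posterior over an allowed subset of states, rowwise
best_state <- function(ll, allowed) {
  ll2 <- ll
  ll2[!allowed] <- -Inf
  win <- max.col(ll2, ties.method = "first")
  mx <- ll2[cbind(seq_len(nrow(ll2)), win)]
  post <- exp(ll2 - mx)
  post[!is.finite(post)] <- 0
  list(win = win, posterior = 1 / rowSums(post))
}

pileup_matrices <- function(pileup) {
  nm <- c("A", "C", "G", "T", "gap")
  fwd <- as.matrix(pileup[paste0(nm, "_fwd")])
  rev <- as.matrix(pileup[paste0(nm, "_rev")])
  q <- as.matrix(pileup[paste0("meanQ_", nm)])
  list(fwd = fwd, rev = rev, counts = fwd + rev, q = q)
}

#' Call all sites of one individual's pileup
#'
#' Applies, in order: the minimum-coverage rule, a per-allele mean-quality
#' filter, maximum-posterior state selection, the both-strands requirement
#' for variant alleles (a winning state containing a strand-failing variant
#' allele falls back to the best state without it, with status
#' `no_call_strand`), and the posterior threshold.
#'
#' @param pileup per-individual pileup data.frame (see [simulate_pileups()]).
#' @param params [caller_params()]
#' @param reference optional reference sequence (string or character
#'   vector); when given, the strand rule applies to non-reference alleles,
#'   otherwise to non-majority alleles.
#' @return data.frame with one row per site: `pos`, `coverage`, `status`,
#'   `zygosity`, `allele1`, `allele2`, `frac1`, `frac2`, `posterior`,
#'   `meanQ1`, `meanQ2`.
#' @export
call_pileup <- function(pileup, params = caller_params(), reference = NULL) {
  pm <- pileup_matrices(pileup)
  counts <- pm$counts
  L <- nrow(counts)
  cov <- rowSums(counts)
  err <- 10^(-pm$q / 10)
  err[is.na(err)] <- 1e-3           # unused: zero-count alleles only
  err[err >= 0.75] <- 0.74          # keep 1 - e positive
  ll <- state_logliks(counts, err)
  # state prior: heteroplasmy mass het_prior over the 10 pair states
  lp <- c(rep(log((1 - params$het_prior) / 5), 5L),
          rep(log(params$het_prior / 10), 10L))
  ll <- sweep(ll, 2L, lp, `+`)

  # allele-level masks
  low_q <- counts > 0L & !is.na(pm$q) & pm$q < params$min_mean_quality
  top <- max.col(counts, ties.method = "first")
  if (is.null(reference)) {
    is_variant <- col(counts) != top
  } else {
    refv <- if (length(reference) == 1L) strsplit(reference, "")[[1]] else reference
    refv <- refv[pileup$pos]
    is_variant <- col(counts) != match(refv, ALLELES)
  }
  strand_bad <- counts > 0L & !(pm$fwd > 0L & pm$rev > 0L) & is_variant &
    params$require_both_strands

  state_ok <- function(allele_bad) {
    ok <- matrix(TRUE, L, 15L)
    for (s in 1:15) {
      al <- state_alleles(s)
      ok[, s] <- !rowSums(allele_bad[, al, drop = FALSE])
    }
    ok
  }
  allowed1 <- state_ok(low_q)
  b1 <- best_state(ll, allowed1)
  # does the winner contain a strand-failing variant allele?
  win_has_bad <- vapply(seq_len(L), function(i) {
    any(strand_bad[i, state_alleles(b1$win[i])])
  }, NA)
  res_win <- b1$win
  res_post <- b1$posterior
  status <- rep("called", L)
  if (any(win_has_bad)) {
    allowed2 <- allowed1 & state_ok(strand_bad)
    b2 <- best_state(ll, allowed2)
    res_win[win_has_bad] <- b2$win[win_has_bad]
    res_post[win_has_bad] <- b2$posterior[win_has_bad]
    status[win_has_bad] <- "no_call_strand"
  }
  low_post <- status == "called" & res_post < params$posterior_threshold
  status[low_post] <- "no_call_low_posterior"
  status[cov < params$min_coverage] <- "no_call_low_coverage"

  a1 <- a2 <- rep(NA_integer_, L)
  hom <- res_win <= 5L
  a1[hom] <- res_win[hom]
  prs <- STATE_PAIRS[, pmax(res_win - 5L, 1L), drop = FALSE]
  i2 <- which(!hom)
  if (length(i2)) {
    pa <- prs[1L, i2]; pb <- prs[2L, i2]
    ca <- counts[cbind(i2, pa)]; cb <- counts[cbind(i2, pb)]
    swap <- cb > ca
    a1[i2] <- ifelse(swap, pb, pa)
    a2[i2] <- ifelse(swap, pa, pb)
  }
  n1 <- counts[cbind(seq_len(L), pmax(a1, 1L))]
  n2 <- ifelse(is.na(a2), 0L, counts[cbind(seq_len(L), pmax(a2, 1L, na.rm = TRUE))])
  frac1 <- ifelse(is.na(a2), 1, n1 / pmax(n1 + n2, 1L))
  frac2 <- ifelse(is.na(a2), NA_real_, n2 / pmax(n1 + n2, 1L))
  nocov <- status == "no_call_low_coverage"
  zyg <- ifelse(is.na(a2), "homoplasmic", "heteroplasmic")
  data.frame(
    pos = pileup$pos, coverage = cov, status = status,
    zygosity = ifelse(nocov, NA_character_, zyg),
    allele1 = ifelse(nocov, NA_character_, ALLELES[a1]),
    allele2 = ifelse(nocov | is.na(a2), NA_character_, ALLELES[pmax(a2, 1L)]),
    frac1 = ifelse(nocov, NA_real_, frac1),
    frac2 = ifelse(nocov, NA_real_, frac2),
    posterior = ifelse(nocov, NA_real_, res_post),
    meanQ1 = ifelse(nocov, NA_real_, pm$q[cbind(seq_len(L), pmax(a1, 1L))]),
    meanQ2 = ifelse(nocov | is.na(a2), NA_real_,
                    pm$q[cbind(seq_len(L), pmax(a2, 1L, na.rm = TRUE))]),
    stringsAsFactors = FALSE)
}

#' Call a single pileup row
#' @param pileup_row one-row pileup data.frame.
#' @inheritParams call_pileup
#' @param ref_allele optional reference allele at the site.
#' @return one-row data.frame as in [call_pileup()].
#' @export
call_site <- function(pileup_row, params = caller_params(), ref_allele = NULL) {
  if (any(pileup_matrices(pileup_row)$counts < 0L))
    stop_mitopop("negative counts")
  reference <- NULL
  if (!is.null(ref_allele)) {
    reference <- rep("N", max(pileup_row$pos))
    reference[pileup_row$pos] <- ref_allele
  }
  call_pileup(pileup_row, params, reference = reference)
}

#' Classify a heteroplasmic site call
#'
#' @param call one-row [call_pileup()] result with heteroplasmic zygosity.
#' @param params [caller_params()]
#' @return list with `maf` and `class` in gross / micro / indeterminate.
#' @export
classify_heteroplasmy <- function(call, params = caller_params()) {
  if (!identical(call$zygosity, "heteroplasmic"))
    stop_mitopop("classify_heteroplasmy needs a heteroplasmic call")
  maf <- min(call$frac1, call$frac2)
  cls <- if (maf >= params$gross_maf_min) "gross"
         else if (maf <= params$micro_maf_max) "micro"
         else "indeterminate"
  list(maf = maf, class = cls)
}

#' Phase the intra-individual haplotypes of one individual
#'
#' The major haplotype is the maximum-posterior consensus: it takes the
#' majority allele at every covered site, including sites whose posterior
#' falls below the variant-confidence threshold (the threshold governs
#' variant reporting, not consensus -- falling back to the reference there
#' would bias the haplotype toward the reference). With no gross
#' heteroplasmic site the individual contributes that single haplotype;
#' otherwise the minor haplotype carries all minority alleles (the
#' two-genome mixture model). A site whose minority allele is the reference
#' while the individual's other heteroplasmic minorities are alternatives
#' contradicts a single mixture and is flagged `frequency_conflict` and
#' excluded from phasing.
#'
#' @param calls [call_pileup()] result for one individual.
#' @param reference reference sequence (string or character vector).
#' @param params [caller_params()]
#' @return list: `major`, `minor` (character vectors; `minor` NULL when
#'   homoplasmic), `het_sites` (data.frame with `pos`, `major_allele`,
#'   `minor_allele`, `maf`, `conflict`).
#' @export
phase_intraindividual_haplotypes <- function(calls, reference,
                                             params = caller_params()) {
  refv <- if (length(reference) == 1L) strsplit(reference, "")[[1]] else reference
  major <- refv
  covered <- calls[calls$status != "no_call_low_coverage" &
                     !is.na(calls$allele1), , drop = FALSE]
  major[covered$pos] <- covered$allele1
  called <- calls[calls$status == "called", , drop = FALSE]
  het <- called[called$zygosity == "heteroplasmic", , drop = FALSE]
  if (nrow(het)) {
    cls <- vapply(seq_len(nrow(het)), function(i)
      classify_heteroplasmy(het[i, ], params)$class, "")
    het <- het[cls == "gross", , drop = FALSE]
  }
  if (nrow(het) == 0L)
    return(list(major = major, minor = NULL,
                het_sites = data.frame(pos = integer(0),
                                       major_allele = character(0),
                                       minor_allele = character(0),
                                       maf = numeric(0),
                                       conflict = logical(0))))
  hs <- data.frame(pos = het$pos, major_allele = het$allele1,
                   minor_allele = het$allele2,
                   maf = pmin(het$frac1, het$frac2),
                   conflict = FALSE, stringsAsFactors = FALSE)
  minor_is_ref <- hs$minor_allele == refv[hs$pos]
  if (any(minor_is_ref) && any(!minor_is_ref)) hs$conflict <- minor_is_ref
  major[hs$pos] <- hs$major_allele
  use <- !hs$conflict
  minor <- major
  minor[hs$pos[use]] <- hs$minor_allele[use]
  list(major = major, minor = minor, het_sites = hs)
}

#' Screen heteroplasmic individuals for contamination signatures
#'
#' A cross-contaminated sample looks heteroplasmic at exactly the sites
#' where its genuine haplotype differs from the contaminant's; each
#' heteroplasmic individual's site set is therefore compared with its
#' major haplotype's full pairwise difference set against every other
#' sampled haplotype, and an exact match is reported.
#'
#' @param haplotypes [mito_alignment()] of major haplotypes (minors allowed;
#'   they are skipped as comparison targets for their own individual).
#' @param het_calls data.frame with columns `individual` and `position`.
#' @return data.frame per heteroplasmic individual: `individual`,
#'   `flagged`, `matched_id`.
#' @export
screen_contamination <- function(haplotypes, het_calls) {
  inds <- unique(het_calls$individual)
  if (length(inds) == 0L)
    return(data.frame(individual = character(0), flagged = logical(0),
                      matched_id = character(0)))
  mat <- haplotypes$seq
  meta <- haplotypes$meta
  out <- lapply(inds, function(ind) {
    hset <- sort(het_calls$position[het_calls$individual == ind])
    self <- which(meta$individual == ind & !meta$is_minor)
    if (length(self) != 1L)
      stop_mitopop("individual ", ind, " not in alignment")
    others <- setdiff(which(!meta$is_minor | meta$individual != ind), self)
    others <- setdiff(others, which(meta$individual == ind))
    for (j in others) {
      ok <- mat[self, ] != "N" & mat[j, ] != "N"
      diffs <- which(mat[self, ] != mat[j, ] & ok)
      if (length(diffs) == length(hset) && all(diffs == hset))
        return(data.frame(individual = ind, flagged = TRUE,
                          matched_id = meta$id[j], stringsAsFactors = FALSE))
    }
    data.frame(individual = ind, flagged = FALSE, matched_id = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
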