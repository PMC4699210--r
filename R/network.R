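# Median-joining haplotype networks (Bandelt, Forster & Roehl 1999 scheme):
# iterate minimum-spanning-network construction and quasi-median addition,
# with SNP columns weighted 10 and indel columns 20 by default.

# Merge runs of adjacent columns with an identical non-empty gap pattern
# into a single column (simple indel coding: one event, one character).
merge_indel_runs <- function(mat) {
  L <- ncol(mat)
  if (L < 2L) return(list(mat = mat, map = seq_len(L)))
  gap_pat <- apply(mat == "-", 2L, function(z) paste(which(z), collapse = ","))
  keep <- rep(TRUE, L)
  for (j in 2:L) {
    if (gap_pat[j] != "" && gap_pat[j] == gap_pat[j - 1L]) keep[j] <- FALSE
  }
  list(mat = mat[, keep, drop = FALSE], map = which(keep))
}

# Weighted Hamming distance matrix over columns with the given weights.
weighted_dist <- function(nodes, weights) {
  k <- nrow(nodes)
  D <- matrix(0, k, k)
  for (j in seq_len(ncol(nodes))) {
    ne <- outer(nodes[, j], nodes[, j], "!=")
    D <- D + weights[j] * ne
  }
  D
}

prim_mst <- function(D) {
  k <- nrow(D)
  if (k == 1L) return(list(edges = matrix(integer(0), 0, 2), cost = 0))
  in_tree <- c(TRUE, rep(FALSE, k - 1L))
  best <- as.numeric(D[1L, ]); parent <- rep(1L, k)
  edges <- matrix(0L, k - 1L, 2L)
  cost <- 0
  for (e in seq_len(k - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    in_tree[v] <- TRUE
    cost <- cost + best[v]
    edges[e, ] <- c(parent[v], v)
    upd <- !in_tree & D[v, ] < best
    best[upd] <- D[v, upd]
    parent[upd] <- v
  }
  list(edges = edges, cost = cost)
}

# Minimum spanning network: process distance classes in increasing order;
# an edge of class delta is feasible when its endpoints lie in different
# components of the graph built from classes < delta - epsilon.
msn_edges <- function(D, epsilon = 0) {
  k <- nrow(D)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[ut]
  classes <- sort(unique(round(dv, 9)))
  edges <- matrix(integer(0), 0, 2)
  comp_at <- function(thr) {
    comp <- seq_len(k)
    find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
    sel <- which(round(dv, 9) < thr - 1e-9)
    for (s in sel) {
      a <- find(ut[s, 1L]); b <- find(ut[s, 2L])
      if (a != b) comp[a] <- b
    }
    vapply(seq_len(k), find, 1L)
  }
  for (cl in classes) {
    comp <- comp_at(cl - epsilon)
    sel <- which(abs(round(dv, 9) - cl) < 1e-9)
    for (s in sel) {
      if (comp[ut[s, 1L]] != comp[ut[s, 2L]])
        edges <- rbind(edges, ut[s, , drop = FALSE])
    }
    if (length(unique(comp_at(cl + 1e-6))) == 1L) break
  }
  edges
}

# components of an undirected graph on 1..k given an edge matrix
edge_components <- function(k, edges) {
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(k), find, 1L)
  match(roots, unique(roots))
}

quasi_median <- function(a, b, c) {
  tie <- a != b & a != c & b != c
  if (any(tie)) return(NULL)       # a three-way tie contributes no vector
  ifelse(a == b | a == c, a, b)    # column-wise majority
}

#' Median-joining haplotype network
#'
#' Builds the epsilon-relaxed minimum spanning network on the haplotypes
#' under weighted Hamming distance, repeatedly adds quasi-medians
#' (column-wise majority of connected triples) that reduce the minimum
#' spanning tree cost, and prunes median vectors of degree below three.
#' With epsilon = 0 the final network contains a minimum spanning tree of
#' the observed haplotypes. Runs of adjacent columns with an identical gap
#' pattern are first merged into one indel character, so a multi-base indel
#' is one weighted event.
#'
#' @param hs [collapse_haplotypes()] result with k >= 2.
#' @param params [network_params()]
#' @param max_rounds cap on median-addition rounds.
#' @return `haplotype_network`: `graph` (igraph), `nodes` (matrix over
#'   variable columns), `node_ids`, `counts` (0 for medians), `is_median`,
#'   `edges` (from, to, weight, columns), `columns` (alignment columns of
#'   the variable columns used).
#' @export
median_joining_network <- function(hs, params = network_params(),
                                   max_rounds = 25L) {
  if (hs$k < 2L) stop_mitopop("network needs k >= 2 haplotypes")
  merged <- merge_indel_runs(hs$seq)
  variable <- which(column_allele_counts(merged$mat) > 1L)
  cols <- merged$map[variable]
  nodes <- merged$mat[, variable, drop = FALSE]
  weights <- ifelse(apply(nodes == "-", 2L, any),
                    params$indel_weight, params$snp_weight)
  node_ids <- hs$ids
  is_median <- rep(FALSE, nrow(nodes))
  mv <- 0L

  for (round in seq_len(max_rounds)) {
    D <- weighted_dist(nodes, weights)
    E <- msn_edges(D, params$epsilon)
    base_cost <- prim_mst(D)$cost
    adj <- matrix(FALSE, nrow(nodes), nrow(nodes))
    adj[E] <- TRUE; adj <- adj | t(adj)
    added <- FALSE
    k <- nrow(nodes)
    if (k >= 3L) {
      # triples connected through >= 2 network edges: pairs of neighbours
      triples <- matrix(integer(0), 0L, 3L)
      for (v in seq_len(k)) {
        nb <- which(adj[v, ])
        if (length(nb) >= 2L)
          triples <- rbind(triples, cbind(v, t(utils::combn(nb, 2L))))
      }
      if (nrow(triples)) triples <- unique(t(apply(triples, 1L, sort)))
      if (nrow(triples))
        triples <- triples[order(triples[, 1L], triples[, 2L], triples[, 3L]),
                           , drop = FALSE]
      for (t in seq_len(nrow(triples))) {
        i <- triples[t, 1L]; j <- triples[t, 2L]; l <- triples[t, 3L]
        qm <- quasi_median(nodes[i, ], nodes[j, ], nodes[l, ])
        if (is.null(qm)) next
        if (any(rowSums(nodes != rep(qm, each = k)) == 0L)) next
        Dq <- vapply(seq_len(k), function(r)
          sum(weights[nodes[r, ] != qm]), 1)
        D2 <- rbind(cbind(D, Dq), c(Dq, 0))
        if (prim_mst(D2)$cost < base_cost - 1e-9) {
          nodes <- rbind(nodes, qm)
          mv <- mv + 1L
          node_ids <- c(node_ids, paste0("mv", mv))
          is_median <- c(is_median, TRUE)
          added <- TRUE
          break
        }
      }
    }
    if (added) next
    # prune median vectors of MSN degree <= 2
    deg <- tabulate(c(E[, 1L], E[, 2L]), nrow(nodes))
    drop <- is_median & deg <= 2L
    if (any(drop)) {
      nodes <- nodes[!drop, , drop = FALSE]
      node_ids <- node_ids[!drop]
      is_median <- is_median[!drop]
    } else break
  }
  D <- weighted_dist(nodes, weights)
  E <- msn_edges(D, params$epsilon)
  counts <- ifelse(is_median, 0L, hs$counts[match(node_ids, hs$ids)])
  edges <- data.frame(
    from = node_ids[E[, 1L]], to = node_ids[E[, 2L]],
    weight = D[E],
    columns = apply(E, 1L, function(e)
      paste(cols[nodes[e[1L], ] != nodes[e[2L], ]], collapse = ",")),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = node_ids, count = counts,
                          is_median = is_median))
  structure(list(graph = g, nodes = nodes, node_ids = node_ids,
                 counts = counts, is_median = is_median, edges = edges,
                 columns = cols, weights = weights),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", sum(!x$is_median), "observed haplotypes,",
      sum(x$is_median), "median vectors,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export a haplotype network to GraphML
#' @param net [median_joining_network()] result.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Partition individuals into the two network lineages
#'
#' `network_cut` removes the single maximum-weight edge of the haplotype
#' minimum spanning tree (ties broken deterministically by the smallest
#' differing column index on the edge) and assigns the resulting components;
#' `linkage` cuts a complete-linkage clustering of unweighted Hamming
#' distances into two groups. Group 1 is the larger group (ties: the group
#' of the alphabetically first individual).
#'
#' @param hs [collapse_haplotypes()] result (with its `meta`).
#' @param method "network_cut" or "linkage".
#' @param params [network_params()]
#' @return named integer vector individual -> group in {1, 2}; attribute
#'   `haplotype_groups` gives the per-haplotype assignment.
#' @export
partition_two_groups <- function(hs, method = c("network_cut", "linkage"),
                                 params = network_params()) {
  method <- match.arg(method)
  if (hs$k < 2L) stop_mitopop("partition needs k >= 2")
  merged <- merge_indel_runs(hs$seq)
  variable <- which(column_allele_counts(merged$mat) > 1L)
  nodes <- merged$mat[, variable, drop = FALSE]
  cols <- merged$map[variable]
  if (method == "network_cut") {
    weights <- ifelse(apply(nodes == "-", 2L, any),
                      params$indel_weight, params$snp_weight)
    D <- weighted_dist(nodes, weights)
    mst <- prim_mst(D)
    w <- D[mst$edges]
    mx <- which(w == max(w))
    if (length(mx) > 1L) {
      first_col <- vapply(mx, function(e) {
        dif <- which(nodes[mst$edges[e, 1L], ] != nodes[mst$edges[e, 2L], ])
        min(cols[dif])
      }, 1)
      mx <- mx[which.min(first_col)]
    }
    keep <- mst$edges[-mx, , drop = FALSE]
    memb <- edge_components(hs$k, keep)
  } else {
    D0 <- weighted_dist(nodes, rep(1, ncol(nodes)))
    memb <- stats::cutree(stats::hclust(stats::as.dist(D0), "complete"), k = 2L)
  }
  # haplotype clusters -> individual groups via each individual's major
  meta <- hs$meta
  majors <- meta[!meta$is_minor, , drop = FALSE]
  grp <- memb[hs$membership[majors$id]]
  names(grp) <- majors$individual
  if (length(unique(grp)) < 2L)
    warning("partition produced a single group; data may lack two lineages")
  sizes <- table(factor(grp, levels = 1:2))
  relabel <- if (sizes[2L] > sizes[1L] ||
                 (sizes[1L] == sizes[2L] &&
                  grp[order(names(grp))][1L] == 2L)) c(2L, 1L) else c(1L, 2L)
  out <- stats::setNames(relabel[grp], names(grp))
  attr(out, "haplotype_groups") <- relabel[memb]
  out
}

#' Count diagnostic (torso) mutations between two groups
#'
#' A column is diagnostic when the allele sets observed in the two groups
#' are disjoint (gaps count as alleles, N is missing); these are the
#' mutations on the network backbone separating the lineages.
#'
#' @param aln [mito_alignment()] (minors included).
#' @param partition named vector individual -> group from
#'   [partition_two_groups()] or truth labels.
#' @return list `(n_sites, n_snv, n_indel)`.
#' @export
count_diagnostic_mutations <- function(aln, partition) {
  grp <- partition[aln$meta$individual]
  if (any(is.na(grp))) stop_mitopop("partition is missing individuals")
  if (length(unique(grp)) < 2L) stop_mitopop("need two nonempty groups")
  r1 <- which(grp == 1L); r2 <- which(grp == 2L)
  n_snv <- n_indel <- 0L
  # only columns where some row differs from row 1 can be diagnostic
  first <- aln$seq[1L, ]
  candidate <- which(colSums(aln$seq != rep(first, each = n_seq(aln))) > 0L |
                       first == "N")
  for (j in candidate) {
    a1 <- unique(aln$seq[r1, j]); a1 <- a1[a1 != "N"]
    a2 <- unique(aln$seq[r2, j]); a2 <- a2[a2 != "N"]
    if (length(a1) && length(a2) && !length(intersect(a1, a2))) {
      if ("-" %in% c(a1, a2)) n_indel <- n_indel + 1L else n_snv <- n_snv + 1L
    }
  }
  list(n_sites = n_snv + n_indel, n_snv = n_snv, n_indel = n_indel)
}
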