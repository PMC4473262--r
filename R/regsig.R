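#' Metabolite- and pathway-derived gene sets for promoter analysis
#'
#' Builds one gene set per metabolite with network degree `>= min_degree`
#' (its transcript neighbors) and one per subpathway and superpathway (the
#' union of the neighbor sets of the pathway's member metabolites present
#' in the network). The background for every set is all remaining genes of
#' the universe.
#'
#' @param network a [threshold_and_build()] result.
#' @param annotations optional data frame with columns `metabolite`,
#'   `subpathway`, `superpathway`; pathway-level sets are only built when
#'   given. Unknown metabolites (IDs such as `X-03094`) are first-class
#'   set seeds.
#' @param min_degree minimum transcript degree for single-metabolite sets.
#' @param universe gene universe for backgrounds; defaults to all network
#'   transcripts.
#' @return named list of `gene_set` records: `genes`, `background`,
#'   `level` (`"metabolite"`, `"subpathway"` or `"superpathway"`).
#' @export
build_gene_sets <- function(network, annotations = NULL, min_degree = 3,
                            universe = NULL) {
  stopifnot(inherits(network, "bipartite_network"))
  universe <- universe %||% unique(network$edges$transcript)
  nb <- split(network$edges$transcript, network$edges$metabolite)
  nb <- lapply(nb, unique)
  sets <- list()
  for (m in names(nb)) {
    if (length(nb[[m]]) >= min_degree) {
      sets[[m]] <- list(genes = nb[[m]],
                        background = setdiff(universe, nb[[m]]),
                        level = "metabolite")
    }
  }
  if (!is.null(annotations)) {
    for (lvl in c("subpathway", "superpathway")) {
      if (!lvl %in% names(annotations)) next
      groups <- split(annotations$metabolite, annotations[[lvl]])
      for (pw in names(groups)) {
        members <- intersect(groups[[pw]], names(nb))
        if (!length(members)) next
        genes <- unique(unlist(nb[members]))
        if (!length(genes)) next
        sets[[paste(lvl, pw, sep = ":")]] <- list(
          genes = genes, background = setdiff(universe, genes), level = lvl)
      }
    }
  }
  sets
}

#' Motif enrichment over a promoter hit table
#'
#' Default backend for transcription-factor binding-site enrichment: per
#' motif, a one-sided hypergeometric test on the number of set genes with
#' at least one occurrence versus the background (a gene "has" a motif if
#' its count is `>= 1`). The backend is intentionally simple so an
#' external promoter scanner's output table can be substituted for the
#' hit table.
#'
#' @param set character vector of gene IDs (non-empty).
#' @param background character vector of gene IDs, disjoint from `set`.
#' @param hits a gene x motif count matrix (rows named by gene), e.g. from
#'   [generate_motif_hits()] or [read_motif_hits()].
#' @param p_cut significance threshold (default `1e-7`).
#' @return data frame (`motif`, `k_set`, `k_background`, `frac_with_hit`,
#'   `p`, `significant`).
#' @export
motif_enrichment <- function(set, background, hits, p_cut = 1e-7) {
  if (!length(set)) stop("empty gene set")
  if (length(intersect(set, background))) {
    stop("set and background must be disjoint")
  }
  set <- intersect(set, rownames(hits))
  background <- intersect(background, rownames(hits))
  if (!length(set)) stop("no set gene present in the hit table")
  has <- unclass(hits) >= 1L
  k_set <- colSums(has[set, , drop = FALSE])
  k_bg <- colSums(has[background, , drop = FALSE])
  n <- length(set)
  N <- n + length(background)
  K <- k_set + k_bg
  p <- stats::phyper(k_set - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(motif = colnames(hits), k_set = k_set, k_background = k_bg,
             frac_with_hit = k_set / n, p = p, significant = p <= p_cut,
             row.names = NULL)
}

#' Enrichment across all gene sets
#'
#' Convenience wrapper running [motif_enrichment()] for every set from
#' [build_gene_sets()].
#'
#' @inheritParams motif_enrichment
#' @param sets result of [build_gene_sets()].
#' @return named list of enrichment data frames (attribute `level` per
#'   entry preserved from the set).
#' @export
enrich_gene_sets <- function(sets, hits, p_cut = 1e-7) {
  lapply(sets, function(s) {
    res <- motif_enrichment(s$genes, s$background, hits, p_cut = p_cut)
    attr(res, "level") <- s$level
    res
  })
}

#' Shared significant motifs and regulatory triads
#'
#' Two summaries of coregulation. (1) Sharing: for every pair of gene sets
#' at the same level (metabolite, subpathway, superpathway), the number of
#' motifs significantly enriched in both; returned as symmetric matrices
#' whose diagonal is the per-set significant-motif count. (2) Triads: a
#' (metabolite M, transcription factor t) pair such that t's transcript is
#' a network neighbor of M and t's motif is significantly enriched in M's
#' other neighbor genes, with the TF gene excluded from the test set (it
#' joins the background). Motifs without a TF-gene mapping are skipped for
#' triads but kept in sharing.
#'
#' @param enrichments result of [enrich_gene_sets()].
#' @param network a [threshold_and_build()] result.
#' @param tf_gene_map data frame with columns `motif`, `gene` mapping
#'   binding motifs to the transcription factor's own gene.
#' @param hits gene x motif count matrix (needed to re-test with the TF
#'   gene excluded).
#' @param p_cut significance threshold.
#' @param min_degree minimum metabolite degree considered for triads.
#' @return list with `shared` (list of matrices by level) and `triads`
#'   (data frame `metabolite`, `motif`, `tf_gene`, `p`).
#' @export
shared_and_triads <- function(enrichments, network, tf_gene_map, hits,
                              p_cut = 1e-7, min_degree = 3) {
  sig_motifs <- lapply(enrichments, function(e) e$motif[e$significant])
  levels_ <- vapply(enrichments, function(e) attr(e, "level"), character(1))
  shared <- list()
  for (lvl in unique(levels_)) {
    ids <- names(enrichments)[levels_ == lvl]
    mat <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)) {
      for (j in seq_len(i)) {
        mat[i, j] <- mat[j, i] <-
          length(intersect(sig_motifs[[ids[i]]], sig_motifs[[ids[j]]]))
      }
    }
    shared[[lvl]] <- mat
  }

  tf_map <- stats::setNames(as.character(tf_gene_map$gene),
                            as.character(tf_gene_map$motif))
  universe <- unique(network$edges$transcript)
  nb <- lapply(split(network$edges$transcript, network$edges$metabolite), unique)
  triads <- list()
  for (m in names(nb)) {
    neigh <- nb[[m]]
    if (length(neigh) < min_degree) next
    for (motif in intersect(colnames(hits), names(tf_map))) {
      tf_gene <- tf_map[[motif]]
      if (!tf_gene %in% neigh) next
      test_set <- setdiff(neigh, tf_gene)
      if (!length(test_set)) next
      bg <- setdiff(universe, test_set)
      e <- motif_enrichment(test_set, bg, hits[, motif, drop = FALSE],
                            p_cut = p_cut)
      if (isTRUE(e$significant[1])) {
        triads[[length(triads) + 1L]] <- data.frame(
          metabolite = m, motif = motif, tf_gene = tf_gene, p = e$p[1])
      }
    }
  }
  triads <- if (length(triads)) do.call(rbind, triads) else {
    data.frame(metabolite = character(0), motif = character(0),
               tf_gene = character(0), p = numeric(0))
  }
  list(shared = shared, triads = triads)
}
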