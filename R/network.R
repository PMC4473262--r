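#' Pairwise metabolite-transcript Spearman correlation
#'
#' Computes Spearman rank correlation for every metabolite x transcript
#' pair, separately per pair on the samples where the metabolite is
#' observed (the transcript matrix must be complete). Two-sided p-values
#' use the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with `n - 2`
#' degrees of freedom. Pairs resting on fewer than 10 samples are flagged
#' (`low_n`) and excluded from downstream thresholding.
#'
#' @param metabolome,transcriptome [omics_matrix()] objects sharing sample
#'   order (residual or log scale).
#' @return a `correlation_table` data frame with columns `metabolite`,
#'   `transcript`, `rho`, `p`, `n_used`, `low_n`.
#' @export
cross_correlate <- function(metabolome, transcriptome) {
  stopifnot(inherits(metabolome, "omics_matrix"),
            inherits(transcriptome, "omics_matrix"))
  if (!identical(rownames(metabolome), rownames(transcriptome))) {
    stop("matrices must share sample order")
  }
  if (anyNA(transcriptome)) {
    stop("transcriptome must be complete; impute or filter upstream")
  }
  M <- unclass(metabolome)
  Tm <- unclass(transcriptome)
  mets <- colnames(M)
  txs <- colnames(Tm)
  out <- vector("list", length(mets))
  for (j in seq_along(mets)) {
    obs <- which(!is.na(M[, j]))
    n <- length(obs)
    if (n < 3L) {
      out[[j]] <- data.frame(metabolite = mets[j], transcript = txs,
                             rho = NA_real_, p = NA_real_, n_used = n)
      next
    }
    rm_ <- rank(M[obs, j])
    RT <- apply(Tm[obs, , drop = FALSE], 2, rank)
    rho <- suppressWarnings(as.numeric(stats::cor(rm_, RT)))
    out[[j]] <- data.frame(metabolite = mets[j], transcript = txs,
                           rho = rho, p = spearman_t_p(rho, n), n_used = n)
  }
  tab <- do.call(rbind, out)
  if (all(tab$n_used < 3L)) stop("no shared samples between the matrices")
  tab$low_n <- tab$n_used < 10L
  rownames(tab) <- NULL
  structure(tab, class = c("correlation_table", "data.frame"),
            n_samples = nrow(M))
}

#' Threshold a correlation table into a bipartite network
#'
#' Applies Benjamini-Hochberg FDR control over the *full* family of `m`
#' tests (by default the table's own row count; pass the pre-collapse
#' probe-level count when probes were collapsed afterwards), keeps pairs at
#' or below the BH p-cutoff, and reports a network-density curve: the
#' fraction of realized pairs as a function of an absolute-correlation
#' cutoff grid (step 0.005).
#'
#' @param corr a [cross_correlate()] table.
#' @param fdr FDR level in (0,1).
#' @param m family size for BH; `>=` number of valid rows.
#' @return a `bipartite_network` list: `edges` (metabolite, transcript,
#'   rho, p), `metabolites`, `transcripts`, `fdr`, `p_cutoff`,
#'   `rho_cutoff`, `connectivity` (edges over all possible
#'   metabolite x transcript pairs) and `density` (cutoff grid).
#' @export
threshold_and_build <- function(corr, fdr = 0.01, m = NULL) {
  stopifnot(inherits(corr, "correlation_table"))
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) stop("fdr must lie in (0,1)")
  valid <- !corr$low_n & !is.na(corr$p)
  m <- m %||% sum(valid)
  p_cut <- bh_cutoff(corr$p[valid], fdr, m = m)
  hit <- valid & corr$p <= p_cut
  edges <- corr[hit, c("metabolite", "transcript", "rho", "p")]
  rownames(edges) <- NULL
  rho_cut <- if (nrow(edges)) min(abs(edges$rho)) else NA_real_
  n_met <- length(unique(corr$metabolite))
  n_tx <- length(unique(corr$transcript))
  grid <- seq(0, max(abs(corr$rho[valid]), 0), by = 0.005)
  dens <- vapply(grid, function(ct) mean(abs(corr$rho[valid]) >= ct), numeric(1))
  structure(list(
    edges = edges,
    metabolites = unique(edges$metabolite),
    transcripts = unique(edges$transcript),
    fdr = fdr, m = m,
    p_cutoff = p_cut, rho_cutoff = rho_cut,
    connectivity = nrow(edges) / (n_met * n_tx),
    density = data.frame(cutoff = grid, density = dens)
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "bipartite_network: %d metabolites, %d transcripts, %d edges (FDR %g, p <= %.3g, |rho| >= %.3g)\n",
    length(x$metabolites), length(x$transcripts), nrow(x$edges),
    x$fdr, x$p_cutoff, x$rho_cutoff
  ))
  invisible(x)
}

#' Neighbors of a metabolite in a bipartite network
#' @param network a [threshold_and_build()] result.
#' @param metabolite metabolite ID.
#' @return character vector of transcript neighbors.
#' @export
network_neighbors <- function(network, metabolite) {
  stopifnot(inherits(network, "bipartite_network"))
  unique(network$edges$transcript[network$edges$metabolite == metabolite])
}

#' Replicate network edges in a second cohort
#'
#' Re-computes the Spearman test for each network edge whose endpoints are
#' mappable to features of a second cohort, and summarizes the fraction of
#' testable edges reaching nominal significance (p < 0.05) and surviving
#' BH FDR < 0.05 applied over the tested-edge set.
#'
#' @param network a [threshold_and_build()] result.
#' @param metabolome2,transcriptome2 [omics_matrix()] objects for cohort 2.
#' @param met_map,gene_map named character vectors mapping cohort-1 feature
#'   IDs to cohort-2 feature IDs (unmapped edges are skipped).
#' @param nominal_p,fdr thresholds for the two summaries.
#' @return list with the per-edge table and counts/fractions.
#' @export
replicate_edges <- function(network, metabolome2, transcriptome2,
                            met_map, gene_map,
                            nominal_p = 0.05, fdr = 0.05) {
  stopifnot(inherits(network, "bipartite_network"))
  e <- network$edges
  e$met2 <- unname(met_map[e$metabolite])
  e$tx2 <- unname(gene_map[e$transcript])
  e <- e[!is.na(e$met2) & !is.na(e$tx2) &
           e$met2 %in% colnames(metabolome2) &
           e$tx2 %in% colnames(transcriptome2), ]
  if (!nrow(e)) stop("empty overlap: no network edge maps into cohort 2")
  res <- t(vapply(seq_len(nrow(e)), function(i) {
    s <- spearman_cor_p(metabolome2[, e$met2[i]], transcriptome2[, e$tx2[i]])
    c(s$rho, s$p, s$n)
  }, numeric(3)))
  e$rho2 <- res[, 1]; e$p2 <- res[, 2]; e$n2 <- res[, 3]
  e$q2 <- bh_adjust(e$p2)
  list(
    table = e,
    n_edges = nrow(network$edges),
    n_testable = nrow(e),
    n_nominal = sum(e$p2 < nominal_p, na.rm = TRUE),
    frac_nominal = mean(e$p2 < nominal_p, na.rm = TRUE),
    n_fdr = sum(e$q2 < fdr, na.rm = TRUE),
    frac_fdr = mean(e$q2 < fdr, na.rm = TRUE)
  )
}

#' Overlap of network genes with marker gene lists
#'
#' Assigns each network gene to every marker label containing it; genes in
#' no list count as "unassigned". Percentages are per label relative to the
#' number of network genes, so a gene present in several lists contributes
#' to each of them (per-source convention).
#'
#' @param network_genes character vector of network gene IDs.
#' @param marker_lists named list of character vectors.
#' @return named numeric vector of percentages including `"unassigned"`.
#' @export
marker_overlap <- function(network_genes, marker_lists) {
  genes <- unique(network_genes)
  if (!length(genes)) return(c(unassigned = 100))
  pct <- vapply(marker_lists,
                function(g) 100 * mean(genes %in% g), numeric(1))
  assigned <- genes %in% unlist(marker_lists)
  c(pct, unassigned = 100 * mean(!assigned))
}
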