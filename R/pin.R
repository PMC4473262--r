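#' Filter functional category annotations
#'
#' Applies the category-level filters used before pathway aggregation:
#' metabolic pathways (kind `"MP"`) with fewer than `min_mp_members`
#' metabolite members are excluded; gene-ontology root terms and terms
#' with no members in the feature universe are removed.
#'
#' @param categories data frame with columns `category`, `kind` (`"GO"` or
#'   `"MP"`) and `member`.
#' @param universe character vector of measured feature IDs; members
#'   outside it are dropped first.
#' @param go_roots GO root-term names to exclude.
#' @param min_mp_members minimum metabolite members per MP term.
#' @return the filtered categories data frame.
#' @export
filter_categories <- function(categories, universe,
                              go_roots = c("biological_process",
                                           "molecular_function",
                                           "cellular_component"),
                              min_mp_members = 2L) {
  stopifnot(all(c("category", "kind", "member") %in% names(categories)))
  categories <- categories[categories$member %in% universe, ]
  categories <- categories[!(categories$kind == "GO" &
                               categories$category %in% go_roots), ]
  sizes <- table(categories$category[categories$kind == "MP"])
  small <- names(sizes)[sizes < min_mp_members]
  categories <- categories[!(categories$kind == "MP" &
                               categories$category %in% small), ]
  rownames(categories) <- NULL
  categories
}

#' Edge-constrained member sets for every GO x MP pair
#'
#' For each (GO term, metabolic pathway) combination, restricts the two
#' categories to the members that share at least one network edge with a
#' member of the partner category: the GO side keeps transcripts with an
#' edge to some MP metabolite, the MP side keeps metabolites with an edge
#' to some GO transcript. Pairs with an empty side are marked untestable.
#'
#' @param categories filtered annotations (see [filter_categories()]).
#' @param network a [threshold_and_build()] result.
#' @return list of pair records: `go`, `mp`, `transcripts`, `metabolites`,
#'   `testable`.
#' @export
build_category_sets <- function(categories, network) {
  stopifnot(inherits(network, "bipartite_network"))
  go_terms <- unique(categories$category[categories$kind == "GO"])
  mp_terms <- unique(categories$category[categories$kind == "MP"])
  members <- split(categories$member, categories$category)
  e <- network$edges
  pairs <- vector("list", length(go_terms) * length(mp_terms))
  k <- 0L
  for (go in go_terms) {
    gt <- members[[go]]
    for (mp in mp_terms) {
      mm <- members[[mp]]
      sub <- e[e$transcript %in% gt & e$metabolite %in% mm, ]
      k <- k + 1L
      pairs[[k]] <- list(go = go, mp = mp,
                         transcripts = unique(sub$transcript),
                         metabolites = unique(sub$metabolite),
                         testable = nrow(sub) > 0L)
    }
  }
  pairs
}

#' Aggregated z-score of a member set
#'
#' Per-sample arithmetic mean of the z-score-normalized profiles of the
#' set's members: `aggZ_j = (1/|C|) * sum_i Z[i, j]`. Samples where a
#' member is missing use the mean over the observed members.
#'
#' @param z a z-scored [omics_matrix()] (see [zscore()]).
#' @param members character vector of feature IDs (non-empty).
#' @return numeric per-sample score vector.
#' @export
aggz_scores <- function(z, members) {
  stopifnot(inherits(z, "omics_matrix"))
  if (scale_tag(z) != "zscore") stop("aggz_scores expects a zscore-scale matrix")
  if (!length(members)) stop("empty member set")
  if (!all(members %in% colnames(z))) stop("member(s) missing from the matrix")
  rowMeans(unclass(z)[, members, drop = FALSE], na.rm = TRUE)
}

#' Build the pathway interaction network (PIN)
#'
#' Correlates, for every testable GO x MP pair, the aggregated z-score of
#' the pair's (edge-constrained) transcript members against that of its
#' metabolite members by Spearman rank correlation. The full PIN keeps
#' pairs passing a Bonferroni-corrected threshold `alpha / n_testable`;
#' a sparser visualization PIN applies the ad-hoc stringent cutoff
#' `viz_p`. Pairs with a constant score vector are skipped with a flag.
#'
#' @param pair_sets result of [build_category_sets()].
#' @param z_met,z_tx z-scored metabolome and transcriptome matrices.
#' @param alpha family-wise error level for the Bonferroni threshold.
#' @param viz_p ad-hoc p-value cutoff for the visualization network.
#' @return a `pin` list: `pairs` (go, mp, rho, p, n_transcripts,
#'   n_metabolites, testable, degenerate), `n_testable`, `bonferroni_p`
#'   (recorded denominator made explicit), `edges` (full PIN) and
#'   `viz_edges`.
#' @export
build_pin <- function(pair_sets, z_met, z_tx, alpha = 0.01, viz_p = 1e-11) {
  rows <- lapply(pair_sets, function(ps) {
    out <- data.frame(go = ps$go, mp = ps$mp, rho = NA_real_, p = NA_real_,
                      n_transcripts = length(ps$transcripts),
                      n_metabolites = length(ps$metabolites),
                      testable = ps$testable, degenerate = FALSE)
    if (!ps$testable) return(out)
    sg <- aggz_scores(z_tx, ps$transcripts)
    sm <- aggz_scores(z_met, ps$metabolites)
    if (stats::sd(sg, na.rm = TRUE) == 0 || stats::sd(sm, na.rm = TRUE) == 0 ||
        sum(!is.na(sg) & !is.na(sm)) < 3) {
      out$degenerate <- TRUE
      return(out)
    }
    s <- spearman_cor_p(sg, sm)
    out$rho <- s$rho
    out$p <- s$p
    out
  })
  tab <- do.call(rbind, rows)
  tested <- tab$testable & !tab$degenerate & !is.na(tab$p)
  n_testable <- sum(tested)
  bonf <- if (n_testable > 0) alpha / n_testable else NA_real_
  edges <- tab[tested & tab$p <= bonf, c("go", "mp", "rho", "p")]
  viz <- tab[tested & tab$p <= min(bonf, viz_p), c("go", "mp", "rho", "p")]
  rownames(edges) <- rownames(viz) <- NULL
  structure(list(pairs = tab, n_testable = n_testable, alpha = alpha,
                 bonferroni_p = bonf, viz_p = viz_p,
                 edges = edges, viz_edges = viz),
            class = "pin")
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf(
    "pin: %d testable GO x MP pairs, %d edges at Bonferroni p <= %.3g, %d at viz p <= %.3g\n",
    x$n_testable, nrow(x$edges), x$bonferroni_p, nrow(x$viz_edges), x$viz_p
  ))
  invisible(x)
}
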