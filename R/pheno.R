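#' Associate clinical traits with features or category scores
#'
#' Per trait and target, fits `trait ~ target + age + sex` by ordinary
#' least squares and reports the two-sided p-value of the target
#' coefficient together with the signed node score
#' `-log10(p) * sign(beta1)`. Significance uses a Bonferroni cutoff
#' `alpha / bonferroni_n`; `bonferroni_n` defaults to the number of
#' targets, which for feature-level analysis should be the total number of
#' metabolites plus transcripts tested per trait. Constant targets are
#' skipped with a flag.
#'
#' @param traits data frame of trait values (columns, e.g. HDL/LDL/TG in
#'   mg/dl) with rownames or a `sample` column matching the samples.
#' @param targets an [omics_matrix()] or plain numeric matrix
#'   (samples x targets), e.g. features or aggregated z-scores of
#'   categories restricted to network members.
#' @param covariates data frame with `age`, `sex`.
#' @param alpha family-wise error level.
#' @param bonferroni_n Bonferroni denominator (recorded in the output).
#' @return a `trait_association` data frame: `trait`, `target`, `beta1`,
#'   `p`, `score`, `significant`, `skipped`, with attributes `alpha`,
#'   `bonferroni_n`, `cutoff`.
#' @export
trait_associations <- function(traits, targets, covariates, alpha = 0.05,
                               bonferroni_n = NULL) {
  if (!is.null(traits$sample)) {
    rownames(traits) <- traits$sample
    traits <- traits[, setdiff(names(traits), "sample"), drop = FALSE]
  }
  V <- unclass(targets)
  stopifnot(is.matrix(V), nrow(V) == nrow(traits))
  bonferroni_n <- bonferroni_n %||% ncol(V)
  cutoff <- alpha / bonferroni_n
  rows <- list()
  k <- 0L
  for (tr in colnames(traits)) {
    y <- traits[[tr]]
    for (j in seq_len(ncol(V))) {
      x <- V[, j]
      ok <- !is.na(x) & !is.na(y)
      k <- k + 1L
      if (sum(ok) < 5L || stats::var(x[ok]) == 0) {
        rows[[k]] <- data.frame(trait = tr, target = colnames(V)[j],
                                beta1 = NA_real_, p = NA_real_,
                                score = NA_real_, significant = FALSE,
                                skipped = TRUE)
        next
      }
      X <- cbind(1, x, covariates$age, covariates$sex)[ok, , drop = FALSE]
      fit <- stats::lm.fit(X, y[ok])
      rss <- sum(fit$residuals^2)
      df <- sum(ok) - fit$rank
      se <- sqrt(chol2inv(chol(crossprod(X)))[2, 2] * rss / df)
      b <- fit$coefficients[2]
      p <- 2 * stats::pt(-abs(b / se), df = df)
      rows[[k]] <- data.frame(trait = tr, target = colnames(V)[j],
                              beta1 = b, p = p,
                              score = -log10(p) * sign(b),
                              significant = p <= cutoff, skipped = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trait_association", "data.frame"),
            alpha = alpha, bonferroni_n = bonferroni_n, cutoff = cutoff)
}

#' Project trait scores onto a network and compare two traits
#'
#' Writes each trait's signed score (`-log10(p) * sign(beta1)`) as a node
#' attribute onto the network and returns the Spearman correlation of the
#' node scores between the two traits over the nodes scored in both
#' tables -- the network-level measure of concordant or antagonistic trait
#' association patterns.
#'
#' @param assoc1,assoc2 single-trait subsets of a [trait_associations()]
#'   table (one `trait` value each).
#' @param network a [threshold_and_build()] result or a `pin`.
#' @return list with `graph` (igraph with `score_<trait>` node
#'   attributes), `correlation` (Spearman rho across shared nodes) and
#'   `n_shared`.
#' @export
project_and_compare <- function(assoc1, assoc2, network) {
  stopifnot(length(unique(assoc1$trait)) == 1L,
            length(unique(assoc2$trait)) == 1L)
  g <- as_igraph(network)
  nodes <- igraph::V(g)$name
  s1 <- stats::setNames(assoc1$score, assoc1$target)[nodes]
  s2 <- stats::setNames(assoc2$score, assoc2$target)[nodes]
  g <- igraph::set_vertex_attr(g, paste0("score_", assoc1$trait[1]), value = s1)
  g <- igraph::set_vertex_attr(g, paste0("score_", assoc2$trait[1]), value = s2)
  shared <- !is.na(s1) & !is.na(s2)
  if (sum(shared) < 3L) stop("fewer than 3 shared scored nodes")
  rho <- stats::cor(rank(s1[shared]), rank(s2[shared]))
  list(graph = g, correlation = rho, n_shared = sum(shared))
}
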