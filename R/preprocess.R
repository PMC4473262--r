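#' Filter features by missingness
#'
#' Retains exactly the features whose missing fraction is `<= max_missing`;
#' features with *strictly more* than `max_missing` missing values are
#' excluded. Sample order is unchanged. The default reproduces the usual
#' metabolomics quality rule of dropping metabolites with more than 50%
#' missing values.
#'
#' @param x an [omics_matrix()] on the raw or log scale.
#' @param max_missing maximum tolerated missing fraction per feature.
#' @return the filtered `omics_matrix`.
#' @export
filter_missing <- function(x, max_missing = 0.5) {
  stopifnot(inherits(x, "omics_matrix"), max_missing >= 0, max_missing <= 1)
  if (!scale_tag(x) %in% c("raw", "log")) {
    stop("filter_missing expects a raw- or log-scale matrix")
  }
  frac <- colMeans(is.na(x))
  keep <- frac <= max_missing
  if (!any(keep)) warning("all features exceeded the missingness threshold")
  as_omics(unclass(x)[, keep, drop = FALSE], scale_tag(x))
}

#' Log-transform and adjust for age and sex
#'
#' Natural-log transforms a raw positive matrix, then removes age and sex
#' effects feature by feature with ordinary least squares on
#' intercept + age + sex, fitted on each feature's observed samples
#' (complete-case per feature). Residuals are returned; missing entries
#' stay missing.
#'
#' @param x an [omics_matrix()] on the raw scale (observed values > 0), or
#'   already on the log scale (then only adjustment is applied).
#' @param covariates data frame with columns `age` and `sex`, rownames (or a
#'   `sample` column) matching the samples of `x` exactly.
#' @return an `omics_matrix` with `scale_tag = "residual"`.
#' @export
log_and_adjust <- function(x, covariates) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!is.null(covariates$sample)) rownames(covariates) <- covariates$sample
  if (is.null(rownames(covariates)) ||
      !identical(rownames(covariates), rownames(x))) {
    stop("alignment error: covariate rows must match sample IDs of `x`")
  }
  if (!all(c("age", "sex") %in% names(covariates))) {
    stop("covariates must contain `age` and `sex`")
  }
  v <- unclass(x)
  if (scale_tag(x) == "raw") {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("domain error: raw values must be positive for log transform")
    }
    v <- log(v)
  } else if (scale_tag(x) != "log") {
    stop("log_and_adjust expects a raw- or log-scale matrix")
  }
  X <- cbind(1, covariates$age, covariates$sex)
  res <- v
  complete <- !anyNA(v)
  if (complete) {
    fit <- stats::lm.fit(X, v)
    res[] <- fit$residuals
  } else {
    for (j in seq_len(ncol(v))) {
      obs <- which(!is.na(v[, j]))
      if (length(obs) <= 3L) {
        res[obs, j] <- NA_real_
        next
      }
      fit <- stats::lm.fit(X[obs, , drop = FALSE], v[obs, j])
      res[obs, j] <- fit$residuals
    }
  }
  as_omics(res, "residual")
}

#' Collapse expression probes to one representative per gene
#'
#' When several array probes map to the same gene, keeps the probe with the
#' maximum correlation strength to any metabolite (max over metabolites of
#' `|rho|` from a probe-level correlation table). Ties within `1e-12` are
#' broken deterministically by the lexicographically smallest probe ID.
#' Feature IDs of the result are gene IDs. Downstream significance
#' thresholds must still be derived from the full probe-level test count;
#' see the `m` argument of [threshold_and_build()].
#'
#' @param expr probe-level [omics_matrix()].
#' @param probe_map data frame with columns `probe`, `gene` (many-to-one),
#'   or a named character vector `probe -> gene`.
#' @param corr a [cross_correlate()] table computed on the full probe-level
#'   matrix.
#' @return gene-level `omics_matrix`.
#' @export
collapse_probes <- function(expr, probe_map, corr) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (is.data.frame(probe_map)) {
    probe_map <- stats::setNames(as.character(probe_map$gene),
                                 as.character(probe_map$probe))
  }
  probes <- colnames(expr)
  if (!all(probes %in% names(probe_map))) {
    stop("probe(s) missing from probe_map")
  }
  if (!all(probes %in% corr$transcript)) {
    stop("probe(s) absent from the correlation table")
  }
  strength <- tapply(abs(corr$rho), corr$transcript, max, na.rm = TRUE)
  strength <- strength[probes]
  genes <- probe_map[probes]
  pick <- vapply(split(seq_along(probes), genes), function(idx) {
    s <- strength[idx]
    tied <- idx[s >= max(s) - 1e-12]
    tied[order(probes[tied])][1]
  }, integer(1))
  out <- unclass(expr)[, pick, drop = FALSE]
  colnames(out) <- names(pick)
  as_omics(out, scale_tag(expr))
}
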