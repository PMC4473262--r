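#' Sample-by-feature omics matrix
#'
#' Thin container for a numeric samples x features matrix with a scale tag
#' recording where in the processing chain the values live. Raw-scale values
#' must be positive wherever observed; `NA` marks missing entries.
#'
#' @param values numeric matrix, samples in rows, features in columns; both
#'   dimensions must carry unique names.
#' @param scale_tag one of `"raw"`, `"log"`, `"residual"`, `"zscore"`.
#' @return an `omics_matrix` object (a matrix with attributes).
#' @export
omics_matrix <- function(values, scale_tag = c("raw", "log", "residual", "zscore")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("sample IDs (rownames) must be present and unique")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("feature IDs (colnames) must be present and unique")
  }
  if (scale_tag == "raw" && any(values <= 0, na.rm = TRUE)) {
    stop("raw-scale observed values must be > 0")
  }
  structure(values, scale_tag = scale_tag, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix: %d samples x %d features [%s scale], %.1f%% missing\n",
    nrow(x), ncol(x), attr(x, "scale_tag"), 100 * mean(is.na(x))
  ))
  invisible(x)
}

scale_tag <- function(x) attr(x, "scale_tag")

## Rebuild an omics_matrix keeping class/attrs consistent after surgery.
as_omics <- function(values, tag) {
  structure(values, scale_tag = tag, class = c("omics_matrix", "matrix", "array"))
}

#' Per-feature z-scoring over observed entries
#'
#' Centers and scales every feature to mean 0, sd 1 across its observed
#' samples. Missing entries stay missing. Constant features become `NA`
#' with a warning.
#'
#' @param x an [omics_matrix()].
#' @return an `omics_matrix` with `scale_tag = "zscore"`.
#' @export
zscore <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  bad <- !is.na(sd) & sd == 0
  if (any(bad)) {
    warning(sprintf("%d constant feature(s) z-scored to NA", sum(bad)))
    sd[bad] <- NA_real_
  }
  z <- sweep(sweep(unclass(x), 2, mu, `-`), 2, sd, `/`)
  as_omics(z, "zscore")
}
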