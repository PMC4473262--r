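`%||%` <- function(a, b) if (is.null(a)) b else a

## Truncated-normal draws by rejection; deterministic under a fixed RNG state.
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

## Two-sided p for a Spearman rho via the t approximation with n - 2 df.
## Vectorised over rho and n; |rho| = 1 collapses to p ~ 0 through the
## machine-eps floor on 1 - rho^2.
spearman_t_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  if (length(n) == 1L) n <- rep(n, length(rho))
  ok <- !is.na(rho) & n > 2
  r <- pmin(pmax(rho[ok], -1), 1)
  tt <- r * sqrt((n[ok] - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n[ok] - 2)
  pmin(p, 1)
}

## Spearman rho + p for two vectors on pairwise-complete samples.
spearman_cor_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = spearman_t_p(rho, n), n = n)
}

#' Benjamini-Hochberg adjusted p-values over a family of `m` tests
#'
#' Like `p.adjust(p, "BH")` but allows the family size `m` to exceed the
#' number of observed p-values, as when significance must account for tests
#' performed on features that were later collapsed or excluded (the missing
#' tests are treated as non-discoveries).
#'
#' @param p numeric vector of p-values.
#' @param m family size, `>= length(p)`.
#' @return adjusted p-values (q-values) in the input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

#' Benjamini-Hochberg rejection cutoff
#'
#' Returns the largest observed p-value `p(k)` satisfying
#' `p(k) <= k * q / m` (step-up rule); rejection set is `p <= cutoff`.
#' Returns `-Inf` when nothing passes.
#'
#' @param p numeric vector of p-values.
#' @param q target FDR level.
#' @param m family size (defaults to `length(p)`).
#' @export
bh_cutoff <- function(p, q, m = length(p)) {
  stopifnot(q > 0, q < 1, m >= length(p))
  ps <- sort(p)
  k <- which(ps <= seq_along(ps) * q / m)
  if (!length(k)) -Inf else ps[max(k)]
}
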