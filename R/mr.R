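## Single-SNP OLS with age/sex adjustment; returns beta, se, p for the SNP.
snp_trait_ols <- function(y, g, age, sex) {
  ok <- !is.na(y) & !is.na(g)
  X <- cbind(1, g, age, sex)[ok, , drop = FALSE]
  yy <- y[ok]
  n <- length(yy)
  if (n < 5L || stats::var(X[, 2]) == 0) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = n))
  }
  fit <- stats::lm.fit(X, yy)
  rss <- sum(fit$residuals^2)
  df <- n - fit$rank
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(XtX_inv[2, 2] * rss / df)
  beta <- unname(fit$coefficients[2])
  c(beta = beta, se = se,
    p = 2 * stats::pt(-abs(beta / se), df = df), n = n)
}

#' Screen candidate instrumental variables
#'
#' For each candidate (SNP, trait) pair, tests the SNP-trait association by
#' OLS with age and sex as covariates, keeps candidates significant at
#' BH FDR `fdr` over the candidate family, and prunes linkage
#' disequilibrium by pairwise genotype r-squared: for every violating pair
#' (`r^2 >= r2_max`) the member with the weaker trait association is
#' dropped, greedily. Monomorphic SNPs are excluded with a warning.
#'
#' @param genotypes samples x SNPs matrix of additive dosages 0/1/2.
#' @param traits samples x traits numeric matrix (metabolite or transcript
#'   levels, typically residual scale).
#' @param covariates data frame with `age` and `sex` aligned to samples.
#' @param candidates data frame with columns `snp`, `trait`.
#' @param fdr validity FDR level.
#' @param r2_max maximum tolerated pairwise genotype r-squared.
#' @return an `instrument_set`: data frame (`snp`, `trait`, `beta`, `se`,
#'   `p`, `q`) of retained instruments with the pruned r-squared matrix as
#'   attribute `r2`.
#' @export
filter_instruments <- function(genotypes, traits, covariates, candidates,
                               fdr = 0.05, r2_max = 0.1) {
  stopifnot(all(c("snp", "trait") %in% names(candidates)))
  mono <- apply(genotypes[, unique(candidates$snp), drop = FALSE], 2,
                function(g) stats::var(g, na.rm = TRUE) == 0)
  if (any(mono)) {
    warning(sprintf("excluding %d monomorphic SNP(s)", sum(mono)))
    candidates <- candidates[!candidates$snp %in% names(mono)[mono], ]
  }
  if (!nrow(candidates)) stop("no polymorphic candidate instruments left")
  est <- t(mapply(function(s, tr) {
    snp_trait_ols(traits[, tr], genotypes[, s], covariates$age, covariates$sex)
  }, candidates$snp, candidates$trait))
  res <- data.frame(snp = candidates$snp, trait = candidates$trait,
                    beta = est[, "beta"], se = est[, "se"], p = est[, "p"],
                    row.names = NULL)
  res <- res[!is.na(res$p), ]
  res$q <- bh_adjust(res$p)
  res <- res[res$q <= fdr, ]
  if (nrow(res) > 1L) {
    ## greedy LD pruning: drop the weaker member of each violating pair
    repeat {
      G <- genotypes[, unique(res$snp), drop = FALSE]
      r2 <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
      diag(r2) <- 0
      if (all(r2 < r2_max, na.rm = TRUE)) break
      worst <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
      pair <- colnames(r2)[worst]
      pmin_ <- vapply(pair, function(s) min(res$p[res$snp == s]), numeric(1))
      drop <- pair[which.max(pmin_)]
      res <- res[res$snp != drop, ]
      if (length(unique(res$snp)) < 2L) break
    }
  }
  r2 <- if (nrow(res)) {
    suppressWarnings(stats::cor(genotypes[, unique(res$snp), drop = FALSE],
                                use = "pairwise.complete.obs"))^2
  } else matrix(numeric(0), 0, 0)
  structure(res, class = c("instrument_set", "data.frame"), r2 = r2)
}

#' Wald ratio causal-effect estimator
#'
#' Ratio of the SNP-outcome to the SNP-exposure regression coefficients,
#' using the SNP as an instrumental variable:
#' `beta_causal = beta_snp_outcome / beta_snp_exposure`.
#'
#' @param beta_snp_outcome,beta_snp_exposure regression coefficients of the
#'   outcome and the exposure on the instrument.
#' @return the causal effect estimate.
#' @export
wald_ratio <- function(beta_snp_outcome, beta_snp_exposure) {
  if (any(beta_snp_exposure == 0)) {
    stop("undefined ratio: SNP-exposure effect is zero")
  }
  beta_snp_outcome / beta_snp_exposure
}

#' Bootstrap inference for a single Wald-ratio causal test
#'
#' Resamples individuals with replacement; in each replicate both stage
#' regressions (exposure on SNP, outcome on SNP, each adjusted for age and
#' sex) are re-fit and the Wald ratio re-formed. Reports the percentile 95%
#' confidence interval and a two-sided bootstrap p-value
#' `2 * min(P(ratio <= 0), P(ratio >= 0))`, floored at `1/n_boot`. If more
#' than 5% of replicates have a near-zero exposure effect the result is
#' flagged unstable.
#'
#' @param exposure,outcome numeric vectors over samples.
#' @param genotype additive dosage vector for the instrument.
#' @param covariates data frame with `age`, `sex`.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return a `causal_result` list: `beta_causal`, `ci_low`, `ci_high`,
#'   `p_boot`, `n_boot`, `unstable`, plus the stage estimates.
#' @export
bootstrap_causal_test <- function(exposure, outcome, genotype, covariates,
                                  n_boot = 10000, seed = 1L, conf = 0.95) {
  ok <- !is.na(exposure) & !is.na(outcome) & !is.na(genotype)
  X <- cbind(1, genotype, covariates$age, covariates$sex)[ok, , drop = FALSE]
  Y <- cbind(exposure, outcome)[ok, , drop = FALSE]
  n <- nrow(Y)
  if (n < 10L) stop("too few complete samples for bootstrap")
  fit <- stats::lm.fit(X, Y)
  b_exp <- fit$coefficients[2, 1]
  b_out <- fit$coefficients[2, 2]
  point <- wald_ratio(b_out, b_exp)

  set.seed(seed)
  ratios <- numeric(n_boot)
  zero_exp <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- stats::lm.fit(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])$coefficients
    be <- cf[2, 1]
    if (abs(be) < 1e-8) {
      zero_exp <- zero_exp + 1L
      ratios[b] <- NA_real_
    } else {
      ratios[b] <- cf[2, 2] / be
    }
  }
  unstable <- zero_exp / n_boot > 0.05
  if (unstable) warning("unstable ratio: > 5% of replicates had near-zero exposure effect")
  r <- ratios[!is.na(ratios)]
  ci <- stats::quantile(r, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  p <- 2 * min(mean(r <= 0), mean(r >= 0))
  p <- min(1, max(p, 1 / n_boot))
  structure(list(
    beta_causal = point, beta_snp_exposure = b_exp, beta_snp_outcome = b_out,
    ci_low = ci[1], ci_high = ci[2], p_boot = p,
    n_boot = n_boot, n = n, unstable = unstable
  ), class = "causal_result")
}

#' @export
print.causal_result <- function(x, ...) {
  cat(sprintf("causal_result: beta = %.4f [%.4f, %.4f], p_boot = %.4g%s\n",
              x$beta_causal, x$ci_low, x$ci_high, x$p_boot,
              if (x$unstable) " (UNSTABLE)" else ""))
  invisible(x)
}

#' Bidirectional Mendelian randomization over network edges
#'
#' For every network edge with an instrument for the metabolite side and/or
#' the transcript side, runs [bootstrap_causal_test()] in the
#' corresponding direction(s) and applies BH q-values across all tested
#' (edge, direction) pairs.
#'
#' @param network a [threshold_and_build()] result.
#' @param metabolome,transcriptome residual-scale [omics_matrix()] objects.
#' @param genotypes samples x SNPs dosage matrix.
#' @param covariates data frame with `age`, `sex`.
#' @param instruments an [filter_instruments()] result; `trait` entries
#'   must name metabolite or transcript features.
#' @param n_boot,fdr,seed bootstrap replicates, FDR level, base seed.
#' @return data frame with one row per tested (edge, direction):
#'   `metabolite`, `transcript`, `direction`, `snp`, `beta_causal`,
#'   `ci_low`, `ci_high`, `p_boot`, `q`, `unstable`.
#' @export
mr_test_edges <- function(network, metabolome, transcriptome, genotypes,
                          covariates, instruments,
                          n_boot = 10000, fdr = 0.05, seed = 1L) {
  stopifnot(inherits(network, "bipartite_network"))
  get_feat <- function(id) {
    if (id %in% colnames(metabolome)) metabolome[, id] else transcriptome[, id]
  }
  ## strongest instrument per trait
  best <- do.call(rbind, lapply(split(instruments, instruments$trait),
                                function(d) d[which.min(d$p), ]))
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(network$edges))) {
    met <- network$edges$metabolite[i]
    tx <- network$edges$transcript[i]
    for (dir in c("Met->mRNA", "mRNA->Met")) {
      exp_id <- if (dir == "Met->mRNA") met else tx
      out_id <- if (dir == "Met->mRNA") tx else met
      inst <- best[best$trait == exp_id, ]
      if (!nrow(inst)) next
      k <- k + 1L
      r <- bootstrap_causal_test(get_feat(exp_id), get_feat(out_id),
                                 genotypes[, inst$snp], covariates,
                                 n_boot = n_boot, seed = seed + k)
      rows[[k]] <- data.frame(
        metabolite = met, transcript = tx, direction = dir, snp = inst$snp,
        beta_causal = r$beta_causal, ci_low = r$ci_low, ci_high = r$ci_high,
        p_boot = r$p_boot, unstable = r$unstable
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(metabolite = character(0), transcript = character(0),
                      direction = character(0), snp = character(0),
                      beta_causal = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_boot = numeric(0),
                      q = numeric(0), unstable = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_boot)
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}
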