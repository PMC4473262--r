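test_that("generators are bit-identical under a fixed seed", {
  cfg <- tiny_config()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(generate_toy_model(cfg), generate_toy_model(cfg))
  gs <- list(setA = c("T001", "T002", "T003"))
  expect_identical(generate_motif_hits(cfg, gs), generate_motif_hits(cfg, gs))
})

test_that("config validation rejects broken worlds", {
  expect_error(synth_config(n_samples = 0), "configuration error")
  expect_error(synth_config(module_rho = 1), "configuration error")
  expect_error(synth_config(missing_rate_range = c(0.7, 0.2)), "configuration error")
  cfg <- tiny_config(causal_chains = list(list(
    snp = "rs0001", exposure = "NOPE", outcome = "T001",
    beta_gx = 0.4, beta_xy = 0.7)))
  expect_error(generate_cohort(cfg), "unknown feature")
})

## Planted-pair Spearman correlations are measured after age/sex adjustment,
## since the covariate effects are injected on top of the latent block
## construction (and the pipeline always adjusts before correlating).
planted_rhos <- function(cfg) {
  co <- generate_cohort(cfg)
  mres <- log_and_adjust(co$metabolome, co$covariates)
  tres <- log_and_adjust(co$transcriptome, co$covariates)
  tr <- co$truth$planted_edges
  mapply(function(m, t) stats::cor(mres[, m], tres[, t], method = "spearman"),
         tr$metabolite, tr$transcript)
}

test_that("planted correlation blocks hit their target rho", {
  base <- list(n_samples = 2000, n_metabolites = 10, n_transcripts = 30,
               n_modules = 2, module_size = 3,
               missing_rate_range = c(0, 0), seed = 1)
  ## null case: |rho| < 3/sqrt(n)
  r0 <- do.call(planted_rhos,
                list(do.call(synth_config, c(base, module_rho = 0))))
  expect_lt(max(abs(r0)), 0.07)
  ## planted case: within +/- 0.05 of the target (Fisher-z sampling bound)
  r5 <- do.call(planted_rhos,
                list(do.call(synth_config, c(base, module_rho = 0.5))))
  expect_lt(max(abs(r5 - 0.5)), 0.05)
  ## negative targets work too
  rn <- do.call(planted_rhos,
                list(do.call(synth_config, c(base, module_rho = -0.4))))
  expect_lt(max(abs(rn + 0.4)), 0.05)
})

test_that("metabolome is positive where observed and exercises the filter", {
  co <- generate_cohort(tiny_config())
  expect_true(all(co$metabolome > 0, na.rm = TRUE))
  expect_false(anyNA(co$transcriptome))
  expect_true(any(colMeans(is.na(co$metabolome)) > 0.5))
  expect_true(all(co$genotypes %in% 0:2))
})

test_that("planted causal chains are recoverable by regression", {
  ## outcome ~ genotype recovers beta_gx * beta_xy within 2 SE in >= 95% of
  ## 100 seeds (total-effect identity of the chain)
  hits <- 0L
  for (s in 1:100) {
    cfg <- synth_config(n_samples = 300, n_metabolites = 8, n_transcripts = 12,
                        n_modules = 0, module_size = 0, n_snps = 5,
                        missing_rate_range = c(0, 0),
                        causal_chains = list(list(
                          snp = "rs0001", exposure = "M001", outcome = "T001",
                          beta_gx = 0.4, beta_xy = 0.7)),
                        seed = s)
    co <- generate_cohort(cfg)
    d <- data.frame(y = log(co$transcriptome[, "T001"]),
                    g = co$genotypes[, "rs0001"],
                    age = co$covariates$age, sex = co$covariates$sex)
    cf <- summary(stats::lm(y ~ g + age + sex, data = d))$coefficients
    if (abs(cf["g", 1] - 0.4 * 0.7) <= 2 * cf["g", 2]) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("toy model records correct ground-truth chain distances", {
  cfg <- tiny_config()
  model <- generate_toy_model(cfg)
  tr <- model$truth$distances
  ## chain semantics: d(M1, gene of R1) = 0, d(M1, gene of R2) = 1
  expect_equal(tr$d[tr$metabolite == "C1M1" & tr$gene == "G1_1"], 0)
  expect_equal(tr$d[tr$metabolite == "C1M1" & tr$gene == "G1_2"], 1)
  ## walking backwards: d(M3, gene of R1) = 1
  expect_equal(tr$d[tr$metabolite == "C1M3" & tr$gene == "G1_1"], 1)
  ## currency metabolites attached to reactions on more than one chain
  cur_rxns <- Filter(function(r) any(startsWith(r$mets, "atp")) ||
                       any(startsWith(r$mets, "h2o")), model$reactions)
  chains <- unique(sub("R.*$", "", vapply(cur_rxns, `[[`, character(1), "id")))
  expect_gt(length(chains), 1L)
  ## duplicated compartment copy present
  expect_true(all(c("C1M1_c", "C1M1_m") %in% model$metabolites$id))
})

test_that("motif hit tables have planted enrichment structure", {
  cfg <- tiny_config(n_motifs = 10)
  genes <- sprintf("T%03d", 1:40)
  set <- genes[1:8]
  hits <- generate_motif_hits(cfg, list(myset = set))
  expect_true(all(hits >= 0))
  expect_true(all(hits == floor(hits)))
  expect_identical(attr(hits, "planted"), c(motif_01 = "myset"))
  expect_error(
    generate_motif_hits(synth_config(n_transcripts = 0, n_modules = 0,
                                     module_size = 0)),
    "empty gene universe")
  expect_error(generate_motif_hits(cfg, list(c("NOPE"))), "outside universe")

  ## perfect split p_in = 1, p_out = 0: enrichment p equals the
  ## hypergeometric tail for a perfect split
  cfg2 <- tiny_config(n_motifs = 3, motif_p_in = 1, motif_p_out = 0)
  h2 <- generate_motif_hits(cfg2, list(s = set))
  e <- motif_enrichment(set, setdiff(genes, set), h2)
  expect_equal(e$p[e$motif == "motif_01"],
               hyper_tail_oracle(8, N = 40, K = 8, n = 8))
  expect_equal(e$frac_with_hit[e$motif == "motif_01"], 1)
})

test_that("null motif enrichment p-values are uniform across seeds", {
  ## p_in == p_out: hypergeometric p over 200 seeds passes a KS test at 0.01
  genes <- sprintf("T%03d", 1:300)
  set <- genes[1:40]
  ps <- vapply(1:200, function(s) {
    cfg <- synth_config(n_samples = 10, n_transcripts = 300, n_modules = 0,
                        module_size = 0, n_motifs = 1,
                        motif_p_in = 0.5, motif_p_out = 0.5, seed = s)
    h <- generate_motif_hits(cfg, list(s = set))
    motif_enrichment(set, setdiff(genes, set), h)$p[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("traits are antagonistic on shared features", {
  co <- generate_cohort(tiny_config(n_samples = 500))
  expect_lt(stats::cor(co$traits$HDL, co$traits$TG), -0.5)
  expect_equal(unname(co$truth$trait_loadings[c("HDL", "TG")]), c(-1, 1))
})
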