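#' Configuration for synthetic cohort generation
#'
#' Captures the stated world every downstream stage assumes: a population
#' cohort of elderly adults (712 individuals, age 68.82 +/- 4.31 years,
#' roughly balanced sexes), log-normal metabolite concentrations with
#' per-feature missingness up to 60%, a complete transcript matrix, planted
#' metabolite-transcript correlation blocks, independent additively-coded
#' SNPs with optional planted SNP -> exposure -> outcome causal chains, and
#' anticorrelated HDL-like / TG-like lipid traits.
#'
#' @param n_samples number of individuals (default 712).
#' @param n_metabolites,n_transcripts feature counts.
#' @param n_modules number of planted correlation blocks; block `k` couples
#'   one hub metabolite to `module_size` transcripts.
#' @param module_size transcripts per planted block.
#' @param module_rho target population Spearman correlation of each planted
#'   metabolite-transcript pair, `|module_rho| < 1`.
#' @param missing_rate_range `c(lo, hi)` range of per-metabolite MCAR
#'   missingness fractions. When `hi > 0.5` one non-planted metabolite is
#'   forced above 50% missing so the quality filter is exercised.
#' @param age_mean,age_sd,age_range age distribution (years), truncated
#'   normal on `age_range`.
#' @param beta_age,beta_sex additive age (per year) and sex effects injected
#'   on the log scale of every feature.
#' @param n_snps number of independent SNPs; minor allele frequencies are
#'   drawn uniformly from `maf_range`.
#' @param maf_range range of minor allele frequencies.
#' @param causal_chains list of lists with elements `snp`, `exposure`,
#'   `outcome`, `beta_gx`, `beta_xy` describing planted causal chains
#'   genotype -> exposure feature -> outcome feature.
#' @param trait_spec list with elements `features` (feature IDs the lipid
#'   traits load on; default: the first planted block), `loading_hdl`,
#'   `loading_tg`, `loading_ldl` (signed loadings) and `noise_sd`. HDL-like
#'   and TG-like traits get opposite-sign loadings by default.
#' @param n_motifs,motif_p_in,motif_p_out motif-hit table shape: number of
#'   motifs, hit probability of a planted motif inside its designated gene
#'   set and outside it.
#' @param toy_chains,toy_chain_length shape of the toy metabolic model:
#'   number of linear reaction chains and reactions per chain.
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   bit-identical across calls.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_samples = 712,
                         n_metabolites = 60,
                         n_transcripts = 300,
                         n_modules = 4,
                         module_size = 5,
                         module_rho = 0.5,
                         missing_rate_range = c(0.05, 0.6),
                         age_mean = 68.82,
                         age_sd = 4.31,
                         age_range = c(55, 85),
                         beta_age = 0.05,
                         beta_sex = 0.3,
                         n_snps = 30,
                         maf_range = c(0.1, 0.5),
                         causal_chains = NULL,
                         trait_spec = NULL,
                         n_motifs = 50,
                         motif_p_in = 0.8,
                         motif_p_out = 0.1,
                         toy_chains = 3,
                         toy_chain_length = 6,
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_metabolites = as.integer(n_metabolites),
    n_transcripts = as.integer(n_transcripts), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), module_rho = module_rho,
    missing_rate_range = missing_rate_range, age_mean = age_mean,
    age_sd = age_sd, age_range = age_range, beta_age = beta_age,
    beta_sex = beta_sex, n_snps = as.integer(n_snps), maf_range = maf_range,
    causal_chains = causal_chains, trait_spec = trait_spec,
    n_motifs = as.integer(n_motifs), motif_p_in = motif_p_in,
    motif_p_out = motif_p_out, toy_chains = as.integer(toy_chains),
    toy_chain_length = as.integer(toy_chain_length), seed = as.integer(seed)
  )
  counts <- c("n_samples", "n_metabolites", "n_transcripts", "n_modules",
              "module_size", "n_snps", "n_motifs", "toy_chains", "toy_chain_length")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop(sprintf("configuration error: %s must be a non-negative count", f))
    }
  }
  if (cfg$n_samples <= 0L) stop("configuration error: n_samples must be positive")
  if (abs(cfg$module_rho) >= 1) stop("configuration error: |module_rho| must be < 1")
  mr <- cfg$missing_rate_range
  if (length(mr) != 2 || mr[1] < 0 || mr[2] > 1 || mr[1] > mr[2]) {
    stop("configuration error: missing_rate_range must satisfy 0 <= lo <= hi <= 1")
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_transcripts ||
      cfg$n_modules > cfg$n_metabolites) {
    stop("configuration error: planted modules exceed available features")
  }
  class(cfg) <- "synth_config"
  cfg
}

feature_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate a synthetic cohort
#'
#' Draws a full multi-omics cohort under `config`: metabolome (raw positive
#' concentrations with MCAR missingness), transcriptome (complete, raw
#' positive), covariates (age, sex), genotypes (additive 0/1/2), lipid
#' traits (HDL/LDL/TG in mg/dl) and a `truth` record of everything planted.
#'
#' Planted correlation blocks use a shared Gaussian latent factor on the log
#' scale; per-pair latent Pearson correlation is calibrated as
#' `r = 2 sin(pi * module_rho / 6)` so the population Spearman correlation
#' of each planted pair equals `module_rho` (rank correlation is invariant
#' to the exponentiation into concentrations). Age and sex effects are
#' injected additively on the log scale. For each causal chain the exposure
#' latent is `beta_gx * G + N(0,1)` and the outcome latent
#' `beta_xy * exposure + N(0,1)`.
#'
#' @param config a [synth_config()].
#' @return a `synthetic_cohort` list with elements `metabolome`,
#'   `transcriptome` (both [omics_matrix()]), `covariates`, `genotypes`,
#'   `traits` (data.frames keyed by sample), and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  met_ids <- feature_ids("M", config$n_metabolites)
  tx_ids <- feature_ids("T", config$n_transcripts)

  age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)

  ## latent log-scale signals
  met_lat <- matrix(stats::rnorm(n * config$n_metabolites), n, config$n_metabolites,
                    dimnames = list(samples, met_ids))
  tx_lat <- matrix(stats::rnorm(n * config$n_transcripts), n, config$n_transcripts,
                   dimnames = list(samples, tx_ids))

  ## planted blocks: hub metabolite k <-> module_size transcripts
  r_latent <- 2 * sin(pi * config$module_rho / 6)
  a <- sqrt(abs(r_latent))
  sgn <- sign(r_latent + (r_latent == 0))
  planted <- NULL
  if (config$n_modules > 0L && config$module_size > 0L) {
    rows <- vector("list", config$n_modules)
    for (k in seq_len(config$n_modules)) {
      f <- stats::rnorm(n)
      hub <- met_ids[k]
      met_lat[, hub] <- a * f + sqrt(1 - a^2) * stats::rnorm(n)
      tx_block <- tx_ids[((k - 1) * config$module_size + 1):(k * config$module_size)]
      for (tx in tx_block) {
        tx_lat[, tx] <- sgn * a * f + sqrt(1 - a^2) * stats::rnorm(n)
      }
      rows[[k]] <- data.frame(metabolite = hub, transcript = tx_block,
                              rho = config$module_rho, module = k)
    }
    planted <- do.call(rbind, rows)
  }

  ## genotypes
  geno <- NULL
  snp_ids <- character(0)
  if (config$n_snps > 0L) {
    snp_ids <- sprintf("rs%04d", seq_len(config$n_snps))
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    geno <- sapply(maf, function(q) stats::rbinom(n, 2, q))
    dimnames(geno) <- list(samples, snp_ids)
  }

  ## causal chains override the latents of their endpoint features
  chains <- config$causal_chains
  if (!is.null(chains)) {
    all_feats <- c(met_ids, tx_ids)
    for (ch in chains) {
      need <- c("snp", "exposure", "outcome", "beta_gx", "beta_xy")
      if (!all(need %in% names(ch))) {
        stop("configuration error: causal chain missing fields")
      }
      if (!(ch$snp %in% snp_ids)) {
        stop(sprintf("configuration error: unknown SNP '%s' in causal chain", ch$snp))
      }
      if (!all(c(ch$exposure, ch$outcome) %in% all_feats)) {
        stop("configuration error: causal chain references unknown feature")
      }
      g <- geno[, ch$snp]
      x <- ch$beta_gx * g + stats::rnorm(n)
      y <- ch$beta_xy * x + stats::rnorm(n)
      assign_lat <- function(id, v) {
        if (id %in% met_ids) met_lat[, id] <<- v else tx_lat[, id] <<- v
      }
      assign_lat(ch$exposure, x)
      assign_lat(ch$outcome, y)
    }
  }

  ## assemble log-scale values: baseline + covariate effects + latent
  age_c <- age - config$age_mean
  cov_eff <- config$beta_age * age_c + config$beta_sex * sex
  met_base <- stats::rnorm(config$n_metabolites, mean = 3, sd = 0.5)
  tx_base <- stats::rnorm(config$n_transcripts, mean = 5, sd = 0.5)
  log_met <- sweep(met_lat, 2, met_base, `+`) + cov_eff
  log_tx <- sweep(tx_lat, 2, tx_base, `+`) + cov_eff

  metab <- exp(log_met)
  transc <- exp(log_tx)

  ## MCAR missingness, per-metabolite rate drawn from the configured range
  rates <- stats::runif(config$n_metabolites,
                        config$missing_rate_range[1], config$missing_rate_range[2])
  hi <- config$missing_rate_range[2]
  planted_mets <- if (is.null(planted)) character(0) else unique(planted$metabolite)
  ## planted hubs must survive the standard 50% quality filter, otherwise
  ## the planted truth is untestable downstream: cap their rate at 0.5
  if (length(planted_mets)) {
    idx <- match(planted_mets, met_ids)
    rates[idx] <- pmin(rates[idx], 0.5)
  }
  if (hi > 0.5 && config$n_metabolites > 0L) {
    free <- setdiff(met_ids, planted_mets)
    forced <- if (length(free)) free[length(free)] else met_ids[config$n_metabolites]
    rates[match(forced, met_ids)] <- hi
  }
  for (j in seq_len(config$n_metabolites)) {
    n_miss <- if (hi > 0.5 && rates[j] == hi && rates[j] > 0.5) {
      ceiling(n * rates[j])          # guarantee strictly > 50% missing
    } else {
      round(n * rates[j])
    }
    if (n_miss > 0) metab[sample.int(n, n_miss), j] <- NA_real_
  }

  ## lipid traits: antagonistic HDL-like / TG-like loadings on shared features
  ts <- config$trait_spec %||% list()
  shared <- ts$features %||% (if (!is.null(planted)) {
    c(planted$metabolite[planted$module == 1][1],
      planted$transcript[planted$module == 1])
  } else c(met_ids[seq_len(min(2, length(met_ids)))],
           tx_ids[seq_len(min(3, length(tx_ids)))]))
  loading_hdl <- ts$loading_hdl %||% -1
  loading_tg <- ts$loading_tg %||% 1
  loading_ldl <- ts$loading_ldl %||% 0
  noise_sd <- ts$noise_sd %||% 0.5
  lat_all <- cbind(met_lat, tx_lat)
  sig <- rowMeans(lat_all[, shared, drop = FALSE])
  std1 <- function(v) (v - mean(v)) / stats::sd(v)
  hdl <- 55.80 + 13.95 * std1(loading_hdl * sig + noise_sd * stats::rnorm(n))
  tg <- 132.64 + 75.70 * std1(loading_tg * sig + noise_sd * stats::rnorm(n))
  ldl <- 140.60 + 35.97 * std1(loading_ldl * sig + stats::rnorm(n))
  traits <- data.frame(sample = samples, HDL = hdl, LDL = ldl, TG = tg,
                       row.names = samples)

  structure(list(
    metabolome = omics_matrix(metab, "raw"),
    transcriptome = omics_matrix(transc, "raw"),
    covariates = data.frame(sample = samples, age = age, sex = sex,
                            row.names = samples),
    genotypes = geno,
    traits = traits,
    truth = list(
      planted_edges = planted,
      causal = if (is.null(chains)) NULL else do.call(rbind, lapply(chains, as.data.frame)),
      trait_features = shared,
      trait_loadings = c(HDL = loading_hdl, TG = loading_tg, LDL = loading_ldl),
      beta_age = config$beta_age, beta_sex = config$beta_sex,
      missing_rates = stats::setNames(rates, met_ids)
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples, %d metabolites, %d transcripts, %d SNPs\n",
    nrow(x$metabolome), ncol(x$metabolome), ncol(x$transcriptome),
    if (is.null(x$genotypes)) 0L else ncol(x$genotypes)
  ))
  invisible(x)
}

#' Generate a toy compartmentalized metabolic model
#'
#' Emits `toy_chains` linear reaction chains (metabolite - reaction -
#' metabolite - ...), one gene and one subsystem label per reaction, in the
#' style of a carnitine-shuttle fragment of a genome-scale reconstruction.
#' The raw model is deliberately messy in the two ways a real
#' reconstruction is: two designated currency metabolites are attached to
#' reactions on otherwise disjoint chains, and the first metabolite of
#' chain 1 is duplicated across two compartments with a pure transport
#' reaction between the copies. Ground-truth reaction-step distances of all
#' within-chain (metabolite, gene) pairs are recorded for round-trip
#' testing.
#'
#' @param config a [synth_config()] (uses `toy_chains`, `toy_chain_length`,
#'   `seed`).
#' @return a [metabolic_model()] whose `truth$distances` data frame holds
#'   the planted distances on merged (compartment-free) identifiers.
#' @export
generate_toy_model <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 101L)
  nc <- config$toy_chains
  L <- config$toy_chain_length
  mets <- list()
  reactions <- list()
  truth <- list()
  currency <- c("atp", "h2o")
  for (cur in currency) {
    mets[[paste0(cur, "_c")]] <- list(id = paste0(cur, "_c"), compartment = "c",
                                      kegg = NA_character_, hmdb = NA_character_)
  }
  for (c_i in seq_len(nc)) {
    met_base <- sprintf("C%dM%d", c_i, seq_len(L + 1))
    for (i in seq_len(L + 1)) {
      id <- paste0(met_base[i], "_c")
      mets[[id]] <- list(id = id, compartment = "c",
                         kegg = sprintf("K%d%03d", c_i, i),
                         hmdb = sprintf("HMDB%d%04d", c_i, i))
    }
    for (j in seq_len(L)) {
      rid <- sprintf("C%dR%d", c_i, j)
      parts <- c(paste0(met_base[j], "_c"), paste0(met_base[j + 1], "_c"))
      ## every other reaction also consumes a currency co-factor,
      ## alternating between the two so both bridge disjoint chains
      if (j %% 2 == 1) parts <- c(parts, paste0(currency[((c_i + j) %% 2) + 1], "_c"))
      reactions[[rid]] <- list(id = rid, mets = parts,
                               genes = sprintf("G%d_%d", c_i, j),
                               subsystem = sprintf("subsystem_%d", c_i))
    }
    ## truth distances on merged ids: d(M_i, gene of R_j)
    grid <- expand.grid(i = seq_len(L + 1), j = seq_len(L))
    d <- ifelse(grid$j >= grid$i, grid$j - grid$i, grid$i - grid$j - 1)
    truth[[c_i]] <- data.frame(
      metabolite = met_base[grid$i],
      gene = sprintf("G%d_%d", c_i, grid$j),
      d = d
    )
  }
  ## duplicated compartment copy of chain 1's first metabolite + transport
  if (nc > 0L && L > 0L) {
    dup <- "C1M1_m"
    mets[[dup]] <- list(id = dup, compartment = "m",
                        kegg = "K1001", hmdb = "HMDB10001")
    reactions[["TR1"]] <- list(id = "TR1", mets = c("C1M1_c", dup),
                               genes = character(0), subsystem = "transport")
  }
  metabolic_model(
    metabolites = do.call(rbind, lapply(mets, function(m) {
      data.frame(id = m$id, compartment = m$compartment,
                 kegg = m$kegg, hmdb = m$hmdb)
    })),
    reactions = unname(reactions),
    currency = currency,
    truth = list(distances = do.call(rbind, truth))
  )
}

#' Generate a gene x motif occurrence-count table
#'
#' Plants one enriched motif per supplied gene set: inside its designated
#' set the motif hits with probability `motif_p_in`, outside with
#' `motif_p_out < motif_p_in`. All remaining motifs hit uniformly at
#' `motif_p_out` across the whole universe. A hit contributes
#' `1 + Poisson(0.5)` occurrences.
#'
#' @param config a [synth_config()].
#' @param gene_sets named list of character vectors; members must belong to
#'   the transcript universe implied by `config`.
#' @return integer matrix (genes x motifs) of class `motif_hit_table` with
#'   a `planted` attribute mapping planted motifs to their sets.
#' @export
generate_motif_hits <- function(config, gene_sets = list()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 202L)
  genes <- feature_ids("T", config$n_transcripts)
  if (length(genes) == 0L) stop("empty gene universe")
  bad <- setdiff(unlist(gene_sets), genes)
  if (length(bad)) {
    stop(sprintf("gene set members outside universe: %s", paste(bad, collapse = ", ")))
  }
  motifs <- sprintf("motif_%02d", seq_len(config$n_motifs))
  hit_count <- function(p, k) {
    hit <- stats::rbinom(k, 1, p)
    as.integer(hit * (1L + stats::rpois(k, 0.5)))
  }
  counts <- matrix(0L, length(genes), length(motifs),
                   dimnames = list(genes, motifs))
  n_planted <- min(length(gene_sets), length(motifs))
  planted <- character(0)
  for (i in seq_len(length(motifs))) {
    if (i <= n_planted) {
      inside <- genes %in% gene_sets[[i]]
      counts[inside, i] <- hit_count(config$motif_p_in, sum(inside))
      counts[!inside, i] <- hit_count(config$motif_p_out, sum(!inside))
      nm <- names(gene_sets)[i]
      if (is.null(names(gene_sets)) || is.na(nm) || !nzchar(nm)) {
        nm <- sprintf("set_%d", i)
      }
      planted[motifs[i]] <- nm
    } else {
      counts[, i] <- hit_count(config$motif_p_out, length(genes))
    }
  }
  structure(counts, planted = planted,
            class = c("motif_hit_table", "matrix", "array"))
}
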