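## Independent oracles used to check the package implementations. These are
## deliberately naive (quadratic, enumeration, hand-rolled BFS) and share no
## code with the package internals.

## Brute-force Benjamini-Hochberg: for each observed p-value check the
## step-up condition by counting, then reject everything at or below the
## largest passing p. O(n^2).
bh_reject_oracle <- function(p, q, m = length(p)) {
  pass <- vapply(p, function(pi) pi <= sum(p <= pi) * q / m, logical(1))
  if (!any(pass)) return(rep(FALSE, length(p)))
  p <= max(p[pass])
}

## Hand-written breadth-first search over the metabolite-reaction incidence
## structure of a prepared model. Returns the number of reaction steps from
## `met` to the nearest reaction catalyzed by `gene` (0 = direct reactant),
## Inf if disconnected, NA if unmapped.
bfs_distance_oracle <- function(model, met, gene) {
  rxn_of_gene <- vapply(model$reactions,
                        function(r) gene %in% r$genes, logical(1))
  if (!met %in% model$metabolites$id || !any(rxn_of_gene)) return(NA_real_)
  ## adjacency: metabolite -> reactions, reaction -> metabolites
  met2rxn <- list()
  rxn2met <- list()
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    rxn2met[[r$id]] <- r$mets
    for (mm in r$mets) met2rxn[[mm]] <- c(met2rxn[[mm]], r$id)
  }
  targets <- vapply(model$reactions[rxn_of_gene], `[[`, character(1), "id")
  ## BFS over metabolites; depth d reaches reactions at distance d
  frontier <- met
  seen <- met
  d <- 0
  repeat {
    rxns <- unique(unlist(met2rxn[frontier]))
    if (length(intersect(rxns, targets))) return(d)
    nxt <- setdiff(unique(unlist(rxn2met[rxns])), seen)
    if (!length(nxt)) return(Inf)
    seen <- c(seen, nxt)
    frontier <- nxt
    d <- d + 1
  }
}

## One-tailed Fisher p for over-representation in a 2x2 table
## [[a, b], [c, d]] (a = significant & in band), by direct enumeration of
## the hypergeometric tail using binomial coefficients.
fisher_tail_oracle <- function(a, b, c, d) {
  K <- a + b      # significant pairs
  n <- a + c      # pairs in band
  N <- a + b + c + d
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## Hypergeometric upper tail P(X >= k) by enumeration (same parametrization
## as the motif enrichment backend: N genes, K with a hit, n drawn).
hyper_tail_oracle <- function(k, N, K, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## Small default config shared by tests: fast but non-trivial.
tiny_config <- function(...) {
  args <- list(n_samples = 200, n_metabolites = 15, n_transcripts = 40,
               n_modules = 2, module_size = 4, module_rho = 0.5,
               n_snps = 10, seed = 7)
  do.call(synth_config, utils::modifyList(args, list(...)))
}
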