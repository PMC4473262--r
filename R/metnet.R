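#' Metabolic model container
#'
#' Minimal representation of a genome-scale metabolic reconstruction:
#' metabolites (with compartment and external KEGG/HMDB references),
#' reactions (participant metabolite sets, flattened gene association,
#' subsystem label) and a currency-metabolite list.
#'
#' @param metabolites data frame with columns `id`, `compartment` and
#'   optionally `kegg`, `hmdb`.
#' @param reactions list of lists with elements `id`, `mets` (participant
#'   metabolite IDs), `genes` (character vector; boolean AND/OR structure
#'   is flattened to the gene set) and `subsystem`.
#' @param currency character vector of currency metabolite base IDs.
#' @param truth optional ground-truth record (used by the toy generator).
#' @param prepared logical; set by [prepare_model()].
#' @return a `metabolic_model` object.
#' @export
metabolic_model <- function(metabolites, reactions, currency = character(0),
                            truth = NULL, prepared = FALSE) {
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  for (r in reactions) {
    if (length(r$mets) < 1L) stop(sprintf("reaction %s has no participants", r$id))
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 currency = currency, truth = truth, prepared = prepared),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions%s\n",
              nrow(x$metabolites), length(x$reactions),
              if (x$prepared) " (prepared)" else ""))
  invisible(x)
}

strip_compartment <- function(ids, regex) sub(regex, "", ids)

#' Prepare a metabolic model for distance calculation
#'
#' Three cleanup steps on a raw compartmentalized reconstruction:
#' (1) compartment merging -- species sharing a base identity across
#' compartments (compartment suffix stripped by `compartment_regex`,
#' default Recon-style `_c`/`_m` or `[c]` suffixes) become one node;
#' reactions whose merged participant set collapses to a single node (pure
#' transport self-loops) are dropped, and duplicate reactions with
#' identical participant sets are collapsed (gene sets unioned);
#' (2) currency metabolites and all their incidences are removed
#' (reactions left without participants are dropped); (3) the graph is
#' treated as undirected thereafter. Idempotent.
#'
#' @param model a [metabolic_model()].
#' @param currency currency metabolite base IDs; defaults to the model's
#'   own list. IDs absent from the model yield a warning only.
#' @param compartment_regex regex matching the compartment suffix to strip.
#' @return the prepared `metabolic_model` (no compartment tags remain).
#' @export
prepare_model <- function(model, currency = NULL,
                          compartment_regex = "(_[a-z][a-z0-9]?|\\[[a-z]\\])$") {
  stopifnot(inherits(model, "metabolic_model"))
  currency <- currency %||% model$currency
  mets <- model$metabolites
  base <- strip_compartment(mets$id, compartment_regex)
  merged <- mets[!duplicated(base), , drop = FALSE]
  merged$id <- base[!duplicated(base)]
  merged$compartment <- NA_character_
  missing_cur <- setdiff(currency, merged$id)
  if (length(missing_cur) && !model$prepared) {
    warning(sprintf("currency id(s) not in model: %s",
                    paste(missing_cur, collapse = ", ")))
  }
  rx <- list()
  seen <- character(0)
  for (r in model$reactions) {
    parts <- unique(strip_compartment(r$mets, compartment_regex))
    if (length(parts) < 2L) next              # pure transport self-loop
    parts <- setdiff(parts, currency)         # currency incidences deleted
    if (length(parts) < 1L) next
    key <- paste(sort(parts), collapse = "|")
    if (key %in% seen) {
      i <- match(key, seen)
      rx[[i]]$genes <- union(rx[[i]]$genes, r$genes)
    } else {
      seen <- c(seen, key)
      rx[[length(rx) + 1L]] <- list(id = r$id, mets = parts,
                                    genes = r$genes, subsystem = r$subsystem)
    }
  }
  merged <- merged[!merged$id %in% currency, , drop = FALSE]
  rownames(merged) <- NULL
  metabolic_model(merged, rx, currency = currency,
                  truth = model$truth, prepared = TRUE)
}

## Undirected bipartite metabolite-reaction incidence graph.
model_graph <- function(model) {
  rx_ids <- vapply(model$reactions, `[[`, character(1), "id")
  edges <- do.call(rbind, lapply(model$reactions, function(r) {
    cbind(paste0("met:", r$mets), paste0("rxn:", r$id))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  iso <- setdiff(paste0("met:", model$metabolites$id), igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}

#' Metabolite-gene reaction-step distances
#'
#' Shortest-path distance between metabolites and enzyme-coding genes on
#' the undirected metabolite-reaction incidence graph of a prepared model.
#' The distance is the minimal number of reaction steps: 0 when the
#' metabolite is a direct reactant of a reaction catalyzed by the gene,
#' 1 when one reaction lies between them, and so on (minimum over all
#' reactions the gene catalyzes). `NA` ("not mapped") marks metabolites or
#' genes absent from the model, `Inf` mapped-but-disconnected pairs.
#'
#' @param model a prepared [metabolic_model()].
#' @param metabolite_ids,gene_ids identifiers to score (model metabolite
#'   IDs and gene IDs as used in the reactions' `genes` sets).
#' @return a `distance_table` data frame (`metabolite`, `gene`, `d`).
#' @export
pairwise_distances <- function(model, metabolite_ids, gene_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!model$prepared) {
    stop("model must be prepared (prepare_model) before distance calculation")
  }
  g <- model_graph(model)
  rx_ids <- vapply(model$reactions, `[[`, character(1), "id")
  gene_rxns <- lapply(stats::setNames(gene_ids, gene_ids), function(gid) {
    rx_ids[vapply(model$reactions, function(r) gid %in% r$genes, logical(1))]
  })
  vnames <- igraph::V(g)$name
  met_nodes <- paste0("met:", metabolite_ids)
  met_ok <- met_nodes %in% vnames & metabolite_ids %in% model$metabolites$id
  all_rxn_nodes <- paste0("rxn:", unique(unlist(gene_rxns)))
  all_rxn_nodes <- intersect(all_rxn_nodes, vnames)
  D <- NULL
  if (any(met_ok) && length(all_rxn_nodes)) {
    D <- igraph::distances(g, v = met_nodes[met_ok], to = all_rxn_nodes)
  }
  grid <- expand.grid(metabolite = metabolite_ids, gene = gene_ids,
                      stringsAsFactors = FALSE)
  grid$d <- NA_real_
  for (i in seq_len(nrow(grid))) {
    if (!met_ok[match(grid$metabolite[i], metabolite_ids)]) next
    rxns <- gene_rxns[[grid$gene[i]]]
    if (!length(rxns)) next                     # gene unmapped -> NM
    nodes <- intersect(paste0("rxn:", rxns), colnames(D))
    if (!length(nodes)) next
    len <- min(D[paste0("met:", grid$metabolite[i]), nodes])
    ## path length in the bipartite graph is 2k - 1 edges for k reactions
    grid$d[i] <- if (is.infinite(len)) Inf else (len - 1) / 2
  }
  structure(grid, class = c("distance_table", "data.frame"))
}

#' Enrichment of significant pairs at short metabolic distances
#'
#' For each finite distance `d` (individually) and each cumulative band
#' `<= d`, builds the 2x2 table of (significant vs not) x (in band vs not)
#' over all finite-distance pairs and reports the one-tailed Fisher exact
#' p-value for over-representation of significant pairs in the band.
#' Additionally, for distances 0..2, tabulates subsystem annotations among
#' significant pairs (relative frequencies of the subsystems of the
#' reactions realizing the pair's distance).
#'
#' @param distances a [pairwise_distances()] table.
#' @param significant logical vector aligned to `distances` rows flagging
#'   pairs that are network edges.
#' @param model optional prepared model; needed for the subsystem table.
#' @return list with `per_distance` and `cumulative` data frames
#'   (`d`, `n_band`, `n_sig_band`, `p`, `empty`), and `subsystems` (list
#'   by distance 0..2 of named frequency vectors) when `model` is given.
#' @export
distance_enrichment <- function(distances, significant, model = NULL) {
  stopifnot(inherits(distances, "distance_table"),
            length(significant) == nrow(distances))
  fin <- is.finite(distances$d)
  d <- distances$d[fin]
  sig <- significant[fin]
  if (!length(d)) stop("no finite-distance pairs")
  ds <- sort(unique(d))
  one_test <- function(in_band) {
    n11 <- sum(sig & in_band); n12 <- sum(sig & !in_band)
    n21 <- sum(!sig & in_band); n22 <- sum(!sig & !in_band)
    if (sum(in_band) == 0L) return(c(p = 1, empty = 1))
    tab <- matrix(c(n11, n21, n12, n22), 2)
    c(p = stats::fisher.test(tab, alternative = "greater")$p.value, empty = 0)
  }
  per <- t(vapply(ds, function(x) one_test(d == x), numeric(2)))
  cum <- t(vapply(ds, function(x) one_test(d <= x), numeric(2)))
  band_n <- function(f) vapply(ds, function(x) sum(f(x)), numeric(1))
  out <- list(
    per_distance = data.frame(
      d = ds, n_band = band_n(function(x) d == x),
      n_sig_band = band_n(function(x) d == x & sig),
      p = per[, 1], empty = as.logical(per[, 2])),
    cumulative = data.frame(
      d = ds, n_band = band_n(function(x) d <= x),
      n_sig_band = band_n(function(x) d <= x & sig),
      p = cum[, 1], empty = as.logical(cum[, 2]))
  )
  if (!is.null(model)) {
    out$subsystems <- subsystem_frequencies(distances, significant, model)
  }
  out
}

## Subsystem frequency among significant pairs at distances 0..2: for each
## such pair, the subsystems of the gene's reactions realizing the minimum
## distance are counted.
subsystem_frequencies <- function(distances, significant, model) {
  g <- model_graph(model)
  rx_ids <- vapply(model$reactions, `[[`, character(1), "id")
  subsys <- vapply(model$reactions, function(r) r$subsystem %||% NA_character_,
                   character(1))
  names(subsys) <- rx_ids
  res <- list()
  for (dd in 0:2) {
    rows <- which(significant & !is.na(distances$d) & distances$d == dd)
    counts <- character(0)
    for (i in rows) {
      gid <- distances$gene[i]
      rxns <- rx_ids[vapply(model$reactions,
                            function(r) gid %in% r$genes, logical(1))]
      if (!length(rxns)) next
      len <- igraph::distances(g, v = paste0("met:", distances$metabolite[i]),
                               to = paste0("rxn:", rxns))[1, ]
      hit <- rxns[(len - 1) / 2 == dd]
      counts <- c(counts, unique(subsys[hit]))
    }
    res[[as.character(dd)]] <- if (length(counts)) {
      sort(table(counts) / length(counts), decreasing = TRUE)
    } else table(character(0))
  }
  res
}
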