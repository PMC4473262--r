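#' Write / read an omics matrix as TSV
#'
#' Samples in rows, a leading `sample` column, header row of feature IDs,
#' empty cell = missing.
#'
#' @param x an [omics_matrix()].
#' @param path file path.
#' @export
write_omics_tsv <- function(x, path) {
  df <- data.frame(sample = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_omics_tsv
#' @param scale_tag scale of the stored values.
#' @export
read_omics_tsv <- function(path, scale_tag = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  storage.mode(m) <- "double"
  omics_matrix(m, scale_tag)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `metabolome.tsv`, `transcriptome.tsv`, `covariates.tsv`,
#' `genotypes.tsv`, `traits.tsv` and the planted-truth sidecar
#' `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_tsv(cohort$metabolome, file.path(dir, "metabolome.tsv"))
  write_omics_tsv(cohort$transcriptome, file.path(dir, "transcriptome.tsv"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$genotypes)) {
    gdf <- data.frame(sample = rownames(cohort$genotypes), cohort$genotypes,
                      check.names = FALSE)
    utils::write.table(gdf, file.path(dir, "genotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write / read a metabolic model as JSON
#'
#' Schema: `{metabolites: [{id, compartment, kegg, hmdb}], reactions:
#' [{id, mets, genes, subsystem}], currency: [...]}`.
#'
#' @param model a [metabolic_model()].
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  obj <- list(
    metabolites = model$metabolites,
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, mets = as.list(r$mets), genes = as.list(r$genes),
           subsystem = r$subsystem %||% NA_character_)
    }),
    currency = as.list(model$currency)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id, compartment = m$compartment %||% NA_character_,
               kegg = m$kegg %||% NA_character_,
               hmdb = m$hmdb %||% NA_character_)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    list(id = r$id, mets = unlist(r$mets), genes = unlist(r$genes) %||% character(0),
         subsystem = r$subsystem %||% NA_character_)
  })
  metabolic_model(mets, rxns, currency = unlist(obj$currency) %||% character(0))
}

#' Read a metabolic model from an SBML (subset) file
#'
#' Parses the Level-3-style subset this package needs: `species` (id,
#' compartment), `reaction` elements with reactant/product species
#' references, gene associations either from `fbc:geneProductRef`
#' elements or from a `GENE_ASSOCIATION:` line in the reaction notes
#' (boolean structure flattened to the gene set), and a `SUBSYSTEM:`
#' notes line.
#'
#' @param path SBML file path.
#' @return a [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    kegg = NA_character_, hmdb = NA_character_
  )
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(node) {
    refs <- xml2::xml_find_all(
      node, ".//listOfReactants/speciesReference | .//listOfProducts/speciesReference")
    parts <- unique(xml2::xml_attr(refs, "species"))
    gpr <- xml2::xml_find_all(node, ".//geneProductRef")
    genes <- xml2::xml_attr(gpr, "geneProduct")
    notes <- paste(xml2::xml_text(xml2::xml_find_all(node, ".//notes//p")),
                   collapse = "\n")
    if (!length(genes)) {
      ga <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^\n]*", notes))
      if (length(ga)) {
        txt <- sub("GENE_ASSOCIATION:", "", ga)
        genes <- regmatches(txt, gregexpr("[A-Za-z0-9_.:-]+", txt))[[1]]
        genes <- setdiff(genes, c("and", "or", "AND", "OR"))
      }
    }
    ss <- regmatches(notes, regexpr("SUBSYSTEM:[^\n]*", notes))
    subsystem <- if (length(ss)) trimws(sub("SUBSYSTEM:", "", ss)) else NA_character_
    list(id = xml2::xml_attr(node, "id"), mets = parts,
         genes = unique(genes %||% character(0)), subsystem = subsystem)
  })
  metabolic_model(mets, rxns)
}

#' Convert a network to igraph
#'
#' @param x a `bipartite_network` or `pin` object.
#' @return an undirected igraph with node attribute `type`
#'   (metabolite/transcript) or `kind` (GO/MP) and edge attributes `rho`,
#'   `p`.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.bipartite_network <- function(x) {
  e <- x$edges
  g <- igraph::graph_from_data_frame(
    e[, c("metabolite", "transcript", "rho", "p")], directed = FALSE)
  igraph::set_vertex_attr(g, "type", value = ifelse(
    igraph::V(g)$name %in% e$metabolite, "metabolite", "transcript"))
}

#' @export
as_igraph.pin <- function(x) {
  e <- x$edges
  g <- igraph::graph_from_data_frame(e[, c("go", "mp", "rho", "p")],
                                     directed = FALSE)
  igraph::set_vertex_attr(g, "kind", value = ifelse(
    igraph::V(g)$name %in% e$go, "GO", "MP"))
}

#' @export
as_igraph.igraph <- function(x) x

#' Export a network to GraphML and its edge table to TSV
#'
#' @param x a `bipartite_network` or `pin`.
#' @param graphml,tsv output paths (either may be `NULL` to skip).
#' @export
write_network <- function(x, graphml = NULL, tsv = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(x), graphml, format = "graphml")
  }
  if (!is.null(tsv)) {
    utils::write.table(x$edges, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read / write a long-format motif hit table
#'
#' TSV columns `gene`, `motif`, `count`; absent combinations are zero.
#'
#' @param path file path.
#' @export
read_motif_hits <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("gene", "motif", "count") %in% names(df)))
  genes <- unique(df$gene)
  motifs <- unique(df$motif)
  m <- matrix(0L, length(genes), length(motifs),
              dimnames = list(genes, motifs))
  m[cbind(match(df$gene, genes), match(df$motif, motifs))] <- as.integer(df$count)
  structure(m, class = c("motif_hit_table", "matrix", "array"))
}

#' @rdname read_motif_hits
#' @param hits gene x motif count matrix.
#' @export
write_motif_hits <- function(hits, path) {
  idx <- which(unclass(hits) > 0, arr.ind = TRUE)
  df <- data.frame(gene = rownames(hits)[idx[, 1]],
                   motif = colnames(hits)[idx[, 2]],
                   count = unclass(hits)[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT-like category annotations
#'
#' Each line: `category<TAB>kind<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return long data frame with columns `category`, `kind`, `member`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L) stop("GMT line needs category, kind and >= 1 member")
    data.frame(category = f[1], kind = f[2], member = f[-(1:2)])
  })
  do.call(rbind, rows)
}
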