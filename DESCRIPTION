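Package: mtinet
Title: Metabolite-Transcript Correlation Networks with Causal, Pathway
    and Regulatory Analysis
Version: 0.1.0
Authors@R:
    person("Anna", "Keller", email = "anna.keller@example.org",
           role = c("aut", "cre"))
Description: Builds significance-thresholded bipartite correlation
    networks between blood metabolite concentrations and whole-blood
    transcript levels from population-cohort data, and layers causal,
    mechanistic and regulatory analyses on top of them: bidirectional
    Mendelian randomization of network edges using the Wald ratio with
    bootstrap inference, reaction-step distance enrichment against a
    genome-scale metabolic reconstruction, aggregation of the network
    into a pathway interaction network via aggregated z-scores,
    transcription-factor binding-site enrichment over promoter motif
    hit tables, and projection of clinical lipid traits onto both
    networks. A synthetic-cohort module generates data with the
    statistical structure every stage assumes, so the complete pipeline
    runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
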