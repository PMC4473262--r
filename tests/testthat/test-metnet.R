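## tiny hand-built compartmentalized model:
## chain A -(R1:g1)-> B -(R2:g2)-> C, A duplicated in two compartments with
## a transport reaction, currency metabolite "atp" attached to R1 and to a
## second disjoint chain D -(R9:g9)-> E.
hand_model <- function() {
  mets <- data.frame(
    id = c("A_c", "A_m", "B_c", "C_c", "D_c", "E_c", "atp_c"),
    compartment = c("c", "m", "c", "c", "c", "c", "c"),
    kegg = NA_character_, hmdb = NA_character_)
  rxns <- list(
    list(id = "TR", mets = c("A_c", "A_m"), genes = character(0),
         subsystem = "transport"),
    list(id = "R1", mets = c("A_c", "B_c", "atp_c"), genes = "g1",
         subsystem = "alpha"),
    list(id = "R2", mets = c("B_c", "C_c"), genes = "g2", subsystem = "alpha"),
    list(id = "R9", mets = c("D_c", "E_c", "atp_c"), genes = "g9",
         subsystem = "beta"))
  metabolic_model(mets, rxns, currency = "atp")
}

test_that("prepare_model merges compartments, drops self-loops and currency", {
  pm <- prepare_model(hand_model())
  expect_true(pm$prepared)
  ## merged node, no compartment tags left
  expect_true("A" %in% pm$metabolites$id)
  expect_false(any(grepl("_[cm]$", pm$metabolites$id)))
  ## transport self-loop dropped; currency node gone
  ids <- vapply(pm$reactions, `[[`, character(1), "id")
  expect_false("TR" %in% ids)
  expect_false("atp" %in% pm$metabolites$id)
  ## idempotent
  expect_equal(prepare_model(pm), pm)
  ## absent currency id warns only
  expect_warning(prepare_model(hand_model(), currency = c("atp", "ghost")),
                 "ghost")
})

test_that("duplicate reactions collapse and union their gene sets", {
  m <- hand_model()
  m$reactions[[5]] <- list(id = "R1b", mets = c("A_m", "B_c"), genes = "g1b",
                           subsystem = "alpha")
  pm <- prepare_model(m)
  ids <- vapply(pm$reactions, `[[`, character(1), "id")
  expect_equal(sum(ids %in% c("R1", "R1b")), 1L)
  kept <- pm$reactions[[which(ids == "R1")]]
  expect_setequal(kept$genes, c("g1", "g1b"))
})

test_that("distances follow direct-reactant and reaction-step semantics", {
  pm <- prepare_model(hand_model())
  d <- pairwise_distances(pm, c("A", "B", "C", "D"), c("g1", "g2", "g9", "gX"))
  get <- function(met, gene) d$d[d$metabolite == met & d$gene == gene]
  expect_equal(get("A", "g1"), 0)   # direct reactant
  expect_equal(get("A", "g2"), 1)   # one reaction apart
  expect_equal(get("C", "g1"), 1)
  ## currency removal disconnects the two chains
  expect_true(is.infinite(get("A", "g9")))
  expect_true(is.infinite(get("D", "g1")))
  ## unmapped gene -> NM (NA)
  expect_true(is.na(get("A", "gX")))
  ## unprepared model refused
  expect_error(pairwise_distances(hand_model(), "A", "g1"), "prepared")
})

test_that("a two-step chain gives d = 2 and gene minima are respected", {
  ## carnitine-shuttle-like chain: fatty acid -> activation -> transfer ->
  ## translocation; the translocase gene sits two reaction steps from the
  ## fatty acid
  mets2 <- data.frame(id = c("FA", "FAcoa", "FAcarOut", "FAcarIn"),
                      compartment = "c", kegg = NA, hmdb = NA)
  rxns2 <- list(
    list(id = "ACT", mets = c("FA", "FAcoa"), genes = "ACSL", subsystem = "lipid"),
    list(id = "CPT1", mets = c("FAcoa", "FAcarOut"), genes = "CPT1A",
         subsystem = "carnitine"),
    list(id = "TRANS", mets = c("FAcarOut", "FAcarIn"), genes = "SLC25A20",
         subsystem = "transport"))
  pm2 <- prepare_model(metabolic_model(mets2, rxns2), compartment_regex = "$^")
  d <- pairwise_distances(pm2, "FA", c("ACSL", "CPT1A", "SLC25A20"))
  expect_equal(d$d[d$gene == "ACSL"], 0)
  expect_equal(d$d[d$gene == "CPT1A"], 1)
  expect_equal(d$d[d$gene == "SLC25A20"], 2)

  ## gene catalyzing reactions at distances 1 and 4 -> minimum 1
  mets3 <- data.frame(id = sprintf("N%d", 1:6), compartment = "c",
                      kegg = NA, hmdb = NA)
  rxns3 <- lapply(1:5, function(i) {
    list(id = sprintf("R%d", i), mets = c(sprintf("N%d", i), sprintf("N%d", i + 1)),
         genes = if (i %in% c(2, 5)) "gBoth" else sprintf("g%d", i),
         subsystem = "s")
  })
  pm3 <- prepare_model(metabolic_model(mets3, rxns3), compartment_regex = "$^")
  d3 <- pairwise_distances(pm3, "N1", "gBoth")
  expect_equal(d3$d, 1)
})

test_that("toy generator round-trips through prepare + distances", {
  model <- generate_toy_model(tiny_config())
  pm <- prepare_model(model)
  tr <- model$truth$distances
  d <- pairwise_distances(pm, unique(tr$metabolite), unique(tr$gene))
  mg <- merge(d, tr, by = c("metabolite", "gene"),
              suffixes = c("_impl", "_truth"))
  expect_equal(nrow(mg), nrow(tr))
  expect_equal(mg$d_impl, mg$d_truth)
  ## cross-chain pairs disconnect after currency removal
  cross <- d$d[substr(d$metabolite, 2, 2) != substr(d$gene, 2, 2)]
  expect_true(all(is.infinite(cross)))
})

test_that("distances match a brute-force BFS oracle on random toy models", {
  for (s in 1:6) {
    cfg <- synth_config(toy_chains = sample(2:5, 1),
                        toy_chain_length = sample(3:10, 1), seed = s)
    pm <- prepare_model(generate_toy_model(cfg))
    mets <- sample(pm$metabolites$id, min(8, nrow(pm$metabolites)))
    genes <- unique(unlist(lapply(pm$reactions, `[[`, "genes")))
    genes <- sample(genes, min(8, length(genes)))
    d <- pairwise_distances(pm, mets, genes)
    for (i in seq_len(nrow(d))) {
      expect_equal(d$d[i],
                   bfs_distance_oracle(pm, d$metabolite[i], d$gene[i]),
                   info = sprintf("seed %d: %s vs %s", s, d$metabolite[i], d$gene[i]))
    }
  }
})

test_that("Fisher enrichment matches exact enumeration", {
  ## [[4,1],[1,4]] -> one-tailed p = 0.1032 (4 s.f.)
  expect_equal(round(fisher_tail_oracle(4, 1, 1, 4), 4), 0.1032)
  dt <- structure(data.frame(
    metabolite = rep(c("A", "B"), each = 5),
    gene = rep(sprintf("g%d", 1:5), 2),
    d = c(0, 0, 1, 2, 3, 0, 1, 1, 2, 4)),
    class = c("distance_table", "data.frame"))
  sig <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  enr <- distance_enrichment(dt, sig)
  for (i in seq_len(nrow(enr$per_distance))) {
    dd <- enr$per_distance$d[i]
    a <- sum(sig & dt$d == dd); b <- sum(sig & dt$d != dd)
    c_ <- sum(!sig & dt$d == dd); d_ <- sum(!sig & dt$d != dd)
    expect_equal(enr$per_distance$p[i], fisher_tail_oracle(a, b, c_, d_))
  }
  for (i in seq_len(nrow(enr$cumulative))) {
    dd <- enr$cumulative$d[i]
    a <- sum(sig & dt$d <= dd); b <- sum(sig & dt$d > dd)
    c_ <- sum(!sig & dt$d <= dd); d_ <- sum(!sig & dt$d > dd)
    expect_equal(enr$cumulative$p[i], fisher_tail_oracle(a, b, c_, d_))
  }
  ## cumulative band at the maximum finite distance contains everything -> p = 1
  expect_equal(enr$cumulative$p[nrow(enr$cumulative)], 1)
  ## all pairs significant -> every p = 1
  enr_all <- distance_enrichment(dt, rep(TRUE, 10))
  expect_true(all(enr_all$per_distance$p == 1))
  expect_true(all(enr_all$cumulative$p == 1))
})

test_that("planted short-distance significance is detected as enrichment", {
  set.seed(9)
  n_pairs <- 300
  d <- sample(0:6, n_pairs, replace = TRUE)
  sig <- ifelse(d <= 1, runif(n_pairs) < 0.5, runif(n_pairs) < 0.05)
  dt <- structure(data.frame(metabolite = sprintf("m%d", seq_len(n_pairs)),
                             gene = "g", d = as.numeric(d)),
                  class = c("distance_table", "data.frame"))
  enr <- distance_enrichment(dt, sig)
  expect_lt(enr$cumulative$p[enr$cumulative$d == 1], 0.01)
})

test_that("subsystem frequencies are tabulated for significant short pairs", {
  pm <- prepare_model(hand_model())
  d <- pairwise_distances(pm, c("A", "B", "C"), c("g1", "g2"))
  sig <- rep(TRUE, nrow(d))
  enr <- distance_enrichment(d, sig, model = pm)
  expect_named(enr$subsystems, c("0", "1", "2"))
  expect_true("alpha" %in% names(enr$subsystems[["0"]]))
})
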