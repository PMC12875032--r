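test_that("importance R is the Euclidean volcano norm", {
  expect_identical(importance_R(3, 1e-4), 5)
  expect_identical(importance_R(0, 1), 0)
  # printed CRP inputs: FC 46.955, adjusted p 4.91e-28
  expect_equal(importance_R(log2(46.955), 4.91e-28), 27.867, tolerance = 1e-3)
  # sign-flip invariance and monotone scaling
  set.seed(4)
  lfc <- rnorm(50); padj <- runif(50)
  expect_equal(importance_R(lfc, padj), importance_R(-lfc, padj))
  expect_true(all(importance_R(1.7 * lfc, padj) >= importance_R(lfc, padj)))
  expect_error(importance_R(1, 0), "floor")
})

test_that("edge weights carry the correlation sign", {
  expect_identical(edge_weight(0, 10), 0)
  expect_equal(edge_weight(-0.6, 5), -3)
  expect_equal(edge_weight(0.5, 27.867), 13.93, tolerance = 1e-2)
  set.seed(5)
  rho <- runif(30, -1, 1); R <- rexp(30)
  expect_equal(edge_weight(-rho, R), -edge_weight(rho, R))
  expect_error(edge_weight(1.5, 1), "rho")
  expect_error(edge_weight(0.5, -1), "non-negative")
})

# Minimal hand-built stage outputs feeding build_graph.
graph_fixture <- function(assoc_p = c(0.01, 0.04, 0.5),
                          rho = c(0.4, -0.2, 0.9)) {
  sets <- gene_sets("T1", "d", list(c("A", "B", "C")))
  enr <- enrich(sets, hits = c("A", "B", "C"),
                universe = c("A", "B", "C", sprintf("U%02d", 1:17)))
  de <- data.frame(protein_id = c("A", "B", "C"),
                   log2fc = c(2, -1.5, 1),
                   p_adj = c(1e-3, 1e-2, 0.5),
                   stringsAsFactors = FALSE)
  assoc <- data.frame(protein_id = c("A", "B", "C"),
                      variable = "pelod", rho = rho, p = assoc_p,
                      stringsAsFactors = FALSE)
  list(enr = enr, de = de, assoc = assoc)
}

test_that("graph aggregation sums gated protein weights", {
  fx <- graph_fixture()
  g <- build_graph(fx$enr, fx$de, fx$assoc)
  et <- graph_edge_table(g)
  expect_equal(nrow(et), 1)
  # A and B pass the raw-p gate; C (p = 0.5) does not
  wA <- 0.4 * importance_R(2, 1e-3)
  wB <- -0.2 * importance_R(-1.5, 1e-2)
  expect_equal(et$weight, wA + wB, tolerance = 1e-12)
  expect_equal(et$n_proteins, 2)

  gm <- build_graph(fx$enr, fx$de, fx$assoc, aggregate = "mean")
  expect_equal(graph_edge_table(gm)$weight, (wA + wB) / 2, tolerance = 1e-12)
})

test_that("the significance gate uses the raw correlation p-value", {
  # p = 0.049 passes even though any FDR adjustment would not
  fx <- graph_fixture(assoc_p = c(0.049, 0.9, 0.9))
  g <- build_graph(fx$enr, fx$de, fx$assoc)
  expect_equal(graph_edge_table(g)$n_proteins, 1)
  # nothing significant: empty edge set, nodes still typed
  fx0 <- graph_fixture(assoc_p = c(0.9, 0.9, 0.9))
  g0 <- build_graph(fx0$enr, fx0$de, fx0$assoc)
  expect_equal(igraph::ecount(g0), 0)
  expect_setequal(igraph::V(g0)$node_type, c("pathway", "clinical"))
})

test_that("graphs are structurally bipartite", {
  ch <- simulate_cohort(sim_config(seed = 61))
  de <- de_test(ch$abundance, ch$samples, contrast_unpaired("D1", "HC"))
  enr <- enrich(ch$gene_sets, de$protein_id[de$status != "ns"],
                colnames(ch$abundance), de)
  assoc <- rbind(
    correlate_panel(ch$abundance, ch$samples, "PELOD2_D1", "pearson", "D1"),
    correlate_panel(ch$abundance, ch$samples, "mortality", "point_biserial",
                    "D1"))
  g <- build_graph(enr, de, assoc)
  types <- igraph::V(g)$node_type
  names(types) <- igraph::V(g)$name
  et <- graph_edge_table(g)
  if (nrow(et)) {
    expect_true(all(types[et$pathway] == "pathway"))
    expect_true(all(types[et$clinical] == "clinical"))
  }
  expect_true(igraph::bipartite_mapping(g)$res)
})

test_that("missing DE coverage of a term member is an error listing ids", {
  fx <- graph_fixture()
  de_partial <- fx$de[fx$de$protein_id != "B", ]
  expect_error(build_graph(fx$enr, de_partial, fx$assoc), "B")
})

test_that("planted enriched terms connect to severity with positive weight", {
  hits <- vapply(1:20, function(s) {
    ch <- simulate_cohort(sim_config(seed = 400 + s))
    de <- de_test(ch$abundance, ch$samples, contrast_unpaired("D1", "HC"))
    enr <- enrich(ch$gene_sets, de$protein_id[de$status != "ns"],
                  colnames(ch$abundance), de)
    assoc <- correlate_panel(ch$abundance, ch$samples, "PELOD2_D1",
                             "pearson", "D1")
    g <- build_graph(enr, de, assoc)
    et <- graph_edge_table(g)
    et <- et[et$pathway %in% ch$truth$enriched_term_ids, , drop = FALSE]
    # planted outcome proteins are (mostly) up/down DEPs whose sign matches
    # their correlation; aggregate weight should come out positive
    nrow(et) > 0 && sum(et$weight) > 0
  }, TRUE)
  expect_gte(sum(hits), 16)
})
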