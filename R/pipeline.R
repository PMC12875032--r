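#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Orchestrates simulate -> summarize -> differential expression -> feature
#' selection -> outcome correlations -> enrichment -> association graph as
#' one reproducible run. Every stage writes its table to `out_dir`, and a
#' JSON manifest records the configuration echo, seed, package version and
#' per-stage row counts. Re-running with an identical configuration
#' reproduces identical result files; the free-text log (timings) is the
#' only non-deterministic artifact.
#'
#' @param config A [sim_config()]; the cohort is simulated from it. Supply
#'   `cohort` instead to analyse existing data.
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-built `sepsis_cohort`-like list with
#'   `abundance`, `samples`, `gene_sets`; overrides `config`-driven
#'   simulation.
#' @param alpha Significance level used for DEP calling, correlation gating
#'   and enrichment FDR.
#' @param fc_min Fold-change gate for DEP calling.
#' @param boruta_iter Maximum Boruta iterations.
#' @param n_trees_boruta,n_trees_final Forest sizes for the Boruta
#'   iterations and the final re-ranking.
#' @param run_selection Set to `FALSE` to skip the (relatively slow) random
#'   forest stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, cohort = NULL,
                         alpha = 0.05, fc_min = 2, boruta_iter = 50,
                         n_trees_boruta = 500, n_trees_final = 5000,
                         run_selection = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  log_line <- function(stage, note) {
    cat(sprintf("[%s] %s\n", stage, note), file = log_path, append = TRUE)
  }
  manifest <- list(package = "sepsisproteome",
                   version = as.character(utils::packageVersion("sepsisproteome")),
                   seed = config$seed,
                   config = unclass(config),
                   stages = list())
  record <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(files = files, rows = rows)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log_line(stage, sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
    out
  }

  # -- simulate ---------------------------------------------------------
  cohort <- timed("simulate", {
    ch <- if (is.null(cohort)) simulate_cohort(config) else cohort
    write_abundance(ch$abundance, file.path(out_dir, "abundance.tsv"))
    write_metadata(ch$samples, file.path(out_dir, "metadata.tsv"))
    write_gmt(ch$gene_sets, file.path(out_dir, "gene_sets.gmt"))
    if (!is.null(ch$truth)) {
      jsonlite::write_json(
        list(dep = ch$truth$dep, outcome_ids = ch$truth$outcome_ids,
             mortality_ids = ch$truth$mortality_ids,
             enriched_term_ids = ch$truth$enriched_term_ids),
        file.path(out_dir, "truth.json"), auto_unbox = FALSE, digits = NA)
    }
    ch
  })
  record("simulate",
         c("abundance.tsv", "metadata.tsv", "gene_sets.gmt", "truth.json"),
         nrow(cohort$abundance))

  # -- summarize --------------------------------------------------------
  timed("summarize", {
    cont <- intersect(c("age_years", "PELOD2_D1", "PELOD2_D3", "picu_days",
                        "hospital_days"), names(cohort$samples))
    cat_ <- intersect(c("sex", "confirmed_sepsis", "comorbidity_any",
                        "comorbidity_neuro", "source_respiratory",
                        "mech_vent", "circ_support", "mortality"),
                      names(cohort$samples))
    summ <- summarize_cohort(cohort$samples, continuous = cont,
                             categorical = cat_)
    utils::write.table(summ, file.path(out_dir, "cohort_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sep_subj <- cohort$samples[cohort$samples$group == "SEPSIS" &
                                 !duplicated(cohort$samples$subject_id), ,
                               drop = FALSE]
    assoc_vars <- intersect(c(cont, cat_), names(sep_subj))
    tiers <- suppressWarnings(
      association_matrix(sep_subj[, assoc_vars, drop = FALSE], alpha = alpha))
    utils::write.table(tiers, file.path(out_dir, "association_tiers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!anyNA(cohort$abundance)) {
      pcs <- pca_embedding(cohort$abundance, k = 2)
      utils::write.table(
        data.frame(sample_id = rownames(pcs), PC1 = pcs[, 1], PC2 = pcs[, 2]),
        file.path(out_dir, "pca.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    record("summarize",
           c("cohort_summary.tsv", "association_tiers.tsv", "pca.tsv"),
           nrow(summ))
  })

  # -- differential expression -----------------------------------------
  de_d1 <- timed("de", {
    de_d1 <- de_test(cohort$abundance, cohort$samples,
                     contrast_unpaired("D1", "HC"),
                     fc_min = fc_min, alpha = alpha)
    de_d3 <- de_test(cohort$abundance, cohort$samples,
                     contrast_paired("D3", "D1"),
                     fc_min = fc_min, alpha = alpha)
    for (nm in c("de_d1_hc", "de_d3_d1")) {
      tab <- if (nm == "de_d1_hc") de_d1 else de_d3
      tab <- as.data.frame(tab)[order(tab$p_adj, tab$p, tab$protein_id), ]
      utils::write.table(tab, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    record("de", c("de_d1_hc.tsv", "de_d3_d1.tsv"),
           c(nrow(de_d1), nrow(de_d3)))
    de_d1
  })

  # -- feature selection ------------------------------------------------
  if (run_selection) {
    timed("select", {
      strat <- ifelse(cohort$samples$group == "HC", "HC",
                      cohort$samples$timepoint)
      sel <- cohort$samples$sample_id[strat %in% c("HC", "D1")]
      X <- cohort$abundance[sel, , drop = FALSE]
      y <- strat[match(sel, cohort$samples$sample_id)]
      dec <- select_features(X, y, n_trees = n_trees_boruta,
                             n_trees_final = n_trees_final,
                             max_iter = boruta_iter, alpha = alpha,
                             seed = derive_seed(config$seed, 4L))
      utils::write.table(dec, file.path(out_dir, "boruta_d1_hc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record("select", "boruta_d1_hc.tsv", nrow(dec))
    })
  }

  # -- outcome associations --------------------------------------------
  assoc <- timed("associate", {
    panels <- list(
      list(var = "PELOD2_D1", method = "pearson", tp = "D1"),
      list(var = "PELOD2_D3", method = "pearson", tp = "D3"),
      list(var = "mortality", method = "point_biserial", tp = "D1"),
      list(var = "mortality", method = "point_biserial", tp = "D3"))
    assoc <- do.call(rbind, lapply(panels, function(pn) {
      suppressWarnings(correlate_panel(cohort$abundance, cohort$samples,
                                       pn$var, pn$method, pn$tp))
    }))
    utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("associate", "associations.tsv", nrow(assoc))
    assoc
  })

  # -- enrichment -------------------------------------------------------
  enr <- timed("enrich", {
    hits <- de_d1$protein_id[de_d1$status != "ns"]
    enr <- enrich(cohort$gene_sets, hits, colnames(cohort$abundance),
                  de_table = de_d1)
    utils::write.table(as.data.frame(enr),
                       file.path(out_dir, "enrichment_d1_hc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("enrich", "enrichment_d1_hc.tsv", nrow(enr))
    enr
  })

  # -- association graph ------------------------------------------------
  timed("graph", {
    # distinguish the two PELOD-2 panels from the two mortality panels
    assoc$variable <- ifelse(assoc$variable == "mortality",
                             paste0("mortality_", assoc$timepoint),
                             assoc$variable)
    g <- build_graph(enr, de_d1, assoc, alpha = alpha,
                     term_fdr_max = alpha)
    write_graphml(g, file.path(out_dir, "pathway_clinical.graphml"))
    utils::write.table(graph_edge_table(g),
                       file.path(out_dir, "graph_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("graph", c("pathway_clinical.graphml", "graph_edges.tsv"),
           igraph::ecount(g))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
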