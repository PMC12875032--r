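#' Volcano-norm relative importance of a protein
#'
#' `R = sqrt(log2fc^2 + (-log10(p_adj))^2)`: the Euclidean norm of the
#' protein's volcano-plot coordinates, combining effect magnitude and
#' significance into one non-negative score.
#'
#' @param log2fc Log2 fold change(s).
#' @param p_adj Adjusted p-value(s) in `(0, 1]`; callers must floor tiny
#'   values (see [build_graph()]'s `p_adj_floor`) rather than pass 0.
#' @return Non-negative importance score(s).
#' @export
importance_R <- function(log2fc, p_adj) {
  stopifnot(all(is.finite(log2fc)))
  if (any(p_adj <= 0) || any(p_adj > 1)) {
    stop("p_adj must lie in (0, 1]; floor zero p-values before calling",
         call. = FALSE)
  }
  sqrt(log2fc^2 + log10(p_adj)^2)
}

#' Signed pathway-edge weight of a protein
#'
#' `w = rho * R`: the protein's clinical correlation scaled by its
#' differential-expression importance. The sign carries the correlation
#' direction.
#'
#' @param rho Correlation coefficient(s) in `[-1, 1]`.
#' @param R Non-negative importance score(s) from [importance_R()].
#' @return Signed weight(s).
#' @export
edge_weight <- function(rho, R) {
  if (any(abs(rho) > 1)) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (any(R < 0)) stop("R must be non-negative", call. = FALSE)
  rho * R
}

#' Pathway-clinical bipartite association graph
#'
#' For each significantly enriched term and each clinical variable, the
#' term's implicated proteins (its hit members) are screened against the
#' association table: a protein contributes when its correlation with the
#' variable is significant at raw `p < alpha`. Each contributing protein
#' adds `w = rho * R` with `R` from its differential-expression log2 fold
#' change and adjusted p-value; the protein-level weights are aggregated
#' (sum by default, mean optionally) into a single signed edge per
#' (term, variable) pair. Pairs with no contributing protein get no edge.
#'
#' @param enrichment An [enrich()] result (with its `hit_members`
#'   attribute).
#' @param de_table A `de_result` covering every implicated protein.
#' @param associations One or more stacked [correlate_panel()] results
#'   (columns `protein_id`, `variable`, `rho`, `p`).
#' @param alpha Raw-p significance gate for the correlation (default 0.05,
#'   applied to the unadjusted p-value).
#' @param aggregate `"sum"` (default, preserves evidence mass) or `"mean"`.
#' @param term_fdr_max Enrichment FDR threshold selecting the pathway nodes.
#' @param p_adj_floor Lower floor applied to adjusted p-values before
#'   `-log10` (default 1e-300, guarding against infinite importance).
#' @return An igraph bipartite graph; vertices carry `node_type`
#'   (`"pathway"`/`"clinical"`), edges carry `weight` (aggregated w) and
#'   `n_proteins`. The protein-level contributions are kept in the
#'   `edge_detail` graph attribute (a data frame).
#' @export
build_graph <- function(enrichment, de_table, associations, alpha = 0.05,
                        aggregate = c("sum", "mean"), term_fdr_max = 0.05,
                        p_adj_floor = 1e-300) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(enrichment, "enrichment_result"))
  members <- attr(enrichment, "hit_members")
  sig_terms <- enrichment$term_id[enrichment$fdr <= term_fdr_max]
  de_idx <- stats::setNames(seq_len(nrow(de_table)), de_table$protein_id)
  vars <- unique(associations$variable)

  detail <- list()
  for (term in sig_terms) {
    prots <- members[[term]]
    if (length(prots) == 0) next
    absent <- setdiff(prots, names(de_idx))
    if (length(absent)) {
      stop("proteins in term '", term, "' missing from DE table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    de_sub <- de_table[de_idx[prots], , drop = FALSE]
    r_score <- importance_R(de_sub$log2fc, pmax(de_sub$p_adj, p_adj_floor))
    names(r_score) <- prots
    for (v in vars) {
      a <- associations[associations$variable == v &
                          associations$protein_id %in% prots &
                          associations$p < alpha, , drop = FALSE]
      if (nrow(a) == 0) next
      w <- edge_weight(a$rho, r_score[a$protein_id])
      detail[[length(detail) + 1L]] <- data.frame(
        term_id = term, variable = v, protein_id = a$protein_id,
        rho = a$rho, R = unname(r_score[a$protein_id]), w = unname(w),
        stringsAsFactors = FALSE)
    }
  }

  if (length(detail)) {
    detail <- do.call(rbind, detail)
    agg_fun <- if (aggregate == "sum") sum else mean
    key <- paste(detail$term_id, detail$variable, sep = "\r")
    w_agg <- tapply(detail$w, key, agg_fun)
    n_prot <- tapply(detail$w, key, length)
    parts <- strsplit(names(w_agg), "\r", fixed = TRUE)
    edges <- data.frame(
      term_id = vapply(parts, `[[`, "", 1L),
      variable = vapply(parts, `[[`, "", 2L),
      weight = unname(as.numeric(w_agg)),
      n_proteins = unname(as.integer(n_prot)),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$term_id, edges$variable), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    detail <- data.frame(term_id = character(0), variable = character(0),
                         protein_id = character(0), rho = numeric(0),
                         R = numeric(0), w = numeric(0),
                         stringsAsFactors = FALSE)
    edges <- data.frame(term_id = character(0), variable = character(0),
                        weight = numeric(0), n_proteins = integer(0),
                        stringsAsFactors = FALSE)
  }

  vertices <- data.frame(
    name = c(sig_terms, vars),
    node_type = c(rep("pathway", length(sig_terms)),
                  rep("clinical", length(vars))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("term_id", "variable", "weight", "n_proteins"), drop = FALSE],
    directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "aggregate", aggregate)
  igraph::graph_attr(g, "edge_detail") <- detail
  g
}

#' Flat edge table of a pathway-clinical graph
#'
#' @param graph An igraph object from [build_graph()].
#' @return Data frame with `pathway`, `clinical`, `weight`, `n_proteins`.
#' @export
graph_edge_table <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::ecount(graph) == 0) {
    return(data.frame(pathway = character(0), clinical = character(0),
                      weight = numeric(0), n_proteins = integer(0),
                      stringsAsFactors = FALSE))
  }
  ed <- igraph::as_data_frame(graph, what = "edges")
  rownames(ed) <- NULL
  types <- stats::setNames(igraph::V(graph)$node_type,
                           igraph::V(graph)$name)
  swap <- unname(types[ed$from] == "clinical")
  data.frame(pathway = ifelse(swap, ed$to, ed$from),
             clinical = ifelse(swap, ed$from, ed$to),
             weight = ed$weight,
             n_proteins = as.integer(ed$n_proteins),
             stringsAsFactors = FALSE)
}
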