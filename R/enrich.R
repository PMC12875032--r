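#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated proteins when `n` hits are drawn without
#' replacement from a universe of `N` proteins of which `K` carry the
#' annotation.
#'
#' @param k Observed overlap.
#' @param K Term size within the universe.
#' @param n Hit-list size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (!all(vapply(list(k, K, n, N), is_count, TRUE))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (k > min(K, n) || K > N || n > N) {
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Odds ratio of the 2x2 overlap table
#'
#' Cross-product ratio `(k * (N - K - n + k)) / ((K - k) * (n - k))`; `0`
#' when the overlap is empty, `+Inf` when a zero cell makes the table
#' degenerate with positive overlap.
#'
#' @inheritParams hypergeom_upper
#' @return Non-negative odds ratio (possibly `Inf`).
#' @export
overlap_odds_ratio <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N) {
    stop("inconsistent counts", call. = FALSE)
  }
  if (k == 0) return(0)
  if (K - k == 0 || n - k == 0) return(Inf)
  (k * (N - K - n + k)) / ((K - k) * (n - k))
}

#' Direction z-score of a term's differentially expressed members
#'
#' `z = (U - D) / sqrt(U + D)` where `U` and `D` count members with positive
#' and negative log2 fold change. Members with exactly zero fold change are
#' counted in neither, with a warning. Direction is `up` when all counted
#' members are positive, `down` when all are negative, otherwise `mixed`.
#'
#' @param log2fcs Log2 fold changes of the term's hit members (>= 1 value).
#' @return List with `z` and `direction`.
#' @export
direction_z <- function(log2fcs) {
  if (length(log2fcs) == 0) stop("need at least one member", call. = FALSE)
  if (any(log2fcs == 0)) {
    warning("members with zero log2 fold change counted in neither direction",
            call. = FALSE)
  }
  u <- sum(log2fcs > 0)
  d <- sum(log2fcs < 0)
  z <- if (u + d == 0) 0 else (u - d) / sqrt(u + d)
  direction <- if (u > 0 && d == 0) "up"
               else if (d > 0 && u == 0) "down"
               else "mixed"
  list(z = z, direction = direction)
}

#' Over-representation analysis of a hit list against gene sets
#'
#' Each term is intersected with the universe before counting; terms with
#' fewer than `min_size` members in the universe (or covering all but one
#' protein) are dropped as uninformative. One-sided hypergeometric p-values
#' are Benjamini-Hochberg adjusted over the tested terms.
#'
#' @param sets A [gene_sets] collection.
#' @param hits Character vector of hit protein ids (subset of `universe`),
#'   typically the DEPs of one contrast.
#' @param universe Character vector of measured protein ids (the panel).
#' @param de_table Optional `de_result` covering the hit proteins, used for
#'   the direction z-score.
#' @param min_size Minimum term size within the universe (default 2).
#' @return Data frame of class `enrichment_result`, sorted by p: `term_id`,
#'   `k`, `K`, `n`, `N`, `odds_ratio`, `z_score`, `direction`, `p`, `fdr`.
#'   The hit members of each term are kept in the `hit_members` attribute
#'   for the downstream association graph.
#' @export
enrich <- function(sets, hits, universe, de_table = NULL, min_size = 2) {
  stopifnot(inherits(sets, "gene_sets"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  hits <- unique(as.character(hits))
  if (!all(hits %in% universe)) {
    stop("hits outside the universe: ",
         paste(setdiff(hits, universe), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(hits)
  lfc <- NULL
  if (!is.null(de_table)) {
    lfc <- stats::setNames(de_table$log2fc, de_table$protein_id)
  }
  rows <- list()
  members <- list()
  for (id in names(sets)) {
    term <- intersect(sets[[id]], universe)
    K <- length(term)
    if (K < min_size || K > N - min_size) next
    hit_mem <- intersect(term, hits)
    k <- length(hit_mem)
    dz <- list(z = NA_real_, direction = NA_character_)
    if (k > 0 && !is.null(lfc)) {
      dz <- suppressWarnings(direction_z(unname(lfc[hit_mem])))
    }
    rows[[id]] <- data.frame(
      term_id = id, k = k, K = K, n = n, N = N,
      odds_ratio = overlap_odds_ratio(k, K, n, N),
      z_score = dz$z, direction = dz$direction,
      p = hypergeom_upper(k, K, n, N),
      stringsAsFactors = FALSE)
    members[[id]] <- hit_mem
  }
  if (length(rows) == 0) {
    stop("no testable terms after universe intersection", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  ord <- order(out$p, out$term_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hit_members") <- members[out$term_id]
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat(sprintf("Over-representation analysis: %d terms tested, %d with FDR <= 0.05 (hit list n = %d of N = %d)\n",
              nrow(x), sum(x$fdr <= 0.05), x$n[1], x$N[1]))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
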