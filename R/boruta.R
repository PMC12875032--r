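#' Depth-limited random-forest classifier with impurity importances
#'
#' Trains a classification forest (default 5,000 trees of maximum depth 5)
#' and returns per-feature impurity importances normalised to sum to one.
#' Fixed seed and single-threaded training make the importances
#' reproducible.
#'
#' @param X Numeric samples x features matrix (no missing values).
#' @param y Binary class labels (two classes, each with at least 2 samples).
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed.
#' @return List of class `rf_fit` with `model` (the ranger object) and
#'   `importance` (named, non-negative, sums to 1).
#' @export
train_forest <- function(X, y, n_trees = 5000, max_depth = 5, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2) stop("y must contain two classes", call. = FALSE)
  if (any(table(y) < 2)) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%03d", seq_len(ncol(X)))
  fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                        max.depth = max_depth, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- pmax(fit$variable.importance, 0)
  total <- sum(imp)
  imp <- if (total > 0) imp / total else {
    warning("all importances zero; returning uniform importances",
            call. = FALSE)
    rep(1 / length(imp), length(imp))
  }
  names(imp) <- colnames(X)
  structure(list(model = fit, importance = imp), class = "rf_fit")
}

#' Boruta all-relevant feature selection
#'
#' Each iteration appends one shuffled "shadow" copy of every real feature,
#' trains a depth-limited forest on the doubled matrix, and scores a hit
#' for every undecided feature whose importance strictly exceeds the
#' maximum shadow importance. After each iteration a two-sided binomial
#' test (success probability 0.5, Bonferroni-corrected over the undecided
#' features) confirms features with significantly many hits and rejects
#' those with significantly few. Features undecided after `max_iter`
#' iterations are tentative.
#'
#' @inheritParams train_forest
#' @param n_trees Trees per iteration forest (500 by default: the heavy
#'   5,000-tree forest is reserved for the final re-ranking).
#' @param max_iter Maximum number of shadow iterations (at least 5).
#' @param alpha Significance level of the binomial decision rule.
#' @return Data frame of class `boruta_result`: `feature_id`, `decision`
#'   (`confirmed`/`rejected`/`tentative`), `hits`, `n_iter` (iterations the
#'   feature stayed in play).
#' @export
boruta_select <- function(X, y, n_trees = 500, max_depth = 5,
                          max_iter = 100, alpha = 0.05, seed = 1L) {
  if (max_iter < 5) {
    stop("max_iter must be at least 5 for the binomial rule to decide",
         call. = FALSE)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%03d", seq_len(ncol(X)))
  features <- colnames(X)
  decision <- stats::setNames(rep("tentative", length(features)), features)
  hits <- stats::setNames(integer(length(features)), features)
  iters <- stats::setNames(integer(length(features)), features)
  active <- features

  for (i in seq_len(max_iter)) {
    if (length(active) == 0) break
    # the full doubled design every iteration: every real feature keeps its
    # shadow so the max-shadow threshold always reflects the whole pool
    # (removing decided features would shrink the competition and let
    # lucky survivors confirm under the global null)
    shadows <- with_seed(derive_seed(seed, 1000L + i), {
      apply(X, 2, sample)
    })
    colnames(shadows) <- paste0("shadow_", features)
    fit <- train_forest(cbind(X, shadows), y, n_trees = n_trees,
                        max_depth = max_depth,
                        seed = derive_seed(seed, 2000L + i))
    imp <- fit$importance
    shadow_max <- max(imp[colnames(shadows)])
    hit <- imp[active] > shadow_max
    hits[active] <- hits[active] + as.integer(hit)
    iters[active] <- i

    m <- length(active)
    p_two <- vapply(active, function(f) {
      h <- hits[[f]]
      min(1, 2 * min(stats::pbinom(h, i, 0.5),
                     stats::pbinom(h - 1, i, 0.5, lower.tail = FALSE)))
    }, 0)
    sig <- p_two <= alpha / m
    newly_conf <- active[sig & hits[active] / i > 0.5]
    newly_rej <- active[sig & hits[active] / i < 0.5]
    decision[newly_conf] <- "confirmed"
    decision[newly_rej] <- "rejected"
    active <- setdiff(active, c(newly_conf, newly_rej))
  }

  out <- data.frame(feature_id = features,
                    decision = unname(decision[features]),
                    hits = unname(hits[features]),
                    n_iter = unname(iters[features]),
                    stringsAsFactors = FALSE)
  class(out) <- c("boruta_result", class(out))
  out
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decision,
                      levels = c("confirmed", "tentative", "rejected")))
  cat(sprintf("Boruta selection over %d features: %d confirmed, %d tentative, %d rejected\n",
              nrow(x), tab["confirmed"], tab["tentative"], tab["rejected"]))
  conf <- x[x$decision == "confirmed", , drop = FALSE]
  if (nrow(conf)) {
    print.data.frame(conf[order(-conf$hits), ], row.names = FALSE)
  }
  invisible(x)
}

#' Re-rank confirmed features with a full-size forest
#'
#' Trains the final classifier (default 5,000 trees, depth 5) on the
#' confirmed features only and returns their importances in descending
#' order, ties broken by feature id.
#'
#' @inheritParams train_forest
#' @param features Character vector of confirmed feature ids (columns of
#'   `X`).
#' @return Data frame `feature_id`, `importance`, sorted by decreasing
#'   importance. Empty (with a warning) when no features are confirmed.
#' @export
rerank_selected <- function(X, y, features, n_trees = 5000, max_depth = 5,
                            seed = 1L) {
  if (length(features) == 0) {
    warning("no confirmed features to re-rank", call. = FALSE)
    return(data.frame(feature_id = character(0), importance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  X <- as.matrix(X)[, features, drop = FALSE]
  if (ncol(X) == 1) {
    return(data.frame(feature_id = features, importance = 1,
                      stringsAsFactors = FALSE))
  }
  fit <- train_forest(X, y, n_trees = n_trees, max_depth = max_depth,
                      seed = seed)
  imp <- fit$importance
  ord <- order(-imp, names(imp))
  data.frame(feature_id = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Boruta selection followed by final re-ranking
#'
#' Convenience wrapper: runs [boruta_select()], then [rerank_selected()] on
#' the confirmed features with the full-size forest, and merges the final
#' importances into the decision table.
#'
#' @inheritParams boruta_select
#' @param n_trees_final Trees of the re-ranking forest.
#' @return A `boruta_result` data frame with a `final_importance` column
#'   (`NA` for features that were not confirmed).
#' @export
select_features <- function(X, y, n_trees = 500, n_trees_final = 5000,
                            max_depth = 5, max_iter = 100, alpha = 0.05,
                            seed = 1L) {
  dec <- boruta_select(X, y, n_trees = n_trees, max_depth = max_depth,
                       max_iter = max_iter, alpha = alpha, seed = seed)
  conf <- dec$feature_id[dec$decision == "confirmed"]
  rank <- suppressWarnings(
    rerank_selected(X, y, conf, n_trees = n_trees_final,
                    max_depth = max_depth, seed = derive_seed(seed, 99L)))
  dec$final_importance <- rank$importance[match(dec$feature_id,
                                                rank$feature_id)]
  dec
}
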