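#' Median and interquartile range of a continuous variable
#'
#' Quartiles use linear interpolation between order statistics (the type-7
#' convention, R's default).
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
summarize_continuous <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stop("no finite values to summarize", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Integer percentage with half-up rounding
#'
#' @param count Numerator (0 <= count <= total).
#' @param total Positive denominator.
#' @return `round(100 * count / total)` with halves rounded up.
#' @export
percent_of <- function(count, total) {
  if (!is_count(total) || total == 0) {
    stop("`total` must be a positive count", call. = FALSE)
  }
  if (!is_count(count) || count > total) {
    stop("`count` must be an integer in [0, total]", call. = FALSE)
  }
  as.integer(round_half_up(100 * count / total))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return Named numeric vector `c(U, p)`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1) {
    warning("degenerate data: all values identical across both groups",
            call. = FALSE)
    return(c(U = length(a) * length(b) / 2, p = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  c(U = unname(res$statistic), p = res$p.value)
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; warns when any expected count is below 5.
#'
#' @param table Matrix of non-negative integer counts (at least 2 x 2 of
#'   non-zero margins).
#' @return Named numeric vector `c(statistic, df, p)`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("expected count below 5; chi-square approximation may be poor",
            call. = FALSE)
  }
  c(statistic = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value)
}

# Classify a metadata column for pairwise testing: numeric with more than two
# distinct values is continuous, anything else categorical.
.var_kind <- function(x) {
  x <- x[!is.na(x)]
  if (is.numeric(x) && length(unique(x)) > 2) "continuous" else "categorical"
}

#' Tiered pairwise association matrix across clinical variables
#'
#' Every unordered pair of variables is tested with the test matching its
#' type pair: chi-square (categorical-categorical), Mann-Whitney or
#' Kruskal-Wallis (categorical-continuous, by number of levels), Pearson
#' correlation (continuous-continuous). Tiers are assigned from the raw
#' p-value and the Benjamini-Hochberg adjusted p-value over the whole family
#' of pairs: `"fdr"` when the adjusted p is at most `alpha`, `"raw"` when
#' only the raw p is below `alpha`, else `"ns"`.
#'
#' @param data Data frame of clinical variables (one row per subject).
#' @param alpha Significance level for both tiers.
#' @return Data frame with one row per variable pair: `var1`, `var2`,
#'   `test`, `p`, `p_adj`, `tier`.
#' @export
association_matrix <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  vars <- names(data)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  test_pair <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) return(list(test = "none", p = NA_real_))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      warning("constant variable in pair; marked non-significant",
              call. = FALSE)
      return(list(test = "constant", p = NA_real_))
    }
    kx <- .var_kind(x); ky <- .var_kind(y)
    if (kx == "categorical" && ky == "categorical") {
      res <- suppressWarnings(chi_square(table(x, y)))
      list(test = "chi_square", p = unname(res["p"]))
    } else if (kx == "continuous" && ky == "continuous") {
      res <- stats::cor.test(x, y, method = "pearson")
      list(test = "pearson", p = res$p.value)
    } else {
      if (kx == "categorical") { g <- x; v <- y } else { g <- y; v <- x }
      if (length(unique(g)) == 2) {
        gs <- split(v, g)
        res <- suppressWarnings(mann_whitney(gs[[1]], gs[[2]]))
        list(test = "mann_whitney", p = unname(res["p"]))
      } else {
        res <- stats::kruskal.test(v, factor(g))
        list(test = "kruskal_wallis", p = res$p.value)
      }
    }
  }
  rows <- lapply(pairs, function(pr) {
    r <- test_pair(data[[pr[1]]], data[[pr[2]]])
    data.frame(var1 = pr[1], var2 = pr[2], test = r$test, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- benjamini_hochberg(out$p[ok])
  out$tier <- ifelse(!ok, "ns",
                     ifelse(out$p_adj <= alpha, "fdr",
                            ifelse(out$p < alpha, "raw", "ns")))
  out
}

#' Principal-component embedding of an abundance matrix
#'
#' Column-centered SVD scores; each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the embedding reproducible
#' across platforms.
#'
#' @param matrix Numeric samples x proteins matrix (no missing values).
#' @param k Number of components.
#' @return Samples x `k` score matrix with an `sdev` attribute.
#' @export
pca_embedding <- function(matrix, k = 2) {
  stopifnot(is.matrix(matrix))
  if (k > min(dim(matrix))) {
    stop("k exceeds matrix dimensions", call. = FALSE)
  }
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("need at least 2 samples and 2 proteins", call. = FALSE)
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  scores
}

#' Cohort summary table (demographics and clinical variables)
#'
#' Continuous variables are summarised as median (IQR) and compared between
#' groups with the Mann-Whitney U test where both groups carry the variable;
#' categorical variables as count (percent) with a chi-square comparison.
#' Variables observed in a single group (e.g. severity scores absent in
#' controls) are summarised without a test.
#'
#' @param records Sample metadata (one row per sample); collapsed to one row
#'   per subject before summarising.
#' @param continuous,categorical Character vectors of variable names.
#' @param group Name of the grouping column (default `"group"`).
#' @return Data frame of class `cohort_summary`: variable, kind, per-group
#'   summary strings, test name and p-value.
#' @export
summarize_cohort <- function(records,
                             continuous = NULL, categorical = NULL,
                             group = "group") {
  stopifnot(group %in% names(records))
  subj <- records[!duplicated(records$subject_id), , drop = FALSE]
  g <- subj[[group]]
  fmt_cont <- function(x) {
    s <- summarize_continuous(x)
    sprintf("%.1f (%.1f-%.1f)", s["median"], s["q1"], s["q3"])
  }
  rows <- list()
  for (v in continuous) {
    if (!v %in% names(subj)) stop("unknown variable: ", v, call. = FALSE)
    by_g <- split(subj[[v]], g)
    by_g <- lapply(by_g, function(x) x[!is.na(x)])
    present <- names(by_g)[lengths(by_g) > 0]
    p <- NA_real_; test <- NA_character_
    if (length(present) == 2) {
      res <- suppressWarnings(mann_whitney(by_g[[present[1]]],
                                           by_g[[present[2]]]))
      p <- unname(res["p"]); test <- "mann_whitney"
    }
    summ <- vapply(by_g, function(x)
      if (length(x)) fmt_cont(x) else NA_character_, "")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, kind = "continuous",
      t(summ), test = test, p = p,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (v in categorical) {
    if (!v %in% names(subj)) stop("unknown variable: ", v, call. = FALSE)
    x <- subj[[v]]
    by_g <- split(x, g)
    summ <- vapply(by_g, function(xx) {
      xx <- xx[!is.na(xx)]
      if (!length(xx)) return(NA_character_)
      n1 <- sum(xx == 1 | xx == TRUE)
      sprintf("%d (%d%%)", n1, percent_of(n1, length(xx)))
    }, "")
    p <- NA_real_; test <- NA_character_
    tab <- table(x, g)
    if (all(dim(tab) >= 2) && !any(rowSums(tab) == 0) &&
        !any(colSums(tab) == 0)) {
      res <- suppressWarnings(chi_square(tab))
      p <- unname(res["p"]); test <- "chi_square"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, kind = "categorical",
      t(summ), test = test, p = p,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", class(out))
  out
}
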