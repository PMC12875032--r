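#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), both non-constant.
#' @return Named numeric vector `c(rho, p, n)`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt(length(x) - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tt), df = length(x) - 2)
  }
  c(rho = r, p = p, n = length(x))
}

#' Point-biserial correlation
#'
#' Numerically identical to the Pearson correlation between the continuous
#' variable and the 0/1-coded group labels.
#'
#' @param x Numeric vector.
#' @param g Binary labels (0/1 or logical; both classes must be present).
#' @return Named numeric vector `c(rho, p, n)`.
#' @export
point_biserial <- function(x, g) {
  g <- as.numeric(g)
  if (!all(g[!is.na(g)] %in% c(0, 1))) {
    stop("labels must be coded 0/1", call. = FALSE)
  }
  ok <- stats::complete.cases(x, g)
  if (length(unique(g[ok])) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  pearson_cor(x, g)
}

#' Protein-wise correlation panel against a clinical variable
#'
#' Correlates every protein with a clinical variable at one timepoint:
#' Pearson for continuous variables (e.g. PELOD-2), point-biserial for
#' dichotomous outcomes (e.g. mortality). Missing values are removed
#' pairwise per protein; constant proteins are skipped with a warning.
#' Benjamini-Hochberg adjustment is applied over the protein family within
#' this panel (one variable, one timepoint) only.
#'
#' @param matrix Samples x proteins abundance matrix.
#' @param records Sample metadata including the clinical variable.
#' @param variable Name of the metadata column to correlate against.
#' @param method `"pearson"` or `"point_biserial"`.
#' @param timepoint Timepoint filter (`"D1"` or `"D3"`); sepsis samples at
#'   that timepoint are used.
#' @return Data frame of class `assoc_result`: `protein_id`, `variable`,
#'   `timepoint`, `method`, `rho`, `n`, `p`, `p_adj`.
#' @export
correlate_panel <- function(matrix, records, variable,
                            method = c("pearson", "point_biserial"),
                            timepoint = "D1") {
  method <- match.arg(method)
  if (!variable %in% names(records)) {
    stop("variable not found in metadata: ", variable, call. = FALSE)
  }
  sel <- records$group == "SEPSIS" & !is.na(records$timepoint) &
    records$timepoint == timepoint
  rec <- records[sel, , drop = FALSE]
  rec <- rec[rec$sample_id %in% rownames(matrix), , drop = FALSE]
  vals <- rec[[variable]]
  usable <- !is.na(vals)
  if (sum(usable) < 3) {
    stop("fewer than 3 usable samples after filtering", call. = FALSE)
  }
  x <- matrix[rec$sample_id[usable], , drop = FALSE]
  vals <- vals[usable]
  skipped <- character(0)
  rows <- lapply(colnames(x), function(pid) {
    xi <- x[, pid]
    ok <- stats::complete.cases(xi, vals)
    if (sum(ok) < 3 || stats::sd(xi[ok]) == 0) {
      skipped <<- c(skipped, pid)
      return(NULL)
    }
    r <- if (method == "pearson") pearson_cor(xi, vals)
         else point_biserial(xi, vals)
    data.frame(protein_id = pid, variable = variable,
               timepoint = timepoint, method = method,
               rho = unname(r["rho"]), n = unname(r["n"]),
               p = unname(r["p"]), stringsAsFactors = FALSE)
  })
  if (length(skipped)) {
    warning("skipped constant or under-observed proteins: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no testable proteins in panel", call. = FALSE)
  }
  out$p_adj <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", class(out))
  out
}

#' @export
print.assoc_result <- function(x, n = 10, ...) {
  cat(sprintf("Protein-%s correlations (%s, %s): %d proteins, %d with raw p < 0.05, %d with FDR <= 0.05\n",
              x$variable[1], x$method[1], x$timepoint[1], nrow(x),
              sum(x$p < 0.05), sum(x$p_adj <= 0.05)))
  ord <- order(x$p)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n), digits = 4)
  invisible(x)
}
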