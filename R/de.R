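#' Contrast specifications for differential expression
#'
#' `contrast_unpaired(a, b)` compares two independent strata (effect is
#' `mean(a) - mean(b)`); `contrast_paired(a, b)` compares two timepoints
#' within subjects via per-subject differences `a - b`. Strata are named by
#' the sample's timepoint for sepsis samples and `"HC"` for controls.
#'
#' @param a,b Stratum labels (`"HC"`, `"D1"`, `"D3"`).
#' @return A contrast specification list.
#' @export
contrast_unpaired <- function(a, b) {
  structure(list(type = "unpaired", a = a, b = b), class = "de_contrast")
}

#' @rdname contrast_unpaired
#' @export
contrast_paired <- function(a, b) {
  structure(list(type = "paired", a = a, b = b), class = "de_contrast")
}

# Stratum label per sample: HC for controls, otherwise the timepoint.
.stratum <- function(records) {
  ifelse(records$group == "HC", "HC", records$timepoint)
}

#' Per-protein effect and residual variance for a contrast
#'
#' For an unpaired contrast the effect is the difference of group means with
#' the pooled two-sample variance (`d = nA + nB - 2`, unscaled variance
#' `v = 1/nA + 1/nB`). For a paired contrast the effect is the mean of the
#' per-subject differences (`d = npairs - 1`, `v = 1/npairs`).
#'
#' @param matrix Samples x proteins abundance matrix.
#' @param records Sample metadata with `sample_id`, `subject_id`, `group`,
#'   `timepoint`.
#' @param contrast A [contrast_unpaired()] or [contrast_paired()] spec.
#' @return List of class `de_fit`: `coef` (named per-protein effect), `s2`
#'   (residual variance), `df_resid`, `v`, and the contrast.
#' @export
fit_contrast <- function(matrix, records, contrast) {
  stopifnot(inherits(contrast, "de_contrast"))
  need <- c("sample_id", "subject_id", "group", "timepoint")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[records$sample_id %in% rownames(matrix), , drop = FALSE]
  strat <- .stratum(records)
  if (contrast$type == "unpaired") {
    ida <- records$sample_id[strat == contrast$a]
    idb <- records$sample_id[strat == contrast$b]
    if (length(ida) < 2 || length(idb) < 2) {
      stop("need at least 2 samples per arm", call. = FALSE)
    }
    xa <- matrix[ida, , drop = FALSE]
    xb <- matrix[idb, , drop = FALSE]
    na <- length(ida); nb <- length(idb)
    coef <- colMeans(xa) - colMeans(xb)
    s2 <- ((na - 1) * apply(xa, 2, stats::var) +
           (nb - 1) * apply(xb, 2, stats::var)) / (na + nb - 2)
    d <- na + nb - 2
    v <- 1 / na + 1 / nb
  } else {
    ra <- records[strat == contrast$a, , drop = FALSE]
    rb <- records[strat == contrast$b, , drop = FALSE]
    common <- intersect(ra$subject_id, rb$subject_id)
    orphans <- setdiff(union(ra$subject_id, rb$subject_id), common)
    if (length(orphans)) {
      stop("unmatched pair subjects: ", paste(orphans, collapse = ", "),
           call. = FALSE)
    }
    if (length(common) < 2) {
      stop("need at least 2 complete pairs", call. = FALSE)
    }
    ida <- ra$sample_id[match(common, ra$subject_id)]
    idb <- rb$sample_id[match(common, rb$subject_id)]
    diffs <- matrix[ida, , drop = FALSE] - matrix[idb, , drop = FALSE]
    np <- length(common)
    coef <- colMeans(diffs)
    s2 <- apply(diffs, 2, stats::var)
    d <- np - 1
    v <- 1 / np
  }
  structure(list(coef = coef, s2 = s2, df_resid = d, v = v,
                 contrast = contrast),
            class = "de_fit")
}

# Newton inversion of the trigamma function (limma-style), relative
# tolerance 1e-8. Used by the variance-prior moment estimator.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior of the hierarchical variance
#' model by matching the mean and variance of `log(s2)` to their theoretical
#' digamma/trigamma moments. When the trigamma moment equation has no
#' positive solution the prior degrees of freedom are infinite (complete
#' shrinkage to a common variance).
#'
#' @param s2 Per-protein residual variances (zeros are excluded from
#'   estimation with a message).
#' @param d Residual degrees of freedom of each `s2`.
#' @return List of class `ebayes_prior` with `d0` (prior df, possibly `Inf`)
#'   and `s0sq` (prior variance).
#' @export
estimate_ebayes_prior <- function(s2, d) {
  if (all(s2 <= 0)) {
    stop("all residual variances are zero: degenerate data", call. = FALSE)
  }
  if (any(s2 <= 0)) {
    message(sum(s2 <= 0),
            " zero-variance proteins excluded from prior estimation")
    s2 <- s2[s2 > 0]
  }
  if (length(s2) < 2) {
    stop("need at least 2 proteins with positive variance", call. = FALSE)
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  structure(list(d0 = d0, s0sq = s0sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("Empirical-Bayes variance prior: d0 = %s, s0^2 = %.6g\n",
              format(x$d0), x$s0sq))
  invisible(x)
}

#' Moderated t-statistics
#'
#' Shrinks each residual variance toward the prior,
#' `s2_post = (d0 * s0sq + d * s2) / (d0 + d)`, and forms
#' `t = beta / sqrt(s2_post * v)` on `d0 + d` degrees of freedom with a
#' two-sided p-value. `d0 = 0` recovers the ordinary t-test; `d0 = Inf`
#' fixes the variance at `s0sq` (z-like test).
#'
#' @param beta Per-protein effect estimates.
#' @param s2 Per-protein residual variances.
#' @param d Residual degrees of freedom.
#' @param v Unscaled variance of the effect.
#' @param prior An [estimate_ebayes_prior()] result (or a list with `d0`,
#'   `s0sq`).
#' @return Data frame with `t_mod`, `df_total`, `p`.
#' @export
moderated_t <- function(beta, s2, d, v, prior) {
  d0 <- prior$d0; s0sq <- prior$s0sq
  stopifnot(d0 >= 0, s0sq > 0 || d0 == 0)
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + d * s2) / (d0 + d)
  df_total <- d0 + d
  se <- sqrt(s2_post * v)
  t_mod <- numeric(length(beta))
  zero_se <- se == 0
  if (any(zero_se & beta != 0)) {
    warning("zero posterior variance with non-zero effect: infinite t",
            call. = FALSE)
  }
  t_mod[!zero_se] <- beta[!zero_se] / se[!zero_se]
  t_mod[zero_se] <- sign(beta[zero_se]) * Inf
  t_mod[zero_se & beta == 0] <- 0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(t_mod = t_mod, df_total = df_total, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input order is preserved; adjusted values are monotone (cumulative
#' minimum from the largest p) and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Signed linear-scale fold change
#'
#' `2^log2fc` for non-negative log2 fold changes, `-2^(-log2fc)` otherwise,
#' so magnitude is always at least 1 and the sign carries direction.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Signed fold changes.
#' @export
signed_fold_change <- function(log2fc) {
  stopifnot(all(is.finite(log2fc)))
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' Call differentially expressed proteins
#'
#' `up` when `log2fc >= log2(fc_min)` and `p_adj <= alpha`; `down` for the
#' mirror condition; otherwise `ns`. Boundary values are inclusive.
#'
#' @param results Data frame with `log2fc` and `p_adj`.
#' @param fc_min Minimum linear fold change (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `results` with a `status` column.
#' @export
call_deps <- function(results, fc_min = 2, alpha = 0.05) {
  stopifnot(all(c("log2fc", "p_adj") %in% names(results)), fc_min > 0)
  lfc <- log2(fc_min)
  results$status <- ifelse(
    results$p_adj <= alpha & results$log2fc >= lfc, "up",
    ifelse(results$p_adj <= alpha & results$log2fc <= -lfc, "down", "ns"))
  results
}

#' Empirical-Bayes moderated-t differential expression
#'
#' Full stage: per-protein contrast fit, variance-prior estimation,
#' moderated t-statistics, Benjamini-Hochberg adjustment and DEP calling
#' with the fold-change gate.
#'
#' @inheritParams fit_contrast
#' @inheritParams call_deps
#' @return Data frame of class `de_result` with one row per protein:
#'   `protein_id`, `log2fc`, `signed_fc`, `t_mod`, `df_total`, `p`, `p_adj`,
#'   `status`; attributes `prior` and `contrast`.
#' @export
de_test <- function(matrix, records, contrast, fc_min = 2, alpha = 0.05) {
  fit <- fit_contrast(matrix, records, contrast)
  prior <- estimate_ebayes_prior(fit$s2, fit$df_resid)
  mt <- moderated_t(fit$coef, fit$s2, fit$df_resid, fit$v, prior)
  out <- data.frame(protein_id = names(fit$coef),
                    log2fc = unname(fit$coef),
                    signed_fc = signed_fold_change(unname(fit$coef)),
                    t_mod = mt$t_mod, df_total = mt$df_total, p = mt$p,
                    stringsAsFactors = FALSE)
  out$p_adj <- benjamini_hochberg(out$p)
  out <- call_deps(out, fc_min = fc_min, alpha = alpha)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", class(out))
  out
}

#' @export
print.de_result <- function(x, n = 10, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Differential expression (%s %s vs %s): %d proteins, %d up, %d down\n",
              ct$type, ct$a, ct$b, nrow(x),
              sum(x$status == "up"), sum(x$status == "down")))
  pr <- attr(x, "prior")
  cat(sprintf("  prior: d0 = %s, s0^2 = %.4g\n", format(pr$d0), pr$s0sq))
  ord <- order(x$p_adj, x$p)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n), digits = 4)
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  table(factor(object$status, levels = c("up", "down", "ns")))
}
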