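test_that("unpaired contrast fit reproduces hand pooled-variance arithmetic", {
  d <- toy_dataset(list(D1 = c(1, 2, 3), HC = c(4, 5, 6)))
  fit <- fit_contrast(d$abundance, d$records, contrast_unpaired("D1", "HC"))
  expect_equal(unname(fit$coef), -3)
  expect_equal(unname(fit$s2), 1)
  expect_equal(fit$df_resid, 4)
  expect_equal(fit$v, 2 / 3)

  d0 <- toy_dataset(list(D1 = c(0, 0), HC = c(1, 1)))
  fit0 <- fit_contrast(d0$abundance, d0$records, contrast_unpaired("D1", "HC"))
  expect_equal(unname(fit0$coef), -1)
  expect_equal(unname(fit0$s2), 0)
  expect_equal(fit0$df_resid, 2)
})

test_that("paired contrast uses within-subject differences", {
  d <- toy_dataset(list(D1 = c(1, 2, 4), D3 = c(2, 4, 5)))
  fit <- fit_contrast(d$abundance, d$records, contrast_paired("D3", "D1"))
  # diffs: 1, 2, 1
  expect_equal(unname(fit$coef), 4 / 3)
  expect_equal(unname(fit$s2), var(c(1, 2, 1)))
  expect_equal(fit$df_resid, 2)
  expect_equal(fit$v, 1 / 3)

  # subject-duplicated matrix: all differences zero
  dd <- toy_dataset(list(D1 = c(1, 5, 2), D3 = c(1, 5, 2)))
  fit0 <- fit_contrast(dd$abundance, dd$records, contrast_paired("D3", "D1"))
  expect_equal(unname(fit0$coef), 0)

  # orphan subjects are listed
  d2 <- toy_dataset(list(D1 = c(1, 2, 3), D3 = c(2, 4)))
  expect_error(fit_contrast(d2$abundance, d2$records,
                            contrast_paired("D3", "D1")),
               "S03")
})

test_that("variance-prior moments solve the documented cases", {
  # identical variances: no dispersion, complete shrinkage
  pr <- estimate_ebayes_prior(rep(2, 10), d = 6)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0sq, 2 * exp(-digamma(3) + log(3)), tolerance = 1e-10)

  # two proteins, s2 = {1, e}: finite positive d0
  pr2 <- estimate_ebayes_prior(c(1, exp(1)), d = 10)
  expect_true(is.finite(pr2$d0) && pr2$d0 > 0)

  expect_error(estimate_ebayes_prior(c(0, 0), d = 4), "degenerate")
})

test_that("variance prior is recovered from its own hierarchical model", {
  set.seed(8)
  d0 <- 4; s0sq <- 1; d <- 10; n <- 5000
  sigma2 <- d0 * s0sq / rchisq(n, df = d0)
  s2 <- sigma2 * rchisq(n, df = d) / d
  pr <- estimate_ebayes_prior(s2, d)
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s0sq - s0sq) / s0sq, 0.15)
})

test_that("moderated t interpolates between ordinary t and z limits", {
  # hand case: d0 = 4, s0^2 = 1, d = 2, s2 = 2, beta = 1, v = 1
  mt <- moderated_t(1, 2, 2, 1, list(d0 = 4, s0sq = 1))
  expect_equal(mt$t_mod, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(mt$df_total, 6)

  # d0 = 0: the ordinary two-sample t statistic
  d <- toy_dataset(list(D1 = c(1.2, 2.5, 3.1), HC = c(2.4, 4.8, 6.6)))
  fit <- fit_contrast(d$abundance, d$records, contrast_unpaired("D1", "HC"))
  mt0 <- moderated_t(fit$coef, fit$s2, fit$df_resid, fit$v,
                     list(d0 = 0, s0sq = 1))
  tt <- t.test(c(1.2, 2.5, 3.1), c(2.4, 4.8, 6.6), var.equal = TRUE)
  expect_equal(mt0$t_mod, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(mt0$p, tt$p.value, tolerance = 1e-12)

  # d0 = Inf: fixed-variance z-form
  mtInf <- moderated_t(2, 5, 4, 0.5, list(d0 = Inf, s0sq = 1))
  expect_equal(mtInf$t_mod, 2 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(mtInf$p, 2 * pnorm(-abs(2 / sqrt(0.5))), tolerance = 1e-12)

  # zero effect
  expect_equal(moderated_t(0, 1, 4, 1, list(d0 = 4, s0sq = 1))$p, 1)
})

test_that("moderated pipeline agrees with the limma oracle", {
  skip_if_not_installed("limma")
  ch <- generate_cohort(sim_config(seed = 17))
  strat <- ifelse(ch$samples$group == "HC", "HC", ch$samples$timepoint)
  keep <- strat %in% c("HC", "D1")
  ids <- ch$samples$sample_id[keep]
  de <- de_test(ch$abundance, ch$samples, contrast_unpaired("D1", "HC"))

  design <- cbind(1, strat[keep] == "D1")
  fit <- limma::lmFit(t(ch$abundance[ids, ]), design)
  fit <- limma::eBayes(fit)
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior")$s0sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_mod, unname(fit$t[de$protein_id, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[de$protein_id, 2]), tolerance = 1e-8)
})

test_that("shrinkage pulls t statistics toward the prior variance", {
  ch <- generate_cohort(sim_config(seed = 23))
  fit <- fit_contrast(ch$abundance, ch$samples, contrast_unpaired("D1", "HC"))
  pr <- estimate_ebayes_prior(fit$s2, fit$df_resid)
  mod <- moderated_t(fit$coef, fit$s2, fit$df_resid, fit$v, pr)
  ord <- fit$coef / sqrt(fit$s2 * fit$v)
  low <- fit$s2 < pr$s0sq
  expect_true(all(abs(mod$t_mod[low]) <= abs(ord[low]) + 1e-12))
  expect_true(all(abs(mod$t_mod[!low]) >= abs(ord[!low]) - 1e-12))
})

test_that("BH adjustment matches the documented examples and validates input", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("DEP calls are inclusive at both thresholds", {
  df <- data.frame(log2fc = c(1.0, 0.9, -1.5, 2.0),
                   p_adj = c(0.05, 0.001, 0.01, 0.2))
  out <- call_deps(df)
  expect_equal(out$status, c("up", "ns", "down", "ns"))
})

test_that("signed fold change matches the printed convention", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-3), -8)
  expect_equal(signed_fold_change(0), 1)
  # printed CRP fold change 46.955 corresponds to log2fc = log2(46.955)
  expect_equal(signed_fold_change(log2(46.955)), 46.955, tolerance = 1e-12)
  expect_equal(signed_fold_change(5.5532), 46.96, tolerance = 1e-3)
})

test_that("de_test output satisfies its structural invariants", {
  ch <- generate_cohort(sim_config(seed = 29))
  de <- de_test(ch$abundance, ch$samples, contrast_unpaired("D1", "HC"))
  expect_s3_class(de, "de_result")
  expect_true(all(de$p_adj >= de$p - 1e-15))
  expect_true(all(abs(de$signed_fc) >= 1))
  up <- de[de$status == "up", ]
  expect_true(all(up$log2fc >= 1 & up$p_adj <= 0.05))
  dn <- de[de$status == "down", ]
  expect_true(all(dn$log2fc <= -1 & dn$p_adj <= 0.05))
  # missing metadata column is reported by name
  bad <- ch$samples[, setdiff(names(ch$samples), "timepoint")]
  expect_error(de_test(ch$abundance, bad, contrast_unpaired("D1", "HC")),
               "timepoint")
})
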