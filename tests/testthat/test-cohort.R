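test_that("median/IQR summaries use interpolated quartiles", {
  expect_equal(summarize_continuous(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(summarize_continuous(7), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(summarize_continuous(c(1, 1, 1, 1)),
               c(median = 1, q1 = 1, q3 = 1))
  expect_error(summarize_continuous(numeric(0)), "finite")
})

test_that("percentages round half-up like the printed cohort table", {
  expect_identical(percent_of(15, 23), 65L)
  expect_identical(percent_of(19, 23), 83L)
  expect_identical(percent_of(0, 23), 0L)
  expect_identical(percent_of(1, 8), 13L)  # 12.5 rounds up
  expect_error(percent_of(1, 0), "total")
  expect_error(percent_of(5, 3), "count")
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res["U"]), 0)
  expect_equal(unname(res["p"]), 1 / 3)
  # same multiset in both arms: p = 1
  expect_equal(unname(mann_whitney(c(5, 1, 3), c(5, 1, 3))["p"]), 1,
               tolerance = 1e-10)
  a <- c(1.2, 5.1, 2.2, 9); b <- c(0.4, 3.3, 7.7)
  expect_equal(mann_whitney(a, b)["p"], mann_whitney(b, a)["p"])
  expect_warning(res <- mann_whitney(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(unname(res["p"]), 1)
})

test_that("exact Mann-Whitney branch agrees with full enumeration", {
  # brute-force two-sided p by enumerating all assignments of ranks
  enum_p <- function(a, b) {
    n <- length(a); vals <- c(a, b)
    u_obs <- sum(outer(a, b, ">"))
    us <- apply(utils::combn(length(vals), n), 2, function(idx) {
      sum(outer(vals[idx], vals[-idx], ">"))
    })
    mu <- length(a) * length(b) / 2
    mean(abs(us - mu) >= abs(u_obs - mu))
  }
  set.seed(19)
  for (rep in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- round(rnorm(na), 3); b <- round(rnorm(nb), 3)
    expect_equal(unname(mann_whitney(a, b)["p"]), enum_p(a, b),
                 tolerance = 1e-10)
  }
})

test_that("chi-square is Pearson without continuity correction", {
  res <- chi_square(matrix(c(5, 5, 5, 5), 2))
  expect_equal(unname(res["statistic"]), 0)
  expect_equal(unname(res["p"]), 1)
  suppressWarnings(res2 <- chi_square(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(unname(res2["statistic"]), 20)
  expect_equal(unname(res2["df"]), 1)
  tab <- matrix(c(12, 7, 9, 14), 2)
  expect_equal(chi_square(tab)["statistic"], chi_square(t(tab))["statistic"])
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "marginal")
})

test_that("chi-square matches the hand 2x2 formula on random tables", {
  set.seed(5)
  for (rep in 1:100) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    hand <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(unname(suppressWarnings(chi_square(tab))["statistic"]), hand,
                 tolerance = 1e-12)
  }
})

test_that("association matrix tiers follow raw and adjusted significance", {
  set.seed(21)
  df <- data.frame(x = rnorm(40))
  df$x_copy <- df$x
  df$noise <- rnorm(40)
  out <- association_matrix(df)
  self <- out[out$var1 == "x" & out$var2 == "x_copy", ]
  expect_identical(self$tier, "fdr")
  expect_true(all(out$tier %in% c("fdr", "raw", "ns")))
  # constant variable warns (once per pair) and is non-significant
  expect_warning(association_matrix(data.frame(a = rnorm(10), flat = 1)),
                 "constant")
  df$flat <- 1
  out2 <- suppressWarnings(association_matrix(df))
  expect_true(all(out2$tier[out2$var1 == "flat" | out2$var2 == "flat"] == "ns"))
})

test_that("association matrix is calibrated on independent variables", {
  set.seed(31)
  fracs <- replicate(20, {
    df <- as.data.frame(matrix(rnorm(50 * 10), 50))
    out <- association_matrix(df)
    mean(out$p < 0.05)
  })
  # 45 pairs x 20 seeds, null: fraction of raw p<0.05 near 0.05
  expect_gt(mean(fracs), 0.05 - 3 * sqrt(0.05 * 0.95 / (45 * 20)))
  expect_lt(mean(fracs), 0.05 + 3 * sqrt(0.05 * 0.95 / (45 * 20)))
})

test_that("PCA embedding is deterministic in sign and ordered by variance", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("p%02d", 1:10)))
  m <- rbind(m, dup = m[1, ])
  sc <- pca_embedding(m, k = 2)
  expect_equal(sc[1, ], sc["dup", ], ignore_attr = TRUE)
  expect_gte(var(sc[, 1]), var(sc[, 2]))
  expect_error(pca_embedding(m, k = 50), "k exceeds")
})

test_that("cohort strata separate in PC space when effects are planted", {
  ch <- generate_cohort(sim_config(seed = 13))
  strat <- ifelse(ch$samples$group == "HC", "HC", ch$samples$timepoint)
  keep <- strat %in% c("HC", "D1")
  sc <- pca_embedding(ch$abundance[ch$samples$sample_id[keep], ], k = 2)
  lab <- strat[keep]
  # mean silhouette of the two clusters on PC coordinates
  dmat <- as.matrix(dist(sc))
  sil <- vapply(seq_along(lab), function(i) {
    same <- which(lab == lab[i] & seq_along(lab) != i)
    a <- mean(dmat[i, same])
    b <- mean(dmat[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})

test_that("cohort summary table reports both kinds of variables", {
  ch <- simulate_cohort(tiny_config())
  summ <- suppressWarnings(summarize_cohort(
    ch$samples, continuous = c("age_years", "PELOD2_D1"),
    categorical = c("sex", "mech_vent")))
  expect_equal(nrow(summ), 4)
  expect_setequal(summ$kind[summ$variable %in% c("sex", "mech_vent")],
                  "categorical")
  # age present in both groups: tested; PELOD-2 sepsis-only: no test
  expect_false(is.na(summ$p[summ$variable == "age_years"]))
  expect_true(is.na(summ$p[summ$variable == "PELOD2_D1"]))
})
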