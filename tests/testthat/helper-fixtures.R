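# Shared fixtures built in code: small cohorts and toy matrices.

tiny_config <- function(...) {
  sim_config(n_sepsis = 8, n_control = 8, n_proteins = 30, n_dep = 6,
             n_outcome_proteins = 3, n_mortality_proteins = 2,
             n_terms = 8, term_size_range = c(4L, 10L), enriched_terms = 2,
             seed = 42L, ...)
}

# A minimal abundance matrix + records pair with known group means.
toy_dataset <- function(values_by_stratum, n_proteins = 1) {
  strata <- names(values_by_stratum)
  rows <- list(); recs <- list(); subj_count <- 0
  for (st in strata) {
    vals <- values_by_stratum[[st]]
    for (i in seq_along(vals)) {
      id <- sprintf("%s_%02d", st, i)
      rows[[id]] <- rep(vals[i], n_proteins)
      recs[[id]] <- data.frame(
        sample_id = id,
        subject_id = if (st %in% c("D1", "D3")) sprintf("S%02d", i) else id,
        group = if (st == "HC") "HC" else "SEPSIS",
        timepoint = if (st == "HC") NA_character_ else st,
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- sprintf("P%02d", seq_len(n_proteins))
  list(abundance = mat, records = do.call(rbind, recs))
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
enum_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
}

# Brute-force BH rejection set: largest j with p_(j) <= j * alpha / m.
bh_reject_bruteforce <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}
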