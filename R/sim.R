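#' Simulation configuration for a synthetic sepsis proteomics cohort
#'
#' Builds and validates the parameter set for [generate_cohort()] and friends.
#' Defaults emulate a paired-sampling pediatric sepsis study: 23 sepsis
#' subjects sampled on intensive-care days 1 and 3 (D1/D3), 23 healthy
#' controls, and a targeted panel of ~120 plasma proteins on the log2 scale.
#'
#' @param n_sepsis Number of sepsis subjects (each contributes a D1 and a D3
#'   sample).
#' @param n_control Number of healthy-control subjects (one sample each,
#'   timepoint `NA`).
#' @param n_proteins Panel size.
#' @param n_dep Number of planted differentially expressed proteins (DEPs).
#' @param effect_log2fc Absolute planted log2 fold change of each DEP for the
#'   D1-versus-control comparison; signs are drawn per protein.
#' @param sd_within Residual standard deviation on the log2 scale.
#' @param d3_attenuation Fraction of the D1 effect remaining at D3
#'   (in `[0, 1]`).
#' @param n_outcome_proteins Number of proteins planted to correlate with the
#'   PELOD-2 severity score.
#' @param rho_outcome Target magnitude of the per-protein population
#'   correlation with PELOD-2 (`|rho| < 1`); `0` disables the planting.
#' @param n_mortality_proteins Number of proteins feeding the logistic
#'   mortality model.
#' @param mortality_rate Target marginal death probability among sepsis
#'   subjects.
#' @param n_terms Number of synthetic gene sets.
#' @param term_size_range Length-2 integer vector, min/max gene-set size.
#' @param enriched_terms Number of terms seeded with planted DEPs
#'   (at least 70% of their members are DEPs).
#' @param missing_rate Optional completely-at-random missingness rate applied
#'   to the abundance matrix (default 0: no missing values).
#' @param seed Integer seed; identical configs reproduce identical data.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sepsis = 23, n_control = 23, n_proteins = 120,
                       n_dep = 20, effect_log2fc = 1.5, sd_within = 0.5,
                       d3_attenuation = 0.5, n_outcome_proteins = 8,
                       rho_outcome = 0.6, n_mortality_proteins = 4,
                       mortality_rate = 0.15, n_terms = 25,
                       term_size_range = c(8L, 30L), enriched_terms = 3,
                       missing_rate = 0, seed = 1L) {
  cfg <- list(
    n_sepsis = n_sepsis, n_control = n_control, n_proteins = n_proteins,
    n_dep = n_dep, effect_log2fc = effect_log2fc, sd_within = sd_within,
    d3_attenuation = d3_attenuation,
    n_outcome_proteins = n_outcome_proteins, rho_outcome = rho_outcome,
    n_mortality_proteins = n_mortality_proteins,
    mortality_rate = mortality_rate, n_terms = n_terms,
    term_size_range = as.integer(term_size_range),
    enriched_terms = enriched_terms, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  for (f in c("n_sepsis", "n_control", "n_proteins", "n_terms")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) stop_field(f, "must be a positive count")
  }
  for (f in c("n_dep", "n_outcome_proteins", "n_mortality_proteins",
              "enriched_terms")) {
    if (!is_count(cfg[[f]])) stop_field(f, "must be a non-negative count")
  }
  if (cfg$n_dep > cfg$n_proteins) stop_field("n_dep", "cannot exceed n_proteins")
  if (cfg$n_outcome_proteins > cfg$n_proteins)
    stop_field("n_outcome_proteins", "cannot exceed n_proteins")
  if (cfg$n_mortality_proteins > cfg$n_proteins)
    stop_field("n_mortality_proteins", "cannot exceed n_proteins")
  if (cfg$enriched_terms > cfg$n_terms)
    stop_field("enriched_terms", "cannot exceed n_terms")
  if (!is.numeric(cfg$effect_log2fc) || !is.finite(cfg$effect_log2fc))
    stop_field("effect_log2fc", "must be finite")
  if (!is.numeric(cfg$sd_within) || cfg$sd_within <= 0)
    stop_field("sd_within", "must be positive")
  if (cfg$d3_attenuation < 0 || cfg$d3_attenuation > 1)
    stop_field("d3_attenuation", "must lie in [0, 1]")
  if (abs(cfg$rho_outcome) >= 1)
    stop_field("rho_outcome", "must satisfy |rho| < 1")
  if (cfg$mortality_rate <= 0 || cfg$mortality_rate >= 1)
    stop_field("mortality_rate", "must lie strictly in (0, 1)")
  if (length(cfg$term_size_range) != 2 || any(cfg$term_size_range < 1) ||
      cfg$term_size_range[1] > cfg$term_size_range[2])
    stop_field("term_size_range", "must be an increasing pair of positive sizes")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d sepsis subjects (D1 + D3) vs %d controls; %d proteins\n",
              x$n_sepsis, x$n_control, x$n_proteins))
  cat(sprintf("  planted: %d DEPs (|log2FC| = %g, D3 attenuation %g), %d PELOD-2 proteins (rho = %g), %d mortality proteins (rate %g)\n",
              x$n_dep, x$effect_log2fc, x$d3_attenuation,
              x$n_outcome_proteins, x$rho_outcome, x$n_mortality_proteins,
              x$mortality_rate))
  cat(sprintf("  gene sets: %d terms (sizes %d-%d), %d enriched; seed %d\n",
              x$n_terms, x$term_size_range[1], x$term_size_range[2],
              x$enriched_terms, x$seed))
  invisible(x)
}

# Population mean/sd of each protein in a given stratum, given the planted
# structure. Used both when generating and when standardising for the
# clinical model.
.stratum_moments <- function(truth, timepoint) {
  mu <- truth$mu
  delta <- numeric(length(mu))
  names(delta) <- names(mu)
  delta[truth$dep$protein_id] <- truth$dep$effect
  g2 <- truth$gamma^2
  is_out <- stats::setNames(names(mu) %in% truth$outcome_ids, names(mu))
  if (timepoint == "D1") {
    list(mean = mu + delta,
         sd = truth$sd_within * sqrt(1 + g2 * is_out))
  } else { # D3: value = D1 + (a - 1) * delta + fresh noise
    list(mean = mu + truth$d3_attenuation * delta,
         sd = truth$sd_within * sqrt(2 + g2 * is_out))
  }
}

#' Generate a synthetic abundance matrix with planted structure
#'
#' Draws a log2 abundance matrix for `n_control` healthy-control samples plus
#' paired D1/D3 samples from `n_sepsis` sepsis subjects. Planted DEPs are
#' shifted by their signed effect at D1 (attenuated at D3); outcome proteins
#' additionally load on a per-subject latent severity factor so that
#' [generate_clinical()] can plant severity correlations.
#'
#' @param config A [sim_config()] object.
#' @return A list with `abundance` (samples x proteins matrix), `samples`
#'   (data frame of sample/subject/group/timepoint identity) and `truth`
#'   (planted ground truth: signed DEP effects, outcome and mortality protein
#'   ids, latent factors).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    p_ids <- sprintf("P%03d", seq_len(config$n_proteins))
    mu <- stats::rnorm(config$n_proteins, mean = 8, sd = 2)
    names(mu) <- p_ids

    dep_ids <- sort(sample(p_ids, config$n_dep))
    dep_sign <- sample(c(-1, 1), config$n_dep, replace = TRUE)
    dep <- data.frame(protein_id = dep_ids,
                      effect = dep_sign * config$effect_log2fc,
                      stringsAsFactors = FALSE)

    rho <- abs(config$rho_outcome)
    m_out <- if (rho == 0) 0L else config$n_outcome_proteins
    # Outcome proteins are taken from the planted DEPs first: disease-driving
    # proteins tracking severity is the structure the downstream graph assumes.
    outcome_ids <- character(0)
    if (m_out > 0) {
      k1 <- min(m_out, length(dep_ids))
      outcome_ids <- sample(dep_ids, k1)
      if (m_out > k1) {
        outcome_ids <- c(outcome_ids, sample(setdiff(p_ids, dep_ids), m_out - k1))
      }
      outcome_ids <- sort(outcome_ids)
    }
    mortality_ids <- sort(sample(p_ids, config$n_mortality_proteins))
    gamma <- if (rho > 0) sqrt(rho / (1 - rho)) else 0

    subj <- sprintf("S%03d", seq_len(config$n_sepsis))
    u <- stats::rnorm(config$n_sepsis)
    names(u) <- subj

    sdw <- config$sd_within
    delta <- numeric(config$n_proteins)
    names(delta) <- p_ids
    delta[dep$protein_id] <- dep$effect
    out_mask <- as.numeric(p_ids %in% outcome_ids)

    base <- matrix(mu, nrow = config$n_control, ncol = config$n_proteins,
                   byrow = TRUE)
    hc <- base + matrix(stats::rnorm(config$n_control * config$n_proteins,
                                     sd = sdw),
                        nrow = config$n_control)
    d1 <- matrix(mu + delta, nrow = config$n_sepsis,
                 ncol = config$n_proteins, byrow = TRUE) +
      gamma * sdw * (u %o% out_mask) +
      matrix(stats::rnorm(config$n_sepsis * config$n_proteins, sd = sdw),
             nrow = config$n_sepsis)
    d3 <- d1 +
      matrix((config$d3_attenuation - 1) * delta, nrow = config$n_sepsis,
             ncol = config$n_proteins, byrow = TRUE) +
      matrix(stats::rnorm(config$n_sepsis * config$n_proteins, sd = sdw),
             nrow = config$n_sepsis)

    hc_ids <- sprintf("HC%03d", seq_len(config$n_control))
    d1_ids <- paste0(subj, "_D1")
    d3_ids <- paste0(subj, "_D3")
    abundance <- rbind(hc, d1, d3)
    rownames(abundance) <- c(hc_ids, d1_ids, d3_ids)
    colnames(abundance) <- p_ids

    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(abundance)) < config$missing_rate,
                     nrow = nrow(abundance))
      abundance[mask] <- NA_real_
    }

    samples <- data.frame(
      sample_id = c(hc_ids, d1_ids, d3_ids),
      subject_id = c(hc_ids, subj, subj),
      group = c(rep("HC", config$n_control), rep("SEPSIS", 2 * config$n_sepsis)),
      timepoint = c(rep(NA_character_, config$n_control),
                    rep("D1", config$n_sepsis), rep("D3", config$n_sepsis)),
      stringsAsFactors = FALSE
    )

    truth <- list(
      dep = dep, outcome_ids = outcome_ids, mortality_ids = mortality_ids,
      enriched_term_ids = character(0),
      mu = mu, gamma = gamma, u = u,
      sd_within = sdw, d3_attenuation = config$d3_attenuation,
      rho_outcome = rho, seed = config$seed
    )
    list(abundance = abundance, samples = samples, truth = truth)
  })
}

#' Attach synthetic clinical variables to the sample table
#'
#' PELOD-2 severity scores (per timepoint) are a noisy linear readout of the
#' standardised planted outcome proteins, calibrated so each planted protein's
#' population correlation with the score equals `rho_outcome`. Mortality is
#' drawn from a logistic model on the mortality-protein values with marginal
#' rate calibrated to `mortality_rate`. Demographic and treatment covariates
#' (sex, age, comorbidity and infection-source flags, ventilation and
#' circulatory support, length of stay) are generated as nuisance variables
#' with no planted protein signal. Controls carry no severity scores.
#'
#' @param truth Ground-truth list from [generate_cohort()].
#' @param records Sample table from [generate_cohort()].
#' @param config The [sim_config()] used to generate the cohort.
#' @param abundance The abundance matrix from [generate_cohort()] (the scores
#'   are a function of the realised protein values).
#' @return The `records` data frame with clinical columns appended.
#' @export
generate_clinical <- function(truth, records, config, abundance) {
  stopifnot(inherits(config, "sim_config"))
  sep <- records[records$group == "SEPSIS", , drop = FALSE]
  subj <- unique(sep$subject_id)
  if (!all(subj %in% names(truth$u)) ||
      !all(records$sample_id %in% rownames(abundance))) {
    stop("truth/records identity mismatch: unknown subject or sample ids",
         call. = FALSE)
  }
  n <- length(subj)
  rho <- truth$rho_outcome
  m <- length(truth$outcome_ids)

  pelod_from <- function(timepoint, noise) {
    mom <- .stratum_moments(truth, timepoint)
    ids <- paste0(subj, "_", timepoint)
    if (m > 0) {
      z <- sweep(sweep(abundance[ids, truth$outcome_ids, drop = FALSE], 2,
                       mom$mean[truth$outcome_ids]), 2,
                 mom$sd[truth$outcome_ids], "/")
      g2 <- truth$gamma^2
      extra_var <- if (timepoint == "D1") 1 else 2
      cc <- (g2 + extra_var / m) / (extra_var + g2)
      sn <- sqrt(cc^2 / rho^2 - cc)
      p <- rowMeans(z) + sn * noise
    } else {
      p <- noise
    }
    pmax(0, round(10 + 4 * p, 1))
  }

  with_seed(derive_seed(config$seed, 2L), {
    noise1 <- stats::rnorm(n)
    noise3 <- stats::rnorm(n)
    pelod1 <- pelod_from("D1", noise1)
    pelod3 <- pelod_from("D3", noise3)

    # Mortality: logistic model on the standardised D1 values of the
    # mortality proteins, intercept solved so the marginal rate matches.
    mom1 <- .stratum_moments(truth, "D1")
    mids <- truth$mortality_ids
    if (length(mids) > 0) {
      zm <- sweep(sweep(abundance[paste0(subj, "_D1"), mids, drop = FALSE], 2,
                        mom1$mean[mids]), 2, mom1$sd[mids], "/")
      mscore <- rowMeans(zm)
      g2n <- truth$gamma^2 / (1 + truth$gamma^2)
      m_o <- sum(mids %in% truth$outcome_ids)
      var_m <- (length(mids) + m_o * (m_o - 1) * g2n) / length(mids)^2
      mstd <- mscore / sqrt(var_m)
    } else {
      mstd <- stats::rnorm(n)
    }
    slope <- 1.5
    marg <- function(b0) {
      stats::integrate(function(z) stats::dnorm(z) * stats::plogis(b0 + slope * z),
                       -Inf, Inf)$value - config$mortality_rate
    }
    b0 <- stats::uniroot(marg, c(-30, 30))$root
    mortality <- stats::rbinom(n, 1, stats::plogis(b0 + slope * mstd))

    ctrl_subj <- unique(records$subject_id[records$group == "HC"])
    n_all <- n + length(ctrl_subj)
    age <- round(pmin(17, pmax(0.1, stats::rnorm(n_all, 11, 3.5))), 1)
    sex <- sample(c("M", "F"), n_all, replace = TRUE)

    flag <- function(rate) stats::rbinom(n, 1, rate)
    clin <- data.frame(
      subject_id = subj,
      PELOD2_D1 = pelod1, PELOD2_D3 = pelod3, mortality = mortality,
      confirmed_sepsis = flag(0.65),
      comorbidity_any = flag(0.91), comorbidity_neuro = flag(0.30),
      comorbidity_onco = flag(0.15), comorbidity_gi = flag(0.15),
      source_respiratory = flag(0.48), wound_infection = flag(0.10),
      mech_vent = flag(0.74), circ_support = flag(0.83),
      picu_days = pmax(1, round(stats::rlnorm(n, log(9), 0.45))),
      stringsAsFactors = FALSE
    )
    clin$hospital_days <- clin$picu_days +
      pmax(0, round(stats::rlnorm(n, log(8), 0.6)))

    demo <- data.frame(subject_id = c(subj, ctrl_subj), age_years = age,
                       sex = sex, stringsAsFactors = FALSE)
    out <- merge(records, demo, by = "subject_id", all.x = TRUE, sort = FALSE)
    out <- merge(out, clin, by = "subject_id", all.x = TRUE, sort = FALSE)
    out <- out[match(records$sample_id, out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    front <- c("sample_id", "subject_id", "group", "timepoint")
    out[, c(front, setdiff(names(out), front)), drop = FALSE]
  })
}

#' Generate synthetic gene sets over the simulated protein universe
#'
#' Produces `n_terms` gene sets; `enriched_terms` of them are seeded so that
#' at least 70% of their members are planted DEPs, the rest sample the panel
#' uniformly.
#'
#' @inheritParams generate_clinical
#' @return A [gene_sets] collection with attribute `enriched_term_ids`.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  p_ids <- names(truth$mu)
  if (config$term_size_range[2] > length(p_ids)) {
    stop_field("term_size_range", "maximum size exceeds the protein universe")
  }
  dep_ids <- truth$dep$protein_id
  with_seed(derive_seed(config$seed, 3L), {
    term_ids <- sprintf("TERM%02d", seq_len(config$n_terms))
    enriched <- if (config$enriched_terms > 0) {
      sort(sample(term_ids, config$enriched_terms))
    } else character(0)
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    config$n_terms, replace = TRUE)
    members <- vector("list", config$n_terms)
    for (i in seq_len(config$n_terms)) {
      s <- sizes[i]
      if (term_ids[i] %in% enriched && length(dep_ids) > 0) {
        s <- max(2L, min(s, floor(length(dep_ids) / 0.7)))
        k_dep <- ceiling(0.7 * s)
        members[[i]] <- c(sample(dep_ids, k_dep),
                          if (s > k_dep)
                            sample(setdiff(p_ids, dep_ids), s - k_dep))
      } else {
        members[[i]] <- sample(p_ids, s)
      }
    }
    sets <- gene_sets(term_ids,
                      descriptions = sprintf("synthetic gene set %d",
                                             seq_len(config$n_terms)),
                      members = members)
    attr(sets, "enriched_term_ids") <- enriched
    sets
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_cohort()], [generate_clinical()] and
#' [generate_gene_sets()] under one configuration.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sepsis_cohort`: list with `abundance`,
#'   `samples` (clinical table), `gene_sets` and `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  base <- generate_cohort(config)
  samples <- generate_clinical(base$truth, base$samples, config, base$abundance)
  sets <- generate_gene_sets(config, base$truth)
  truth <- base$truth
  truth$enriched_term_ids <- attr(sets, "enriched_term_ids")
  structure(list(abundance = base$abundance, samples = samples,
                 gene_sets = sets, truth = truth, config = config),
            class = "sepsis_cohort")
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat(sprintf("Synthetic sepsis cohort: %d samples x %d proteins\n",
              nrow(x$abundance), ncol(x$abundance)))
  tab <- table(ifelse(x$samples$group == "HC", "HC", x$samples$timepoint))
  cat("  strata:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  planted: %d DEPs, %d outcome proteins, %d mortality proteins, %d enriched terms\n",
              nrow(x$truth$dep), length(x$truth$outcome_ids),
              length(x$truth$mortality_ids), length(x$truth$enriched_term_ids)))
  invisible(x)
}
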