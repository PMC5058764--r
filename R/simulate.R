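# Synthetic cohort, expression and image generators. Defaults are anchored to
# the published cohort marginals (grade mix, stage, adverse features, event
# fraction, volume and PSA medians), the per-cc secretion anchors for
# low-grade organ-confined (4.01 ng/ml) and high-grade invasive (1.71 ng/ml)
# tumours, and the multivariable recurrence hazard ratios.

lognormal_sdlog <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

#' Cohort simulation parameters
#'
#' Generative model of a prostatectomy cohort. Grade is categorical
#' (13.8/76.5/9.7% low/intermediate/high); stage, extraprostatic extension
#' (EPE), seminal vesicle invasion (SVI) and margins are Bernoulli with
#' grade- or stage-conditional probabilities solved so the marginals hit
#' 30.4% pT3, 29.4% EPE and 6% SVI; prostate and tumour volumes are
#' log-normal parameterised by median and IQR
#' (`sdlog = log(Q3/Q1) / (2 * qnorm(0.75))`), with grade-dependent tumour
#' medians; serum PSA is the benign contribution (per [benign_psa()]) plus
#' secretion-rate x tumour-volume x log-normal noise, where the per-cc
#' secretion rate interpolates geometrically between the anchors 4.01 (low
#' grade, organ-confined) and 1.71 ng/ml (high grade, invasive); recurrence
#' times are exponential under a proportional-hazards model with the planted
#' log-hazard-ratios, administratively censored at a horizon solved to give
#' the target event fraction.
#'
#' @param grade_probs Probabilities of low/intermediate/high grade.
#' @param pt3_target Overall pT3 fraction; `pt3_prob_low`, `pt3_prob_high`
#'   fix the outer grades and the intermediate probability is solved.
#' @param pt3_prob_low,pt3_prob_high Stage probabilities for the outer grades.
#' @param epe_target,epe_prob_pt3 EPE marginal and its pT3-conditional
#'   probability; the pT2 probability is solved.
#' @param svi_target,svi_prob_pt3 As above for SVI.
#' @param margin_prob Positive surgical margin probability.
#' @param prostate_volume_median,prostate_volume_iqr Log-normal anchors (cc).
#' @param tumour_volume_median,tumour_volume_iqr Log-normal anchors (cc).
#' @param tumour_grade_mult_low,tumour_grade_mult_high Multiplicative shifts
#'   of the tumour-volume median for the outer grades; the intermediate shift
#'   is solved so the probability-weighted log-median is unshifted.
#' @param secretion_low_pt2,secretion_high_pt3 Geometric-mean serum PSA
#'   increase (ng/ml) per cc of tumour for the two anchor groups.
#' @param psa_noise_sigma SD of the log-normal multiplicative noise on the
#'   tumour PSA contribution.
#' @param missing_psa_prob Fraction of cases with missing pre-operative PSA.
#' @param constants [tpsad_constants()] used for the benign contribution.
#' @param baseline_hazard Exponential baseline hazard (events/month) of the
#'   reference group (low grade, no adverse features).
#' @param log_hrs Named planted log-hazard-ratios: `epe`, `svi`,
#'   `positive_margins`, `grade_intermediate`, `grade_high`.
#' @param ln_tpsad_loghr Optional planted effect of ln(tPSAD) on the hazard
#'   (default 0; the observed multivariable effect was null).
#' @param target_event_fraction Overall biochemical-recurrence fraction the
#'   censoring horizon is solved for.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#'
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(grade_probs = c(low = 0.138, intermediate = 0.765, high = 0.097),
                              pt3_target = 0.304, pt3_prob_low = 0.08, pt3_prob_high = 0.70,
                              epe_target = 0.294, epe_prob_pt3 = 0.90,
                              svi_target = 0.06, svi_prob_pt3 = 0.18,
                              margin_prob = 0.25,
                              prostate_volume_median = 32.2,
                              prostate_volume_iqr = c(24.2, 43.5),
                              tumour_volume_median = 2.6,
                              tumour_volume_iqr = c(1.3, 4.8),
                              tumour_grade_mult_low = 0.70,
                              tumour_grade_mult_high = 1.80,
                              secretion_low_pt2 = 4.01,
                              secretion_high_pt3 = 1.71,
                              psa_noise_sigma = 0.30,
                              missing_psa_prob = 0.007,
                              constants = tpsad_constants(),
                              baseline_hazard = 0.0015,
                              log_hrs = c(epe = log(1.68), svi = log(1.90),
                                          positive_margins = log(2.12),
                                          grade_intermediate = log(1.97),
                                          grade_high = log(5.28)),
                              ln_tpsad_loghr = 0,
                              target_event_fraction = 0.232,
                              age_mean = 61.5, age_sd = 7, age_range = c(40.2, 79)) {
  if (abs(sum(grade_probs) - 1) > 1e-8) {
    stop_tpsad("`grade_probs` must sum to 1.", "tpsad_validation_error")
  }
  probs <- c(grade_probs, pt3_target, pt3_prob_low, pt3_prob_high, epe_target,
             epe_prob_pt3, svi_target, svi_prob_pt3, margin_prob, missing_psa_prob,
             target_event_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop_tpsad("All probabilities must lie in [0, 1].", "tpsad_validation_error")
  }
  if (psa_noise_sigma < 0) stop_tpsad("`psa_noise_sigma` must be >= 0.", "tpsad_validation_error")

  pt3_prob_int <- (pt3_target - grade_probs[["low"]] * pt3_prob_low -
                     grade_probs[["high"]] * pt3_prob_high) / grade_probs[["intermediate"]]
  epe_prob_pt2 <- (epe_target - pt3_target * epe_prob_pt3) / (1 - pt3_target)
  svi_prob_pt2 <- (svi_target - pt3_target * svi_prob_pt3) / (1 - pt3_target)
  solved <- c(pt3_prob_int, epe_prob_pt2, svi_prob_pt2)
  if (any(solved < 0 | solved > 1)) {
    stop_tpsad("Conditional probabilities solved from the marginal targets fall outside [0, 1]; adjust the anchors.",
               "tpsad_validation_error")
  }
  # intermediate multiplier keeps the probability-weighted log tumour median at 0
  mult_int <- exp(-(grade_probs[["low"]] * log(tumour_grade_mult_low) +
                      grade_probs[["high"]] * log(tumour_grade_mult_high)) /
                    grade_probs[["intermediate"]])

  structure(list(
    grade_probs = grade_probs,
    pt3_prob = c(low = pt3_prob_low, intermediate = unname(pt3_prob_int), high = pt3_prob_high),
    epe_prob = c(pT2 = unname(epe_prob_pt2), pT3 = epe_prob_pt3),
    svi_prob = c(pT2 = unname(svi_prob_pt2), pT3 = svi_prob_pt3),
    margin_prob = margin_prob,
    prostate_volume_median = prostate_volume_median,
    prostate_volume_sdlog = lognormal_sdlog(prostate_volume_iqr[1], prostate_volume_iqr[2]),
    tumour_volume_median = tumour_volume_median,
    tumour_volume_sdlog = lognormal_sdlog(tumour_volume_iqr[1], tumour_volume_iqr[2]),
    tumour_grade_mult = c(low = tumour_grade_mult_low, intermediate = unname(mult_int),
                          high = tumour_grade_mult_high),
    secretion_low_pt2 = secretion_low_pt2,
    # one geometric step per grade level and per stage level
    secretion_step = (secretion_high_pt3 / secretion_low_pt2)^(1 / 3),
    psa_noise_sigma = psa_noise_sigma,
    missing_psa_prob = missing_psa_prob,
    constants = constants,
    baseline_hazard = baseline_hazard,
    log_hrs = log_hrs,
    ln_tpsad_loghr = ln_tpsad_loghr,
    target_event_fraction = target_event_fraction,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range
  ), class = "cohort_sim_params")
}

# planted per-cc secretion rate for a (grade, stage) cell
secretion_rate <- function(params, grade, stage) {
  gstep <- c(low = 0, intermediate = 1, high = 2)[grade]
  sstep <- c(pT2 = 0, pT3 = 1)[stage]
  unname(params$secretion_low_pt2 * params$secretion_step^(gstep + sstep))
}

# linear predictor of the planted proportional-hazards model
planted_eta <- function(params, grade, epe, svi, margins, ln_tpsad = 0) {
  lh <- params$log_hrs
  lh[["epe"]] * epe + lh[["svi"]] * svi + lh[["positive_margins"]] * margins +
    lh[["grade_intermediate"]] * (grade == "intermediate") +
    lh[["grade_high"]] * (grade == "high") +
    params$ln_tpsad_loghr * ln_tpsad
}

# Administrative censoring horizon solved so the expected event fraction over
# the covariate distribution (cells x a fixed Gaussian grid for the ln tPSAD
# term) equals the target. Deterministic given the parameters.
solve_censoring_horizon <- function(params) {
  grades <- c("low", "intermediate", "high")
  stages <- c("pT2", "pT3")
  cells <- expand.grid(grade = grades, stage = stages, epe = c(FALSE, TRUE),
                       svi = c(FALSE, TRUE), margins = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  cells$p <- params$grade_probs[cells$grade] *
    ifelse(cells$stage == "pT3", params$pt3_prob[cells$grade], 1 - params$pt3_prob[cells$grade]) *
    ifelse(cells$epe, params$epe_prob[cells$stage], 1 - params$epe_prob[cells$stage]) *
    ifelse(cells$svi, params$svi_prob[cells$stage], 1 - params$svi_prob[cells$stage]) *
    ifelse(cells$margins, params$margin_prob, 1 - params$margin_prob)
  zgrid <- stats::qnorm(seq(0.5, 199.5) / 200)
  expected_events <- function(horizon) {
    per_cell <- vapply(seq_len(nrow(cells)), function(i) {
      ln_t <- log(secretion_rate(params, cells$grade[i], cells$stage[i])) +
        params$psa_noise_sigma * zgrid
      eta <- planted_eta(params, cells$grade[i], cells$epe[i], cells$svi[i],
                         cells$margins[i], ln_t)
      mean(1 - exp(-params$baseline_hazard * exp(eta) * horizon))
    }, numeric(1))
    sum(cells$p * per_cell)
  }
  upper <- 1e6
  if (expected_events(upper) <= params$target_event_fraction) {
    stop_tpsad("Target event fraction unreachable under the planted hazard model.",
               "tpsad_calibration_error")
  }
  stats::uniroot(function(h) expected_events(h) - params$target_event_fraction,
                 lower = 1e-6, upper = upper, tol = 1e-8)$root
}

#' Simulate a prostatectomy cohort
#'
#' Draws `n` patient records from the generative model described in
#' [cohort_sim_params()]. Fully reproducible for a given `seed`.
#'
#' @param n Number of patients (the published cohort had 1108 analysable
#'   cases).
#' @param params A [cohort_sim_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble of patient records: `case_id`, `age`, `serum_psa`,
#'   `prostate_volume`, `gland_weight` (all `NA`: the synthetic cohort
#'   carries volumes), `total_tumour_volume`, `index_tumour_volume`,
#'   `gleason_primary`, `gleason_secondary`, `stage`, `epe`, `svi`,
#'   `positive_margins`, `recurrence`, `followup_time`. The solved censoring
#'   horizon (months) is attached as attribute `censoring_horizon`.
#' @export
simulate_cohort <- function(n = 1108, params = cohort_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  if (n < 1) stop_tpsad("`n` must be >= 1.", "tpsad_validation_error")
  horizon <- solve_censoring_horizon(params)
  gen <- function() {
    grade <- sample(names(params$grade_probs), n, replace = TRUE, prob = params$grade_probs)
    stage <- ifelse(runif(n) < params$pt3_prob[grade], "pT3", "pT2")
    epe <- runif(n) < params$epe_prob[stage]
    svi <- runif(n) < params$svi_prob[stage]
    margins <- runif(n) < params$margin_prob

    pv <- rlnorm(n, log(params$prostate_volume_median), params$prostate_volume_sdlog)
    tv <- rlnorm(n, log(params$tumour_volume_median * params$tumour_grade_mult[grade]),
                 params$tumour_volume_sdlog)
    secretion <- secretion_rate(params, grade, stage)
    noise <- exp(rnorm(n, 0, params$psa_noise_sigma))
    serum <- benign_psa(pmax(pv - tv, 0), params$constants) + secretion * tv * noise
    serum[runif(n) < params$missing_psa_prob] <- NA_real_

    ln_tpsad_true <- log(secretion * noise)
    eta <- planted_eta(params, grade, epe, svi, margins, ln_tpsad_true)
    event_time <- rexp(n, params$baseline_hazard * exp(eta))

    # Gleason components consistent with the grade strata (3+4 vs 4+3 mix
    # follows the published intermediate-grade split)
    u <- runif(n)
    gp <- dplyr::case_when(grade == "low" ~ 3L,
                           grade == "intermediate" & u < 0.688 ~ 3L,
                           grade == "intermediate" ~ 4L,
                           u < 0.85 ~ 4L, TRUE ~ 5L)
    gs <- dplyr::case_when(grade == "low" ~ 3L,
                           grade == "intermediate" & gp == 3L ~ 4L,
                           grade == "intermediate" ~ 3L,
                           u < 0.5 ~ 4L, TRUE ~ 5L)

    age_lo <- pnorm(params$age_range[1], params$age_mean, params$age_sd)
    age_hi <- pnorm(params$age_range[2], params$age_mean, params$age_sd)
    age <- qnorm(runif(n, age_lo, age_hi), params$age_mean, params$age_sd)

    tibble::tibble(
      case_id = sprintf("case_%05d", seq_len(n)),
      age = round(age, 1),
      serum_psa = serum,
      prostate_volume = pv,
      gland_weight = NA_real_,
      total_tumour_volume = tv,
      index_tumour_volume = tv * runif(n, 0.75, 1),
      gleason_primary = gp,
      gleason_secondary = gs,
      stage = stage,
      epe = epe,
      svi = svi,
      positive_margins = margins,
      recurrence = event_time <= horizon,
      followup_time = pmin(event_time, horizon)
    )
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "censoring_horizon") <- horizon
  out
}

#' The planted androgen-responsive gene cassette
#'
#' Twenty-five genes commonly reported as androgen-responsive in benign
#' prostate epithelium, used as the down-regulated cassette of the expression
#' simulator.
#'
#' @return Character vector of 25 gene symbols.
#' @export
ar_cassette_genes <- function() {
  c("KLK3", "KLK2", "TMPRSS2", "NKX3-1", "FKBP5", "NDRG1", "PART1", "MSMB",
    "ACPP", "PLPP1", "ABCC4", "ELL2", "GNMT", "PMEPA1", "ZBTB16", "EAF2",
    "ORM1", "SLC45A3", "STEAP4", "CAMKK2", "HERC3", "PTGER4", "ADAM7",
    "MAF", "SORD")
}

#' Expression simulation parameters
#'
#' Multi-study Gaussian log-expression model with a planted down-regulated
#' gene cassette and up-regulated AR in the high-grade class; all other genes
#' are null.
#'
#' @param n_studies Number of independent studies (default 5).
#' @param n_genes Genes per study, including the cassette and AR
#'   (default 1000).
#' @param samples_per_class Samples in each of the two classes (default 20).
#' @param cassette Names of the down-regulated cassette (default
#'   [ar_cassette_genes()]).
#' @param lfc_cassette Planted log-fold-change of cassette genes in high
#'   grade (default -2, i.e. down).
#' @param ar_gene,lfc_ar The up-regulated gene and its planted LFC
#'   (defaults "AR", +1).
#' @param sigma Residual SD of log-expression (default 0.5).
#' @param baseline_mean,baseline_sd Per-gene baseline log-expression is drawn
#'   once per study from this normal (defaults 7, 1).
#' @return An object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_studies = 5, n_genes = 1000, samples_per_class = 20,
                                  cassette = ar_cassette_genes(), lfc_cassette = -2,
                                  ar_gene = "AR", lfc_ar = 1, sigma = 0.5,
                                  baseline_mean = 7, baseline_sd = 1) {
  if (n_studies < 1) stop_tpsad("`n_studies` must be >= 1.", "tpsad_validation_error")
  if (sigma <= 0) stop_tpsad("`sigma` must be > 0.", "tpsad_validation_error")
  if (n_genes < length(cassette) + 1) {
    stop_tpsad("`n_genes` must accommodate the cassette plus the AR gene.", "tpsad_validation_error")
  }
  if (samples_per_class < 2) stop_tpsad("`samples_per_class` must be >= 2.", "tpsad_validation_error")
  structure(list(n_studies = n_studies, n_genes = n_genes,
                 samples_per_class = samples_per_class, cassette = cassette,
                 lfc_cassette = lfc_cassette, ar_gene = ar_gene, lfc_ar = lfc_ar,
                 sigma = sigma, baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "expression_sim_params")
}

#' Simulate multi-study expression data
#'
#' @param params An [expression_sim_params()] object.
#' @param seed Optional integer seed.
#' @return A list of [expression_study()] objects.
#' @export
simulate_expression_studies <- function(params = expression_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "expression_sim_params"))
  gen <- function() {
    n_filler <- params$n_genes - length(params$cassette) - 1
    genes <- c(params$cassette, params$ar_gene,
               if (n_filler > 0) sprintf("gene_%04d", seq_len(n_filler)))
    shift <- stats::setNames(rep(0, params$n_genes), genes)
    shift[params$cassette] <- params$lfc_cassette
    shift[params$ar_gene] <- params$lfc_ar
    m <- params$samples_per_class
    labels <- rep(c("high_grade", "comparator"), each = m)
    purrr::map(seq_len(params$n_studies), function(i) {
      baseline <- rnorm(params$n_genes, params$baseline_mean, params$baseline_sd)
      mat <- baseline + matrix(rnorm(params$n_genes * 2 * m, 0, params$sigma),
                               nrow = params$n_genes)
      mat[, seq_len(m)] <- mat[, seq_len(m)] + shift
      dimnames(mat) <- list(genes, sprintf("s%d_%02d", i, seq_len(2 * m)))
      expression_study(sprintf("study_%d", i), mat, labels)
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a uniform-intensity DAB image patch
#'
#' Single-channel 8-bit image whose base intensity encodes a target optical
#' density (`255 * 10^-target_od`) with clipped Gaussian pixel noise.
#'
#' @param target_od Target optical density (>= 0). The implied base intensity
#'   must be >= 1 (8-bit representable).
#' @param noise_sd Pixel noise SD in intensity units (default 2).
#' @param size Side length in pixels (default 256).
#' @param seed Optional integer seed.
#' @return A `size x size` numeric matrix of 8-bit intensities.
#' @export
simulate_ihc_image <- function(target_od, noise_sd = 2, size = 256, seed = NULL) {
  check_numeric(target_od, "target_od", min = 0)
  base <- 255 * 10^(-target_od)
  if (base < 1) stop_tpsad("`target_od` too high for an 8-bit image (base intensity < 1).",
                           "tpsad_validation_error")
  gen <- function() {
    pmin(pmax(round(base + rnorm(size * size, 0, noise_sd)), 0), 255) |>
      matrix(size, size)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate an H-DAB RGB micrograph by forward stain synthesis
#'
#' Per-pixel haematoxylin and DAB absorbance amounts (target plus Gaussian
#' noise, clipped at 0) are combined through the stain basis and re-expressed
#' as 8-bit RGB, the exact forward model inverted by [hdab_deconvolve()].
#'
#' @param dab_od,hema_od Target per-pixel stain absorbances.
#' @param noise_sd SD of the per-pixel absorbance noise (default 0.02).
#' @param size Side length in pixels (default 256).
#' @param seed Optional integer seed.
#' @param vectors A [stain_vectors()] basis.
#' @return A `size x size x 3` array of 8-bit RGB intensities.
#' @export
simulate_ihc_rgb <- function(dab_od, hema_od = 0.3, noise_sd = 0.02, size = 256,
                             seed = NULL, vectors = stain_vectors()) {
  check_numeric(dab_od, "dab_od", min = 0)
  check_numeric(hema_od, "hema_od", min = 0)
  m <- unclass(vectors)
  gen <- function() {
    npix <- size * size
    a_h <- pmax(hema_od + rnorm(npix, 0, noise_sd), 0)
    a_d <- pmax(dab_od + rnorm(npix, 0, noise_sd), 0)
    A <- cbind(a_h, a_d, 0) %*% t(m)  # pixels x channels
    array(absorbance_to_intensity(A), dim = c(size, size, 3))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
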