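#' Constants of the serum-PSA deconvolution
#'
#' Bundles the physiological constants and cohort-eligibility cut-offs used
#' when attributing serum PSA to benign and malignant tissue.
#'
#' * `epithelial_fraction`: fraction of benign prostate volume that is
#'   PSA-secreting epithelium (default 0.1).
#' * `benign_secretion`: serum PSA (ng/ml) contributed per cc of benign
#'   epithelial tissue (default 0.30).
#' * `psa_exclusion_max`: pre-operative serum PSA above which a case is
#'   excluded, to limit the impact of occult metastatic disease (default 20).
#' * `gland_percentile_cut`: empirical gland-size percentile above which a
#'   case is excluded, to limit the impact of very large glands (default 95).
#'
#' @param epithelial_fraction Dimensionless, in (0, 1].
#' @param benign_secretion ng/ml serum PSA per cc of benign epithelium, >= 0.
#' @param psa_exclusion_max ng/ml.
#' @param gland_percentile_cut Percentile in (0, 100].
#'
#' @return An object of class `tpsad_constants` (a named list).
#' @export
tpsad_constants <- function(epithelial_fraction = 0.1,
                            benign_secretion = 0.30,
                            psa_exclusion_max = 20,
                            gland_percentile_cut = 95) {
  if (!is.numeric(epithelial_fraction) || epithelial_fraction < 0 || epithelial_fraction > 1) {
    stop_tpsad("`epithelial_fraction` must be in [0, 1].", "tpsad_validation_error")
  }
  check_numeric(benign_secretion, "benign_secretion", min = 0)
  check_numeric(psa_exclusion_max, "psa_exclusion_max", min = 0)
  if (gland_percentile_cut <= 0 || gland_percentile_cut > 100) {
    stop_tpsad("`gland_percentile_cut` must be in (0, 100].", "tpsad_validation_error")
  }
  structure(
    list(
      epithelial_fraction = epithelial_fraction,
      benign_secretion = benign_secretion,
      psa_exclusion_max = psa_exclusion_max,
      gland_percentile_cut = gland_percentile_cut
    ),
    class = "tpsad_constants"
  )
}

#' @export
print.tpsad_constants <- function(x, ...) {
  cat("tPSAD constants:\n")
  cat(sprintf("  epithelial fraction   %.3g\n", x$epithelial_fraction))
  cat(sprintf("  benign secretion      %.3g ng/ml per cc\n", x$benign_secretion))
  cat(sprintf("  PSA exclusion         > %.3g ng/ml\n", x$psa_exclusion_max))
  cat(sprintf("  gland size exclusion  > %.3g th percentile\n", x$gland_percentile_cut))
  invisible(x)
}

#' Benign prostate tissue volume
#'
#' Volume of the gland occupied by benign tissue: prostate volume minus tumour
#' volume, clamped at zero for the (rare) cases where tumour comprises the
#' whole gland.
#'
#' @param prostate_volume,tumour_volume Volumes in cc, non-negative. Vectorized.
#' @return Benign volume(s) in cc.
#' @export
benign_volume <- function(prostate_volume, tumour_volume) {
  check_numeric(prostate_volume, "prostate_volume", min = 0)
  check_numeric(tumour_volume, "tumour_volume", min = 0)
  pmax(prostate_volume - tumour_volume, 0)
}

#' Serum PSA attributable to benign tissue
#'
#' `epithelial_fraction * benign_secretion * benign_volume`: the expected
#' serum PSA contribution (ng/ml) of the non-malignant gland.
#'
#' @param benign_vol Benign tissue volume (cc), non-negative. Vectorized.
#' @param constants A [tpsad_constants()] object.
#' @return Benign PSA in ng/ml.
#' @export
benign_psa <- function(benign_vol, constants = tpsad_constants()) {
  check_numeric(benign_vol, "benign_vol", min = 0)
  stopifnot(inherits(constants, "tpsad_constants"))
  constants$epithelial_fraction * constants$benign_secretion * benign_vol
}

#' Serum PSA attributable to cancer
#'
#' Total serum PSA minus the estimated benign contribution. Values <= 0 (the
#' benign estimate exceeds the measured PSA) are returned unmodified; callers
#' treat them as non-log-transformable.
#'
#' @param serum_psa Measured serum PSA (ng/ml); missing values are an error.
#' @param benign Benign PSA (ng/ml) as from [benign_psa()].
#' @return Cancer-attributable PSA in ng/ml (may be <= 0).
#' @export
cancer_psa <- function(serum_psa, benign) {
  if (anyNA(serum_psa)) {
    stop_tpsad("`serum_psa` contains missing values; filter or impute before deconvolution.",
               "tpsad_missing_error")
  }
  check_numeric(serum_psa, "serum_psa")
  check_numeric(benign, "benign", min = 0)
  serum_psa - benign
}

#' Gleason grade group
#'
#' Groups Gleason scores into the three strata used throughout the analyses:
#' low (sum <= 6), intermediate (sum = 7), high (sum >= 8).
#'
#' @param gleason_primary,gleason_secondary Integer Gleason components, each
#'   in 3..5. Vectorized.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' grade_group(3, 4) # intermediate
#' @export
grade_group <- function(gleason_primary, gleason_secondary) {
  comp <- c(gleason_primary, gleason_secondary)
  if (anyNA(comp) || !all(comp %in% 3:5)) {
    stop_tpsad("Gleason components must be integers in 3..5.", "tpsad_validation_error")
  }
  gs <- gleason_primary + gleason_secondary
  factor(
    dplyr::case_when(gs <= 6 ~ "low", gs == 7 ~ "intermediate", TRUE ~ "high"),
    levels = c("low", "intermediate", "high")
  )
}

#' Compute tumour PSA density for a cohort
#'
#' The core statistic: serum PSA is deconvolved into a benign component
#' (epithelial fraction x secretion rate x benign volume) and a cancer
#' component (the remainder), and the cancer component is divided by the
#' pathological tumour volume, giving tumour PSA density (tPSAD, ng/ml per
#' cc). The natural log of tPSAD is reported where it is defined.
#'
#' Degenerate cases are retained and flagged rather than dropped:
#' `benign_volume_clamped` (tumour volume exceeded prostate volume),
#' `nonpositive_cancer_psa` (benign estimate at or above measured PSA; tPSAD
#' is reported but not log-transformable), `zero_tumour_volume` (tPSAD
#' undefined), `missing_serum_psa`, and `missing_index_volume` (when
#' `volume_field = "index"`).
#'
#' @param cohort Data frame with columns `case_id`, `serum_psa`,
#'   `prostate_volume`, `total_tumour_volume` (and `index_tumour_volume` when
#'   `volume_field = "index"`).
#' @param constants A [tpsad_constants()] object.
#' @param volume_field Which tumour volume to normalize by: `"total"`
#'   (default) or `"index"` (largest focus only).
#'
#' @return A tibble with one row per case: `case_id`, `tumour_volume`,
#'   `benign_volume`, `benign_psa`, `cancer_psa`, `tpsad`, `ln_tpsad`,
#'   `valid_for_log`, `flags` (semicolon-separated quality notes, empty when
#'   clean).
#' @export
compute_tpsad <- function(cohort, constants = tpsad_constants(),
                          volume_field = c("total", "index")) {
  volume_field <- match.arg(volume_field)
  vol_col <- if (volume_field == "total") "total_tumour_volume" else "index_tumour_volume"
  check_columns(cohort, c("case_id", "serum_psa", "prostate_volume", vol_col), "`cohort`")
  stopifnot(inherits(constants, "tpsad_constants"))

  tv <- cohort[[vol_col]]
  pv <- cohort$prostate_volume
  psa <- cohort$serum_psa
  check_numeric(pv, "prostate_volume", min = 0)
  check_numeric(tv[!is.na(tv)], vol_col, min = 0)

  missing_vol <- is.na(tv)
  missing_psa <- is.na(psa)
  bv <- pmax(pv - dplyr::coalesce(tv, 0), 0)
  clamped <- !missing_vol & (pv - tv) < 0
  bpsa <- benign_psa(bv, constants)
  cpsa <- psa - bpsa
  tpsad <- dplyr::if_else(!missing_vol & tv > 0, cpsa / tv, NA_real_)
  valid <- !is.na(tpsad) & tpsad > 0

  tibble::tibble(
    case_id = cohort$case_id,
    tumour_volume = tv,
    benign_volume = bv,
    benign_psa = bpsa,
    cancer_psa = cpsa,
    tpsad = tpsad,
    ln_tpsad = log(dplyr::if_else(valid, tpsad, NA_real_)),
    valid_for_log = valid,
    flags = paste_flags(
      dplyr::if_else(clamped, "benign_volume_clamped", ""),
      dplyr::if_else(!missing_psa & cpsa <= 0, "nonpositive_cancer_psa", ""),
      dplyr::if_else(!missing_vol & tv == 0, "zero_tumour_volume", ""),
      dplyr::if_else(missing_psa, "missing_serum_psa", ""),
      dplyr::if_else(missing_vol, paste0("missing_", volume_field, "_volume"), "")
    )
  )
}

#' Apply cohort eligibility filters
#'
#' Sequentially excludes, with first-match-wins attribution:
#' 1. cases with missing pre-operative serum PSA;
#' 2. cases with serum PSA above `psa_exclusion_max`;
#' 3. cases whose gland size lies strictly above the remaining cohort's
#'    empirical `gland_percentile_cut` percentile (linear interpolation
#'    between order statistics). Gland size is `gland_weight` (g) when the
#'    column is present and not entirely missing, otherwise
#'    `prostate_volume` (cc, taking 1 g ~ 1 cc).
#'
#' @param cohort Data frame with at least `serum_psa` and `prostate_volume`
#'   (optionally `gland_weight`).
#' @param constants A [tpsad_constants()] object.
#'
#' @return The kept rows as a tibble, with an `exclusions` attribute (a
#'   tibble with columns `rule` and `n_excluded`) retrievable via
#'   [exclusion_log()].
#' @export
apply_cohort_filters <- function(cohort, constants = tpsad_constants()) {
  check_columns(cohort, c("serum_psa", "prostate_volume"), "`cohort`")
  stopifnot(inherits(constants, "tpsad_constants"))
  if (nrow(cohort) == 0) stop_tpsad("`cohort` is empty.", "tpsad_validation_error")

  cohort <- tibble::as_tibble(cohort)
  n_missing <- sum(is.na(cohort$serum_psa))
  kept <- cohort[!is.na(cohort$serum_psa), , drop = FALSE]

  high_psa <- kept$serum_psa > constants$psa_exclusion_max
  n_psa <- sum(high_psa)
  kept <- kept[!high_psa, , drop = FALSE]

  gland <- if ("gland_weight" %in% names(kept) && !all(is.na(kept$gland_weight))) {
    dplyr::coalesce(kept$gland_weight, kept$prostate_volume)
  } else {
    kept$prostate_volume
  }
  n_gland <- 0L
  if (nrow(kept) > 0) {
    cut <- stats::quantile(gland, constants$gland_percentile_cut / 100, type = 7, names = FALSE)
    big <- gland > cut
    n_gland <- sum(big)
    kept <- kept[!big, , drop = FALSE]
  }

  if (nrow(kept) == 0) stop_tpsad("All cases were excluded by the eligibility filters.", "tpsad_empty_cohort")

  attr(kept, "exclusions") <- tibble::tibble(
    rule = c("missing_psa",
             sprintf("psa_above_%g", constants$psa_exclusion_max),
             sprintf("gland_above_p%g", constants$gland_percentile_cut)),
    n_excluded = c(n_missing, n_psa, n_gland)
  )
  kept
}

#' Exclusion log of a filtered cohort
#'
#' @param cohort A tibble returned by [apply_cohort_filters()].
#' @return A tibble with columns `rule` and `n_excluded`.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusions")
  if (is.null(log)) stop_tpsad("No exclusion log; was this cohort produced by apply_cohort_filters()?")
  log
}
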