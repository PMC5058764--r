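#' Tumour volume from serial whole-mount sections
#'
#' Cavalieri estimate of tumour volume from planimetric cross-sectional areas
#' measured on transverse whole-mount sections taken at a fixed interval from
#' prostate base to apex. A multiplicative correction compensates for
#' formalin-induced tissue shrinkage.
#'
#' The estimate treats every section as representing a full slab of thickness
#' equal to the sectioning interval, so the volume is
#' `sum(areas) * spacing * shrinkage_factor / 1000`, converting mm^3 to cc.
#' With `shrinkage_factor = 1` this is the plain Cavalieri sum.
#'
#' @param areas_mm2 Numeric vector of tumour cross-sectional areas (mm^2),
#'   ordered base to apex. All values must be non-negative.
#' @param spacing_mm Inter-section interval in mm (default 3.5).
#' @param shrinkage_factor Dimensionless multiplicative correction for fixation
#'   shrinkage (default 1.25). Must be >= 1.
#'
#' @return Tumour volume in cc (a single number).
#' @examples
#' cavalieri_volume(c(100, 200, 100)) # 1.75 cc
#' @export
cavalieri_volume <- function(areas_mm2, spacing_mm = 3.5, shrinkage_factor = 1.25) {
  check_numeric(areas_mm2, "areas_mm2", min = 0)
  check_numeric(spacing_mm, "spacing_mm")
  check_numeric(shrinkage_factor, "shrinkage_factor", min = 1)
  if (length(spacing_mm) != 1 || spacing_mm <= 0) {
    stop_tpsad("`spacing_mm` must be a single positive number.", "tpsad_validation_error")
  }
  sum(areas_mm2) * spacing_mm * shrinkage_factor / 1000
}

#' Per-case tumour volumes from a section table
#'
#' Applies [cavalieri_volume()] to a long table of section areas, one row per
#' whole-mount section.
#'
#' @param sections Data frame with columns `case_id` and `area_mm2` (and
#'   optionally `section_index`, ignored beyond ordering).
#' @inheritParams cavalieri_volume
#'
#' @return A tibble with one row per case: `case_id`, `n_sections`,
#'   `tumour_volume_cc`.
#' @export
tumour_volumes <- function(sections, spacing_mm = 3.5, shrinkage_factor = 1.25) {
  check_columns(sections, c("case_id", "area_mm2"), "`sections`")
  sections |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      tumour_volume_cc = cavalieri_volume(.data$area_mm2, spacing_mm, shrinkage_factor),
      .groups = "drop"
    )
}

#' Read a section-area table (TSV)
#'
#' One row per section with columns `case_id`, `section_index`, `area_mm2`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of sections.
#' @export
read_sections_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("case_id", "area_mm2"), "section table")
  x
}

#' Prostate gland volume by the ellipsoid formula
#'
#' Gland volume from three orthogonal calliper dimensions using
#' `pi/6 * L * W * H` (the prolate-ellipsoid approximation routinely used for
#' the prostate; dimensions in cm give volume in cc).
#'
#' @param length_cm,width_cm,height_cm Orthogonal gland dimensions (cm),
#'   non-negative. Vectorized.
#' @return Gland volume(s) in cc.
#' @examples
#' ellipsoid_volume(6, 5, 4) # 62.83 cc
#' @export
ellipsoid_volume <- function(length_cm, width_cm, height_cm) {
  check_numeric(length_cm, "length_cm", min = 0)
  check_numeric(width_cm, "width_cm", min = 0)
  check_numeric(height_cm, "height_cm", min = 0)
  pi / 6 * length_cm * width_cm * height_cm
}
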