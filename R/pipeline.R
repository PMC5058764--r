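# End-to-end synthetic-cohort analysis: simulate -> filter -> tPSAD ->
# group comparisons -> quintile survival -> multivariable Cox ->
# expression meta-analysis -> IHC optical densitometry.

#' Default pipeline configuration
#'
#' A fully populated configuration list for [run_full_pipeline()]. Any subset
#' of keys can be overridden via [load_run_config()] or by editing the list.
#'
#' @return A named list: `n_patients`, `constants` (arguments to
#'   [tpsad_constants()]), `cohort` (overrides for [cohort_sim_params()]),
#'   `expression` (overrides for [expression_sim_params()]), `meta`
#'   (`n_perm`, `alpha`), `survival` (`covariates`), and `ihc` (group ODs and
#'   region-sampling settings).
#' @export
default_config <- function() {
  list(
    n_patients = 1108,
    constants = list(),
    cohort = list(),
    expression = list(),
    meta = list(n_perm = 2000, alpha = 0.05),
    survival = list(covariates = c("epe", "svi", "positive_margins",
                                   "grade_intermediate", "grade_high", "ln_tpsad")),
    ihc = list(low_grade_od = 0.8, high_grade_od = 0.5, n_images = 10,
               image_size = 256, noise_sd = 2, n_regions = 3, region_size = 64)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()] (recursively;
#' absent keys keep their defaults).
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_tpsad(sprintf("Config file '%s' not found.", path), "tpsad_io_error")
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

child_seed <- function(seed, i) as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)

#' Run the full synthetic-cohort analysis pipeline
#'
#' Composes every stage of the package on simulated data: a cohort is drawn
#' from the calibrated generative model, eligibility filters and the serum
#' PSA deconvolution are applied, ln(tPSAD) is compared across grade, stage
#' and recurrence groups, recurrence-free survival is analysed by ln(tPSAD)
#' quintile (Kaplan-Meier + log-rank) and by multivariable Cox regression,
#' the cross-study rank meta-analysis is run on simulated expression studies,
#' and DAB optical density is compared between simulated low- and high-grade
#' image groups.
#'
#' Identical `config` and `seed` give identical results; every output table
#' written to `out_dir` carries the seed and a config hash.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Integer seed; child seeds are derived per stage.
#' @param out_dir Optional directory for TSV outputs.
#' @return An object of class `tpsad_report`: a list with elements `cohort`,
#'   `exclusions`, `tpsad` (the analysis table), `comparisons`, `quintile_km`
#'   (list of [km_curve()] by stratum), `logrank`, `cox`, `meta`,
#'   `meta_summary`, `ihc`, and `run_log`.
#' @export
run_full_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL) {
  if (length(seed) != 1 || is.na(seed)) stop_tpsad("`seed` must be a single integer.", "tpsad_validation_error")
  stage <- "configuration"
  result <- tryCatch({
    constants <- do.call(tpsad_constants, config$constants)
    params <- do.call(cohort_sim_params,
                      utils::modifyList(config$cohort, list(constants = constants)))

    stage <- "cohort simulation"
    cohort <- simulate_cohort(config$n_patients, params, seed = child_seed(seed, 1))

    stage <- "eligibility filtering"
    kept <- apply_cohort_filters(cohort, constants)
    exclusions <- exclusion_log(kept)

    stage <- "tPSAD computation"
    res <- compute_tpsad(kept, constants)
    tab <- dplyr::bind_cols(
      kept[setdiff(names(kept), "case_id")], res
    ) |>
      dplyr::mutate(
        grade = grade_group(.data$gleason_primary, .data$gleason_secondary),
        grade_intermediate = as.numeric(.data$grade == "intermediate"),
        grade_high = as.numeric(.data$grade == "high")
      ) |>
      dplyr::relocate("case_id")

    stage <- "group comparisons"
    logt <- tab[tab$valid_for_log, , drop = FALSE]
    comparisons <- dplyr::bind_rows(
      dplyr::mutate(group_compare(logt, ln_tpsad, grade, "anova"),
                    contrast = "ln(tPSAD) by grade", .before = 1),
      dplyr::mutate(group_compare(logt, ln_tpsad, stage, "ttest"),
                    contrast = "ln(tPSAD) by stage", .before = 1),
      dplyr::mutate(group_compare(logt, ln_tpsad, recurrence, "ttest"),
                    contrast = "ln(tPSAD) by recurrence", .before = 1)
    )

    stage <- "quintile survival"
    logt$tpsad_quintile <- quintile_strata(logt$ln_tpsad)
    quintile_km <- lapply(split(logt, logt$tpsad_quintile), function(d) {
      km_curve(d, followup_time, recurrence)
    })
    logrank <- logrank_test(logt, followup_time, recurrence, tpsad_quintile)

    stage <- "Cox regression"
    cox <- cox_fit(logt, config$survival$covariates,
                   time = followup_time, event = recurrence)

    stage <- "expression meta-analysis"
    expr_params <- do.call(expression_sim_params, config$expression)
    studies <- simulate_expression_studies(expr_params, seed = child_seed(seed, 2))
    meta <- meta_rank_enrichment(studies,
                                 genes = c(expr_params$cassette, expr_params$ar_gene),
                                 n_perm = config$meta$n_perm,
                                 seed = child_seed(seed, 3))
    meta_summary <- geneset_direction_summary(meta, config$meta$alpha)

    stage <- "IHC densitometry"
    ihc_cfg <- config$ihc
    measure_group <- function(od, group, seed0) {
      purrr::map_dfr(seq_len(ihc_cfg$n_images), function(i) {
        img <- simulate_ihc_image(od, ihc_cfg$noise_sd, ihc_cfg$image_size,
                                  seed = child_seed(seed0, i))
        s <- sample_region_ods(img, ihc_cfg$n_regions, ihc_cfg$region_size,
                               seed = child_seed(seed0, 1000 + i))
        tibble::tibble(group = group, image = i, mean_od = s$mean_od)
      })
    }
    ods <- dplyr::bind_rows(
      measure_group(ihc_cfg$low_grade_od, "low_grade", child_seed(seed, 4)),
      measure_group(ihc_cfg$high_grade_od, "high_grade", child_seed(seed, 5))
    )
    ihc <- list(ods = ods,
                comparison = group_compare(ods, mean_od, group, "ttest"))

    run_log <- list(
      package_version = as.character(utils::packageVersion("tpsad")),
      seed = seed,
      config_hash = rlang::hash(config),
      censoring_horizon_months = attr(cohort, "censoring_horizon"),
      n_simulated = nrow(cohort),
      n_analysed = nrow(tab),
      exclusions = exclusions
    )

    structure(list(cohort = cohort, exclusions = exclusions, tpsad = tab,
                   comparisons = comparisons, quintile_km = quintile_km,
                   logrank = logrank, cox = cox, meta = meta,
                   meta_summary = meta_summary, ihc = ihc, run_log = run_log),
              class = "tpsad_report")
  }, error = function(e) {
    stop_tpsad(sprintf("Pipeline failed during %s: %s", stage, conditionMessage(e)),
               "tpsad_pipeline_error")
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- result$run_log$config_hash
    write_table(result$tpsad, file.path(out_dir, "tpsad_table.tsv"), seed, h)
    write_table(result$exclusions, file.path(out_dir, "exclusions.tsv"), seed, h)
    write_table(result$comparisons, file.path(out_dir, "group_comparisons.tsv"), seed, h)
    write_table(tidy(result$cox), file.path(out_dir, "cox_fit.tsv"), seed, h)
    km_tab <- purrr::imap_dfr(result$quintile_km, function(km, q) {
      dplyr::mutate(tidy(km), quintile = q, .before = 1)
    })
    write_table(km_tab, file.path(out_dir, "km_by_quintile.tsv"), seed, h)
    write_table(result$meta, file.path(out_dir, "meta_analysis.tsv"), seed, h)
    write_table(result$ihc$ods, file.path(out_dir, "ihc_ods.tsv"), seed, h)
    yaml::write_yaml(result$run_log[names(result$run_log) != "exclusions"],
                     file.path(out_dir, "run_log.yaml"))
  }
  result
}

#' @export
print.tpsad_report <- function(x, ...) {
  cat("tPSAD pipeline report\n")
  cat(sprintf("  cohort: %d simulated, %d analysed (seed %s)\n",
              x$run_log$n_simulated, x$run_log$n_analysed, x$run_log$seed))
  cat("  exclusions:\n")
  for (i in seq_len(nrow(x$exclusions))) {
    cat(sprintf("    %-20s %d\n", x$exclusions$rule[i], x$exclusions$n_excluded[i]))
  }
  cat("  group comparisons (p-values):\n")
  for (i in seq_len(nrow(x$comparisons))) {
    cat(sprintf("    %-26s p = %.3g\n", x$comparisons$contrast[i], x$comparisons$p_value[i]))
  }
  cat(sprintf("  log-rank across ln(tPSAD) quintiles: chi2 = %.3g, p = %.3g\n",
              x$logrank$statistic, x$logrank$p_value))
  cat("  Cox hazard ratios:\n")
  co <- x$cox$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("    %-18s HR %.2f (%.2f-%.2f)\n", co$term[i], co$hazard_ratio[i],
                co$conf_low[i], co$conf_high[i]))
  }
  cat(sprintf("  meta-analysis: %d/%d genes down-significant, %d up-significant\n",
              x$meta_summary$n_down_significant, x$meta_summary$n_total,
              x$meta_summary$n_up_significant))
  cat(sprintf("  IHC: mean OD %.3f (low grade) vs %.3f (high grade), p = %.3g\n",
              mean(x$ihc$ods$mean_od[x$ihc$ods$group == "low_grade"]),
              mean(x$ihc$ods$mean_od[x$ihc$ods$group == "high_grade"]),
              x$ihc$comparison$p_value))
  invisible(x)
}
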