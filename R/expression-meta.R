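#' Expression study container
#'
#' A genes-by-samples expression matrix with a binary grade label per sample,
#' the unit of the cross-study rank meta-analysis. The highest-Gleason group
#' within each study is the `high_grade` class; all remaining tumours act as
#' the `comparator`.
#'
#' @param study_id Character scalar identifying the study.
#' @param values Numeric matrix, genes in rows (unique rownames required),
#'   samples in columns. Assumed log-scale for the t-test path.
#' @param labels Character/factor vector, one per column, with values
#'   `"high_grade"` or `"comparator"`; each class needs >= 2 samples.
#' @param scale Either `"log"` (default) or `"counts"`, declaring how
#'   `values` are to be read.
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(study_id, values, labels, scale = c("log", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_tpsad("`values` must be a numeric matrix.", "tpsad_validation_error")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_tpsad("`values` must have unique gene rownames.", "tpsad_validation_error")
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop_tpsad("`labels` must have one entry per sample column.", "tpsad_validation_error")
  }
  if (!all(labels %in% c("high_grade", "comparator"))) {
    stop_tpsad('`labels` values must be "high_grade" or "comparator".', "tpsad_validation_error")
  }
  if (any(table(factor(labels, c("high_grade", "comparator"))) < 2)) {
    stop_tpsad("Each class needs at least 2 samples.", "tpsad_validation_error")
  }
  structure(list(study_id = study_id, values = values, labels = labels, scale = scale),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s': %d genes x %d samples (%d high_grade / %d comparator), %s scale>\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$labels == "high_grade"), sum(x$labels == "comparator"), x$scale))
  invisible(x)
}

#' Counts per million
#'
#' Library-size normalization of a raw count matrix: each count divided by
#' its sample's total, times 1e6.
#'
#' @param counts Non-negative numeric matrix, genes in rows, samples in
#'   columns. Every column sum must be positive.
#' @return A CPM matrix of the same shape.
#' @export
cpm <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_tpsad("`counts` must be a numeric matrix.", "tpsad_validation_error")
  }
  check_numeric(as.vector(counts), "counts", min = 0)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_tpsad("Every library (column sum) must be positive.", "tpsad_validation_error")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Low-expression gene filter
#'
#' Removes genes whose CPM falls below a threshold in more than a given
#' fraction of samples (default: CPM < 1 in more than a third of samples),
#' to avoid spurious tests on barely expressed genes.
#'
#' @param counts Count matrix, genes in rows.
#' @param cpm_threshold CPM below which a sample counts as "low" (default 1).
#' @param max_low_fraction A gene is kept iff its fraction of low samples is
#'   `<=` this value (default 1/3; strictly more than a third removes).
#' @return Character vector of kept gene names (row indices if unnamed).
#' @export
cpm_filter <- function(counts, cpm_threshold = 1, max_low_fraction = 1/3) {
  mat <- cpm(counts)
  low_frac <- rowMeans(mat < cpm_threshold)
  keep <- low_frac <= max_low_fraction
  if (is.null(rownames(counts))) which(keep) else rownames(counts)[keep]
}

#' TMM normalization factors
#'
#' Per-sample scaling factors by the trimmed mean of M-values: pairwise
#' log-ratios against a reference sample are doubly trimmed (by log-ratio and
#' by absolute intensity) and averaged with precision weights; factors are
#' rescaled to have geometric mean 1. Computation is delegated to
#' `edgeR::calcNormFactors()`.
#'
#' @param counts Count matrix with >= 2 samples.
#' @param ref_sample Optional reference column (index or name); by default the
#'   sample whose upper quartile is closest to the mean upper quartile.
#' @param logratio_trim Fraction trimmed from each tail of the M-values
#'   (default 0.3).
#' @param abs_trim Fraction trimmed by absolute expression (default 0.05).
#' @return Named numeric vector of factors, one per sample, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, logratio_trim = 0.3, abs_trim = 0.05) {
  if (!is.matrix(counts) || ncol(counts) < 2) {
    stop_tpsad("`counts` must be a matrix with at least 2 samples.", "tpsad_validation_error")
  }
  if (any(colSums(counts) <= 0)) stop_tpsad("Every library must be positive.", "tpsad_validation_error")
  ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else ref_sample
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = logratio_trim, sumTrim = abs_trim)
  if (any(!is.finite(f))) {
    warn("No genes survived trimming for at least one sample; its factor is set to 1.")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  stats::setNames(f, colnames(counts))
}

#' Per-gene differential-expression p-values within one study
#'
#' Classical pooled-variance two-sample t-test of high-grade vs comparator
#' for every gene, reported as one-sided p-values in both directions
#' (`p_up`: higher in high grade; `p_down`: lower in high grade). For a
#' continuous statistic `p_up + p_down = 1`. Genes with zero pooled variance
#' are flagged; when the class means are also equal both p-values are 1.
#'
#' @param study An [expression_study()] with log-scale values.
#' @param welch Use Welch's unequal-variance t instead of the pooled
#'   (classical Student) test. Default `FALSE`.
#' @return A tibble: `gene`, `mean_high`, `mean_comparator`, `statistic`,
#'   `df`, `p_up`, `p_down`, `zero_variance`.
#' @export
study_de_pvalues <- function(study, welch = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  x <- study$values
  hi <- study$labels == "high_grade"
  n1 <- sum(hi); n2 <- sum(!hi)
  m1 <- rowMeans(x[, hi, drop = FALSE])
  m2 <- rowMeans(x[, !hi, drop = FALSE])
  v1 <- rowSums((x[, hi, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, !hi, drop = FALSE] - m2)^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  }
  diff <- m1 - m2
  zero_var <- se == 0
  t <- ifelse(zero_var, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p_up <- ifelse(zero_var & diff == 0, 1, stats::pt(t, df, lower.tail = FALSE))
  p_down <- ifelse(zero_var & diff == 0, 1, stats::pt(t, df, lower.tail = TRUE))
  tibble::tibble(
    gene = rownames(x), mean_high = unname(m1), mean_comparator = unname(m2),
    statistic = unname(t), df = unname(df), p_up = unname(p_up),
    p_down = unname(p_down), zero_variance = unname(zero_var)
  )
}

# per-study direction-specific percentile ranks (rank / n_genes, average ties)
study_percentiles <- function(studies, welch = FALSE) {
  purrr::map(studies, function(s) {
    de <- study_de_pvalues(s, welch = welch)
    n <- nrow(de)
    tibble::tibble(
      study_id = s$study_id, gene = de$gene, n_genes = n,
      rank_up = rank(de$p_up, ties.method = "average"),
      rank_down = rank(de$p_down, ties.method = "average")
    ) |>
      dplyr::mutate(pct_up = .data$rank_up / n, pct_down = .data$rank_down / n)
  }) |>
    purrr::list_rbind()
}

#' Cross-study rank meta-analysis of differential expression
#'
#' For each gene, its one-sided differential-expression p-value is ranked
#' within every study carrying it (rank 1 = most significant; ties get
#' average ranks), ranks are rescaled to percentiles (rank / n_genes) so that
#' platforms of different size are comparable, and the per-study percentiles
#' are summarised by their median. Significance of the observed summary is
#' assessed against a permutation null: `n_perm` draws of independent
#' Uniform(0, 1) percentiles, one per study, summarised the same way; the
#' p-value is the smoothed fraction `(# null <= observed + 1) / (n_perm + 1)`.
#' Both directions (up- and down-regulated in high grade) are reported.
#'
#' @param studies List of [expression_study()] objects.
#' @param genes Genes to test; default all genes present in >= 1 study. A
#'   requested gene present in no study is an error.
#' @param n_perm Number of permutation draws (>= 100).
#' @param seed Optional integer seed for the permutation null.
#' @param summary_fun Summary of per-study percentiles: `"median"` (default)
#'   or `"mean"`.
#' @param welch Passed to [study_de_pvalues()].
#'
#' @return A tibble with one row per gene: `gene`, `n_studies`, list-columns
#'   `rank_up`, `rank_down`, `n_genes_per_study`, the summary percentiles
#'   `summary_pct_up`, `summary_pct_down`, and permutation p-values
#'   `perm_p_up`, `perm_p_down`.
#' @export
meta_rank_enrichment <- function(studies, genes = NULL, n_perm = 10000, seed = NULL,
                                 summary_fun = c("median", "mean"), welch = FALSE) {
  summary_fun <- match.arg(summary_fun)
  if (n_perm < 100) stop_tpsad("`n_perm` must be >= 100 (the null is unstable below that).",
                               "tpsad_validation_error")
  if (!length(studies)) stop_tpsad("`studies` is empty.", "tpsad_validation_error")
  sfun <- if (summary_fun == "median") stats::median else mean

  pct <- study_percentiles(studies, welch = welch)
  if (is.null(genes)) genes <- unique(pct$gene)
  missing <- setdiff(genes, pct$gene)
  if (length(missing)) {
    stop_tpsad(sprintf("Gene(s) absent from every study: %s.",
                       paste(head(missing, 5), collapse = ", ")), "tpsad_validation_error")
  }
  pct <- pct[pct$gene %in% genes, , drop = FALSE]

  compute <- function() {
    # one shared null sample of the summary statistic per distinct study count
    ks <- sort(unique(table(pct$gene)))
    null_by_k <- lapply(stats::setNames(ks, ks), function(k) {
      draws <- matrix(runif(n_perm * k), nrow = k)
      if (k == 1) as.vector(draws) else apply(draws, 2, sfun)
    })
    pct |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        n_studies = dplyr::n(),
        rank_up = list(stats::setNames(.data$rank_up, .data$study_id)),
        rank_down = list(stats::setNames(.data$rank_down, .data$study_id)),
        n_genes_per_study = list(stats::setNames(.data$n_genes, .data$study_id)),
        summary_pct_up = sfun(.data$pct_up),
        summary_pct_down = sfun(.data$pct_down),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        perm_p_up = purrr::map2_dbl(.data$n_studies, .data$summary_pct_up, function(k, obs) {
          (sum(null_by_k[[as.character(k)]] <= obs) + 1) / (n_perm + 1)
        }),
        perm_p_down = purrr::map2_dbl(.data$n_studies, .data$summary_pct_down, function(k, obs) {
          (sum(null_by_k[[as.character(k)]] <= obs) + 1) / (n_perm + 1)
        })
      ) |>
      dplyr::arrange(match(.data$gene, genes))
  }
  if (is.null(seed)) compute() else withr::with_seed(seed, compute())
}

#' Tally significant genes per direction
#'
#' Counts how many genes of a meta-analysis result reach a permutation
#' p-value below `alpha` in each direction.
#'
#' @param results Tibble from [meta_rank_enrichment()].
#' @param alpha Significance threshold (default 0.05).
#' @return A one-row tibble: `n_down_significant`, `n_up_significant`,
#'   `n_total`.
#' @export
geneset_direction_summary <- function(results, alpha = 0.05) {
  check_columns(results, c("perm_p_up", "perm_p_down"), "`results`")
  if (nrow(results) == 0) stop_tpsad("`results` is empty.", "tpsad_validation_error")
  tibble::tibble(
    n_down_significant = sum(results$perm_p_down < alpha),
    n_up_significant = sum(results$perm_p_up < alpha),
    n_total = nrow(results)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin validating wrapper around
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  check_numeric(pvalues, "pvalues")
  if (any(pvalues < 0 | pvalues > 1)) {
    stop_tpsad("`pvalues` must lie in [0, 1].", "tpsad_validation_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}
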