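toy_counts <- function() {
  m <- matrix(c(10, 990e3, 4, 0,
                20, 1999976, 4, 0), ncol = 2,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
  m[1, 1] <- 10; m[2, 1] <- 1e6 - 14; m[3, 1] <- 4; m[4, 1] <- 0
  m[1, 2] <- 20; m[2, 2] <- 2e6 - 24; m[3, 2] <- 4; m[4, 2] <- 0
  m
}

test_that("CPM normalizes by library size and preserves proportions", {
  m <- toy_counts() # libraries are exactly 1e6 and 2e6
  cm <- cpm(m)
  expect_equal(cm["g1", "s1"], 10)
  expect_equal(cm["g3", "s2"], 2)
  expect_equal(cm["g4", ], c(s1 = 0, s2 = 0))
  expect_equal(unname(colSums(cm)), c(1e6, 1e6))
  expect_error(cpm(matrix(0, 2, 2)), class = "tpsad_validation_error")
})

test_that("CPM filter removes genes low in strictly more than a third of samples", {
  m <- matrix(10, nrow = 3, ncol = 3, dimnames = list(c("ok", "boundary", "low"), NULL))
  m <- m * 1e5 # library comfortably large
  # per-sample libraries ~3e6; CPM threshold 1 corresponds to count ~3
  m["boundary", 1] <- 0   # low in exactly 1/3 of samples -> kept
  m["low", 1:2] <- 0      # low in 2/3 -> removed
  kept <- cpm_filter(m)
  expect_setequal(kept, c("ok", "boundary"))
})

test_that("TMM factors match the brute-force trimmed-mean oracle", {
  withr::with_seed(41, {
    base <- rpois(1000, lambda = 200)
    counts <- cbind(A = base + rpois(1000, 20), B = base + rpois(1000, 20))
    # identical composition -> both factors 1 (up to trim noise)
    expect_equal(unname(tmm_factors(counts)), c(1, 1), tolerance = 5e-3)
    # doubling a library leaves all M-values at zero
    counts2 <- cbind(A = base, B = 2L * base)
    expect_equal(unname(tmm_factors(counts2)), c(1, 1))

    # asymmetric composition: 50 genes 10-fold up in B only
    counts3 <- counts
    counts3[1:50, "B"] <- counts3[1:50, "B"] * 10L
    f <- tmm_factors(counts3, ref_sample = 1)
    expect_lt(f[["B"]], f[["A"]])
    oracle <- tmm_oracle(counts3, ref = 1)
    expect_equal(unname(f), unname(oracle), tolerance = 1e-6)
    # geometric mean 1; scaling a library leaves the factors essentially
    # unchanged (exactly invariant M-values; the precision weights shift a
    # little because they depend on the raw counts)
    expect_equal(exp(mean(log(f))), 1)
    counts4 <- counts3; counts4[, "A"] <- counts4[, "A"] * 7L
    expect_equal(unname(tmm_factors(counts4, ref_sample = 1)), unname(f),
                 tolerance = 1e-3)
  })
})

make_study <- function(id, mat, n_high) {
  expression_study(id, mat, rep(c("high_grade", "comparator"),
                                c(n_high, ncol(mat) - n_high)))
}

test_that("study t-test p-values behave under null, shift and sign flip", {
  withr::with_seed(42, {
    n <- 30
    mat <- matrix(rnorm(200 * 2 * n), nrow = 200,
                  dimnames = list(sprintf("g%03d", 1:200), NULL))
    mat["g001", 1:n] <- mat["g001", 1:n] + 3 # strongly up in high grade
    st <- make_study("s", mat, n)
    de <- study_de_pvalues(st)
    expect_lt(de$p_up[de$gene == "g001"], 1e-3)
    # one-sided halves sum to one and the null is centred
    expect_equal(de$p_up + de$p_down, rep(1, 200))
    expect_equal(mean(de$p_up[-1]), 0.5, tolerance = 0.05)
    # sign symmetry: p_up on X equals p_down on -X
    de_neg <- study_de_pvalues(make_study("s", -mat, n))
    expect_equal(de$p_up, de_neg$p_down)
  })
})

test_that("zero-variance genes are flagged with p = 1 in both directions", {
  mat <- matrix(5, nrow = 2, ncol = 8, dimnames = list(c("flat", "split"), NULL))
  mat["split", 1:4] <- 9
  de <- study_de_pvalues(make_study("s", mat, 4))
  expect_true(all(de$zero_variance))
  expect_equal(de$p_up[de$gene == "flat"], 1)
  expect_equal(de$p_down[de$gene == "flat"], 1)
  expect_equal(de$p_up[de$gene == "split"], 0) # separated means, zero variance
})

test_that("a top-ranked gene in a single study gets its percentile as permutation p", {
  withr::with_seed(43, {
    mat <- matrix(rnorm(100 * 20, mean = 7), nrow = 100,
                  dimnames = list(sprintf("g%03d", 1:100), NULL))
    mat["g001", 1:10] <- mat["g001", 1:10] - 5 # clearly the most significant, down
    st <- make_study("s1", mat, 10)
    res <- meta_rank_enrichment(list(st), genes = "g001", n_perm = 20000, seed = 7)
    expect_equal(res$rank_down[[1]][["s1"]], 1)
    expect_equal(res$summary_pct_down, 0.01)
    expect_equal(res$perm_p_down, 0.01, tolerance = 0.15) # MC error at p ~ 1e-2
    expect_gt(res$perm_p_up, 0.9)
  })
})

test_that("permutation p matches the exact median-of-uniforms null across genes", {
  withr::with_seed(44, {
    studies <- lapply(1:3, function(i) {
      mat <- matrix(rnorm(150 * 16, mean = 7), nrow = 150,
                    dimnames = list(sprintf("g%03d", 1:150), NULL))
      mat[1:4, 1:8] <- mat[1:4, 1:8] - seq(2, 0.5, length.out = 4)
      make_study(sprintf("s%d", i), mat, 8)
    })
    res <- meta_rank_enrichment(studies, n_perm = 200000, seed = 9)
    exact <- median_uniform_cdf_odd(res$summary_pct_down, k = 3)
    expect_lt(max(abs(res$perm_p_down - exact)), 0.005)
    # a gene sitting at the null centre has p near 0.5
    mid <- which.min(abs(res$summary_pct_down - 0.5))
    expect_equal(res$perm_p_down[mid], 0.5, tolerance = 0.06)
  })
})

test_that("down-enrichment on X equals up-enrichment on -X under a shared seed", {
  withr::with_seed(45, {
    studies <- lapply(1:3, function(i) {
      mat <- matrix(rnorm(80 * 12, mean = 7), nrow = 80,
                    dimnames = list(sprintf("g%02d", 1:80), NULL))
      make_study(sprintf("s%d", i), mat, 6)
    })
    neg <- lapply(studies, function(s) {
      expression_study(s$study_id, -s$values, s$labels)
    })
    a <- meta_rank_enrichment(studies, n_perm = 500, seed = 99)
    b <- meta_rank_enrichment(neg, n_perm = 500, seed = 99)
    expect_equal(a$perm_p_down, b$perm_p_up)
    expect_equal(a$rank_down, b$rank_up)
  })
})

test_that("meta-analysis input contracts are enforced", {
  st <- make_study("s", matrix(rnorm(40), 10, 4,
                               dimnames = list(letters[1:10], NULL)), 2)
  expect_error(meta_rank_enrichment(list(st), n_perm = 50), class = "tpsad_validation_error")
  expect_error(meta_rank_enrichment(list(st), genes = "zzz", n_perm = 200),
               class = "tpsad_validation_error")
  expect_error(expression_study("s", matrix(rnorm(8), 2, 4,
                                            dimnames = list(c("a", "a"), NULL)),
                                rep(c("high_grade", "comparator"), 2)),
               class = "tpsad_validation_error")
})

test_that("a strongly planted cassette is called down-significant in every gene", {
  params <- expression_sim_params(n_studies = 5, n_genes = 300, samples_per_class = 20,
                                  lfc_cassette = -2, sigma = 0.5)
  studies <- simulate_expression_studies(params, seed = 46)
  res <- meta_rank_enrichment(studies, genes = c(params$cassette, "AR"),
                              n_perm = 2000, seed = 47)
  summ <- geneset_direction_summary(res[res$gene %in% params$cassette, ], alpha = 0.05)
  expect_equal(summ$n_down_significant, 25L)
  expect_equal(summ$n_total, 25L)
  # AR is planted up, not down
  expect_lt(res$perm_p_up[res$gene == "AR"], 0.05)
  # alpha = 0 can never call anything
  expect_equal(geneset_direction_summary(res, alpha = 0)$n_down_significant, 0L)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(48, {
    p <- runif(100)
    q <- bh_fdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), class = "tpsad_validation_error")
})
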