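test_that("site filtering applies the four exclusion rules at their boundaries", {
  rows <- make_site_rows(
    n = 6L,
    localization_prob = c(0.74, 0.75, 0.95, 0.95, 0.95, 0.95),
    is_contaminant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    is_reverse = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  # row 5: four zeros (rejected); row 6: exactly three zeros (kept)
  for (j in 1:4) rows[[paste0("reporter_intensity_", j)]][5] <- 0
  for (j in 1:3) rows[[paste0("reporter_intensity_", j)]][6] <- 0

  flt <- filter_sites(rows)
  expect_setequal(flt$kept$site_id, c("s002", "s006"))
  expect_equal(nrow(flt$rejected), 4L)
  reasons <- setNames(flt$rejected$reason, flt$rejected$site_id)
  expect_match(reasons[["s001"]], "localization")
  expect_match(reasons[["s003"]], "contaminant")
  expect_match(reasons[["s004"]], "reversed")
  expect_match(reasons[["s005"]], "zero channels")

  expect_error(filter_sites(rows, n_channels = 10L), "channels")
})

test_that("hand-built five-row fixture keeps exactly the two clean rows", {
  rows <- make_site_rows(
    n = 5L,
    localization_prob = c(0.95, 0.5, 0.95, 0.95, 0.95),
    is_contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    is_reverse = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  flt <- filter_sites(rows)
  expect_equal(nrow(flt$kept), 2L)
})

test_that("imputation replaces zeros by the channel-wise nonzero minimum", {
  rows <- make_site_rows(n = 2L, intensities = rbind(
    c(100, 200, 300, 400, 500, 600),
    c(0,   400, 150, 800, 500, 600)
  ))
  sm <- impute_missing(rows, default_design())
  expect_equal(sm$values[2, 1], log2(100))   # imputed at the channel min

  # no zeros: identity up to the log2 transform
  rows2 <- make_site_rows(n = 3L)
  sm2 <- impute_missing(rows2, default_design())
  expect_equal(sm2$values,
               log2(as.matrix(rows2[paste0("reporter_intensity_", 1:6)])),
               ignore_attr = TRUE)

  # a channel with no nonzero value cannot be imputed
  rows3 <- make_site_rows(n = 2L)
  rows3$reporter_intensity_2 <- 0
  expect_error(impute_missing(rows3, default_design()), "impute")
})

test_that("randomized imputation agrees with a brute-force column scan", {
  set.seed(8)
  for (rep in 1:10) {
    x <- matrix(round(runif(60, 10, 1000)), nrow = 10)
    x[sample(60, 12)] <- 0
    if (any(colSums(x > 0) == 0)) next
    rows <- make_site_rows(n = 10L, intensities = x)
    sm <- impute_missing(rows, default_design())
    manual <- x
    for (j in 1:6) manual[manual[, j] == 0, j] <- min(x[x[, j] > 0, j])
    expect_equal(sm$values, log2(manual), ignore_attr = TRUE)
  }
})

test_that("median polish matches the hand-executed 3x3 oracle", {
  m <- matrix(1:9, nrow = 3, byrow = TRUE)
  mp <- median_polish(m, max_iter = 3L)
  # hand sweep: row medians (2,5,8) -> overall 5, rows (-3,0,3);
  # column medians of the residuals (-1,0,1); residuals vanish
  expect_equal(mp$overall, 5)
  expect_equal(unname(mp$col), c(-1, 0, 1))
  expect_equal(unname(mp$row), c(-3, 0, 3))
  expect_true(all(abs(mp$residuals) < 1e-12))
})

test_that("median polish reconstructs the input and clears medians", {
  set.seed(4)
  x <- matrix(rnorm(200), nrow = 20)
  mp <- median_polish(x, max_iter = 50L)
  recon <- mp$overall + outer(mp$row, mp$col, "+") + mp$residuals
  expect_equal(recon, x, tolerance = 1e-9, ignore_attr = TRUE)
  # columns are swept last, so their medians vanish exactly; the row/column
  # alternation can settle in a fixed point where row medians stay small
  # but nonzero (even-count medians), so only near-zero is guaranteed there
  expect_true(all(abs(apply(mp$residuals, 2, median)) < 1e-9))
  expect_true(all(abs(apply(mp$residuals, 1, median)) < 1e-2))

  # an exactly additive matrix resolves in one iteration
  add <- 2 + outer(rnorm(6), rnorm(4), "+")
  mp2 <- median_polish(add, max_iter = 1L)
  expect_true(all(abs(mp2$residuals) < 1e-9))

  expect_error(median_polish(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("normalization removes channel loading and is idempotent", {
  set.seed(5)
  base <- matrix(rnorm(300, 10), nrow = 50)
  offsets <- c(-1, 0.5, 2, -0.3, 0.8, -2)
  x <- base[, rep(1, 6)] + matrix(offsets, 50, 6, byrow = TRUE)
  sm <- site_matrix(x, default_design())
  norm <- normalize_by_median_polish(sm)
  # pure per-channel offsets: all normalized columns identical
  expect_equal(norm$values, norm$values[, c(1, 1, 1, 1, 1, 1)],
               tolerance = 1e-9, ignore_attr = TRUE)

  norm2 <- normalize_by_median_polish(norm)
  expect_equal(norm2$values, norm$values, tolerance = 1e-6)
})

test_that("normalization recovers injected channel effects (noise-free)", {
  p <- truth_params(n_sites = 400L, n_regulated = 10L, noise_sd = 0,
                    channel_effect_sd = 0.5, compression_factor = 1,
                    missing_midpoint = -Inf, frac_contaminant = 0,
                    frac_reverse = 0, rng_seed = 3L)
  tr <- generate_ground_truth(p)
  tab <- simulate_tmt_experiment(tr)[[1]]
  sm <- impute_missing(tab, attr(tab, "design"))
  mp <- median_polish(sm$values, max_iter = 10L)
  est <- mp$col - mean(mp$col)
  inj <- tr$channel_effects[1, ] - mean(tr$channel_effects[1, ])
  # condition effects leak a constant into each condition block; compare
  # within-condition-centred profiles
  ctr <- function(v) c(v[1:3] - mean(v[1:3]), v[4:6] - mean(v[4:6]))
  expect_equal(ctr(unname(est)), ctr(unname(inj)), tolerance = 1e-6)
})

test_that("moderated t reduces to the ordinary t in the d0 -> 0 limit", {
  set.seed(6)
  n <- 40L
  x <- matrix(rnorm(n * 12, sd = rep(exp(rnorm(n, 0, 0.5)), 12)), nrow = n)
  design <- rbind(default_design(1L), default_design(2L))
  sm <- site_matrix(x, design)
  mod <- moderated_linear_test(sm, prior_df = 0)

  X <- model.matrix(~ factor(design$condition, c("EGTA", "Ca")) +
                      factor(design$batch))
  for (i in seq_len(n)) {
    fit <- lm(x[i, ] ~ X - 1)
    tt <- summary(fit)$coefficients[2, ]
    expect_equal(mod$log2FC[i], unname(tt["Estimate"]), tolerance = 1e-9)
    expect_equal(mod$statistic[i], unname(tt["t value"]), tolerance = 1e-9)
    expect_equal(mod$p[i], unname(tt["Pr(>|t|)"]), tolerance = 1e-9)
  }
})

test_that("the d0 -> Inf limit equalizes variances and preserves ordering", {
  set.seed(7)
  x <- matrix(rnorm(600), nrow = 50)
  sm <- site_matrix(x, rbind(default_design(1L), default_design(2L)))
  mod <- moderated_linear_test(sm, prior_df = Inf)
  expect_equal(length(unique(round(mod$s2_post, 12))), 1L)
  expect_equal(order(mod$statistic), order(mod$log2FC))
})

test_that("moderation agrees with the limma oracle on shared data", {
  skip_if_not_installed("limma")
  set.seed(9)
  n <- 200L
  sds <- sqrt(1 / rchisq(n, df = 5) * 5) * 0.5   # heterogeneous variances
  x <- matrix(rnorm(n * 12, sd = rep(sds, 12)), nrow = n)
  rownames(x) <- paste0("s", seq_len(n))
  design_df <- rbind(default_design(1L), default_design(2L))
  sm <- site_matrix(x, design_df)
  mod <- moderated_linear_test(sm)

  X <- model.matrix(~ factor(design_df$condition, c("EGTA", "Ca")) +
                      factor(design_df$batch))
  lfit <- limma::eBayes(limma::lmFit(x, X))
  expect_equal(attr(mod, "d0"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s0_2"), lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mod$statistic, unname(lfit$t[, 2]), tolerance = 1e-9)
  expect_equal(mod$p, unname(lfit$p.value[, 2]), tolerance = 1e-9)
})

test_that("null p-values are uniform across seeds", {
  ks_crit_1pct <- 1.628 / sqrt(2000)
  pass <- sapply(1:20, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(2000 * 6, sd = rep(sqrt(1 / rchisq(2000, 4) * 4), 6)),
                nrow = 2000)
    sm <- site_matrix(x, default_design())
    mod <- suppressWarnings(moderated_linear_test(sm))
    ks <- max(abs(sort(mod$p) - (seq_len(2000) - 0.5) / 2000))
    ks < ks_crit_1pct
  })
  expect_gte(mean(pass), 0.95)
})

test_that("q-values behave as Storey's estimator", {
  expect_equal(as.numeric(estimate_qvalues(rep(1, 10))), rep(1, 10))
  expect_identical(estimate_qvalues(numeric(0)), numeric(0))

  set.seed(10)
  p <- c(runif(900), rbeta(100, 0.1, 10))
  q_bh <- p.adjust(p, "BH")
  expect_equal(as.numeric(estimate_qvalues(p, pi0 = 1)), q_bh,
               tolerance = 1e-12)

  q <- estimate_qvalues(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(as.numeric(q)[o]) >= -1e-15))
  expect_true(attr(q, "pi0") <= 1)
  expect_error(estimate_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("regulated calls honour the inclusive-fold / strict-q semantics", {
  cfg <- pipeline_config()
  stats <- data.frame(
    log2FC = c(log2(1.15), 1.0, log2(1.149), -log2(1.2)),
    q = c(0.049, 0.05, 0.01, 0.01)
  )
  out <- call_regulated_sites(stats, cfg)
  expect_equal(out$call, c("up", "none", "none", "down"))
  # 2x2 grid around both thresholds: exactly one call
  grid <- data.frame(log2FC = c(0.3, 0.3, 0.05, 0.05),
                     q = c(0.01, 0.2, 0.01, 0.2))
  expect_equal(sum(call_regulated_sites(grid, cfg)$call != "none"), 1L)
})

test_that("the full TMT stage is exact in the noise-free limit", {
  p <- truth_params(n_sites = 300L, n_regulated = 20L, noise_sd = 0,
                    channel_effect_sd = 0.4, compression_factor = 1,
                    missing_midpoint = -Inf, frac_low_locprob = 0,
                    frac_contaminant = 0, frac_reverse = 0, rng_seed = 12L)
  tr <- generate_ground_truth(p)
  fit <- suppressWarnings(tmt_fit(simulate_tmt_experiment(tr)))
  truth <- tr$sites$true_log2fc[match(fit$stats$site_id, tr$sites$site_id)]
  expect_equal(fit$stats$log2FC, truth, tolerance = 1e-9)
  expect_equal(nrow(fit$stats), 300L)
})

test_that("estimated effects are attenuated by the compression factor", {
  p <- truth_params(n_sites = 500L, n_regulated = 25L, noise_sd = 0,
                    channel_effect_sd = 0.3, compression_factor = 1.43,
                    missing_midpoint = -Inf, frac_low_locprob = 0,
                    frac_contaminant = 0, frac_reverse = 0, rng_seed = 13L)
  tr <- generate_ground_truth(p)
  fit <- suppressWarnings(tmt_fit(simulate_tmt_experiment(tr)))
  truth <- tr$sites$true_log2fc[match(fit$stats$site_id, tr$sites$site_id)]
  expect_equal(fit$stats$log2FC, truth / 1.43, tolerance = 1e-9)
})

test_that("tmt_fit methods expose coefficients and summaries", {
  p <- truth_params(n_sites = 200L, n_regulated = 10L, rng_seed = 21L)
  tr <- generate_ground_truth(p)
  fit <- suppressWarnings(tmt_fit(simulate_tmt_experiment(tr)))
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(unname(cf), fit$stats$log2FC)
  s <- summary(fit)
  expect_s3_class(s, "summary.tmt_fit")
  expect_output(print(fit), "regulated calls")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
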