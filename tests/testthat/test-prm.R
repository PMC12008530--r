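test_that("transition QC enforces the 7-transition and 5% rules", {
  cfg <- pipeline_config()

  # 7 healthy transitions: kept intact
  t7 <- make_transitions("AAAK[GG]R", heavy_areas = rep(100, 7))
  qc <- qc_filter_transitions(t7, cfg)
  expect_equal(nrow(qc$kept), 14L)
  expect_equal(nrow(qc$rejected), 0L)

  # 6 transitions: whole peptide dropped
  t6 <- make_transitions("CCCK[GG]R", heavy_areas = rep(100, 6))
  qc6 <- qc_filter_transitions(t6, cfg)
  expect_equal(nrow(qc6$kept), 0L)
  expect_match(qc6$rejected$reason[1], "fewer than 7")

  # 9 transitions, 2 below 5% of the max: 7 survive, peptide kept
  t9 <- make_transitions("DDDK[GG]R",
                         heavy_areas = c(rep(100, 7), 2, 3))
  qc9 <- qc_filter_transitions(t9, cfg)
  expect_equal(length(unique(qc9$kept$fragment_id)), 7L)
  expect_equal(sum(grepl("low-intensity", qc9$rejected$reason)), 2L)

  # all-equal areas: nothing is flagged low-intensity
  teq <- make_transitions("EEEK[GG]R", heavy_areas = rep(55, 8))
  expect_equal(nrow(qc_filter_transitions(teq, cfg)$rejected), 0L)
})

test_that("QC is judged on the heavy channel only", {
  # weak light areas must not remove transitions
  tr <- make_transitions("AAAK[GG]R", heavy_areas = rep(100, 7),
                         light_areas = c(rep(50, 6), 0.1))
  qc <- qc_filter_transitions(tr, pipeline_config())
  expect_equal(length(unique(qc$kept$fragment_id)), 7L)
})

test_that("adding a non-dominant transition never drops a kept peptide", {
  cfg <- pipeline_config()
  set.seed(14)
  for (i in 1:20) {
    areas <- runif(7, 10, 100)
    base <- make_transitions("AAAK[GG]R", heavy_areas = areas)
    kept_before <- nrow(qc_filter_transitions(base, cfg)$kept) > 0
    extra_area <- runif(1, cfg$low_intensity_fraction * max(areas),
                        max(areas))
    extra <- make_transitions("AAAK[GG]R", heavy_areas = extra_area)
    extra$fragment_id <- c("y90", "y90")
    kept_after <- nrow(qc_filter_transitions(rbind(base, extra), cfg)$kept) > 0
    if (kept_before) expect_true(kept_after)
  }
})

test_that("peptide ratios are summed-area ratios with scale invariance", {
  tr <- make_transitions("AAAK[GG]R", heavy_areas = rep(20, 7),
                         light_areas = rep(10, 7))
  q <- summarize_peptide_ratio(tr)
  expect_equal(q$ratio, 0.5)
  expect_equal(q$n_transitions_used, 7L)

  tr2 <- tr
  tr2$peak_area <- tr2$peak_area * 7.3
  expect_equal(summarize_peptide_ratio(tr2)$ratio, 0.5)

  # transition order is irrelevant
  expect_equal(summarize_peptide_ratio(tr[sample(nrow(tr)), ])$ratio, 0.5)

  # zero heavy sum is a quantification error
  tr3 <- make_transitions("AAAK[GG]R", heavy_areas = rep(0, 7),
                          light_areas = rep(1, 7))
  expect_error(summarize_peptide_ratio(tr3), "heavy area is zero")
})

test_that("noise-free simulated ratios are recovered exactly", {
  p <- truth_params(n_sites = 200L, n_regulated = 10L, prm_cv = 0,
                    prm_weak_frac = 0, rng_seed = 15L)
  tr <- generate_ground_truth(p)
  tr$prm_peptides$ratio_EGTA[1] <- 0.27
  tr$prm_peptides$ratio_Ca[1] <- 0.27 * 2^tr$prm_peptides$true_log2fc[1]
  prm <- simulate_prm_experiment(tr)
  q <- summarize_peptide_ratio(subset(prm,
    peptide_seq == tr$prm_peptides$peptide_seq[1] & condition == "EGTA" &
      bio_replicate == 1 & injection == 1 & batch == 1))
  expect_equal(q$ratio, 0.27, tolerance = 1e-12)
})

test_that("injection averaging is the arithmetic mean and symmetric", {
  quants <- do.call(rbind, lapply(1:3, function(i) {
    summarize_peptide_ratio(make_transitions(
      "AAAK[GG]R", heavy_areas = rep(100, 7),
      light_areas = rep(100 * c(0.10, 0.12, 0.14)[i], 7),
      injection = i))
  }))
  avg <- average_injection_replicates(quants)
  expect_equal(avg$ratio, 0.12)
  expect_equal(avg$n_injections, 3L)
  # permutation invariance
  expect_equal(average_injection_replicates(quants[c(3, 1, 2), ])$ratio, 0.12)
  # single injection: identity
  expect_equal(average_injection_replicates(quants[1, ])$ratio, 0.10)
})

test_that("a pure batch offset yields zero condition effect", {
  reps <- expand.grid(condition = c("Ca", "EGTA"), batch = 1:2,
                      bio_replicate = 1:3, stringsAsFactors = FALSE)
  reps$peptide_seq <- "AAAK[GG]R"
  reps$peptidoform <- "ub_only"
  reps$phosphatase_treated <- FALSE
  reps$ratio <- 0.4 * ifelse(reps$batch == 2, 2^0.7, 1)  # batch-2 offset
  reps$n_injections <- 3L
  reps2 <- reps
  reps2$peptide_seq <- "CCCK[GG]R"
  reps2$ratio <- reps2$ratio * 1.5
  out <- suppressWarnings(
    prm_differential_test(rbind(reps, reps2), pipeline_config())
  )
  expect_equal(out$log2FC, c(0, 0), tolerance = 1e-9)
})

test_that("the AP180-scale fold change is recovered across seeds", {
  est <- sapply(1:20, function(s) {
    p <- truth_params(n_sites = 100L, n_regulated = 5L, prm_cv = 0.1,
                      prm_n_peptides = 6L, prm_n_regulated = 1L,
                      rng_seed = 300 + s)
    tr <- generate_ground_truth(p)
    # a peptide deubiquitinated by a factor of 2.8 upon stimulation
    tr$prm_peptides$true_log2fc[1] <- -log2(2.8)
    tr$prm_peptides$ratio_Ca[1] <- tr$prm_peptides$ratio_EGTA[1] / 2.8
    fit <- suppressWarnings(prm_fit(simulate_prm_experiment(tr)))
    fold <- 2^-fit$stats$log2FC[fit$stats$peptide_seq ==
                                  tr$prm_peptides$peptide_seq[1]]
    fold
  })
  expect_lt(abs(mean(est) - 2.8) / 2.8, 0.15)
})

test_that("the full PRM stage is exact with noise off", {
  p <- truth_params(n_sites = 200L, n_regulated = 10L, prm_cv = 0,
                    prm_weak_frac = 0, rng_seed = 16L)
  tr <- generate_ground_truth(p)
  fit <- suppressWarnings(prm_fit(simulate_prm_experiment(tr)))
  m <- match(fit$stats$peptide_seq, tr$prm_peptides$peptide_seq)
  expect_equal(fit$stats$log2FC, tr$prm_peptides$true_log2fc[m],
               tolerance = 1e-9)
  # per-replicate ratios equal the generative truth exactly
  idx <- match(fit$replicates$peptide_seq, tr$prm_peptides$peptide_seq)
  truth <- ifelse(fit$replicates$condition == "Ca",
                  tr$prm_peptides$ratio_Ca[idx],
                  tr$prm_peptides$ratio_EGTA[idx])
  expect_equal(fit$replicates$ratio, truth, tolerance = 1e-12)
})

test_that("prm_fit methods report calls and coefficients", {
  p <- truth_params(n_sites = 100L, n_regulated = 8L, rng_seed = 17L)
  tr <- generate_ground_truth(p)
  fit <- suppressWarnings(prm_fit(simulate_prm_experiment(tr)))
  expect_named(coef(fit))
  expect_output(print(fit), "peptides tested")
  expect_true(all(fit$stats$call %in% c("up", "down", "none")))
  # calls respect the PRM dual threshold
  called <- fit$stats$call != "none"
  expect_true(all(abs(fit$stats$log2FC[called]) >= log2(1.23)))
  expect_true(all(fit$stats$q[called] < 0.05))
})
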