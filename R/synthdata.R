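# Synthetic diGly ubiquitinome experiments with known ground truth.
#
# The generator emulates the statistical structure of a TMT-6plex
# depolarization experiment (3 Ca2+ vs 3 EGTA channels in 2 labeling
# batches) and its PRM validation arm: sparse true regulation on a
# log-normal abundance background, per-channel loading effects, isobaric
# ratio compression, intensity-dependent left-censored missingness, and
# light/heavy transition reports with spiked heavy standards.

.AA <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]

# independent RNG stream per generator stage, derived from one user seed
.stage_seed <- function(seed, stage) {
  ((as.integer(seed) %% 1000003L) * 2048L +
     sum(utf8ToInt(stage)) %% 2048L) %% .Machine$integer.max
}

#' Ground-truth simulation parameters
#'
#' Defaults mirror the scale of a synaptosome diGly screen: 5258 sites of
#' which 43 are truly regulated (60% down, 40% up, reflecting the slight
#' predominance of depolarization-induced deubiquitination), effect sizes
#' uniform on |log2FC| in \[log2(1.3), log2(3)\], two TMT-6plex labeling
#' batches of 3 Ca2+ vs 3 EGTA channels, a ratio-compression factor of
#' 1.43 applied to the observed TMT effects, and a PRM panel of 26 targeted
#' peptides (9 regulated, 17 unregulated) with 7-12 transitions each.
#'
#' Noise magnitudes (`noise_sd` = 0.25 log2 units for TMT reporters,
#' `prm_cv` = 0.1 for transition areas) are calibration choices typical of
#' well-behaved reporter-ion and chromatogram-area data. Missingness is
#' logistic in log2 intensity (left-censoring), with probability 0.5 at
#' `missing_midpoint` and scale `missing_scale`; set
#' `missing_midpoint = -Inf` to disable missing values.
#'
#' @param n_sites number of ubiquitination sites.
#' @param n_regulated number of truly regulated sites.
#' @param prop_down fraction of regulated sites with negative log2FC.
#' @param effect_log2fc_range interval for |true log2FC| of regulated sites.
#' @param channels_per_condition replicate channels per condition per batch.
#' @param n_batches number of TMT labeling batches.
#' @param base_log2_mean,base_log2_sd log2-scale mean and sd of baseline
#'   reporter intensity across sites (log-normal abundance).
#' @param channel_effect_sd sd (log2) of per-channel loading effects; the
#'   effects are centred to mean zero within each batch.
#' @param noise_sd sd (log2) of measurement noise per cell.
#' @param compression_factor isobaric ratio-compression factor; observed
#'   TMT log2 effects are the true effects divided by this (>= 1).
#' @param missing_midpoint,missing_scale logistic missingness model:
#'   P(zero) = plogis((missing_midpoint - log2 intensity) / missing_scale).
#' @param frac_low_locprob fraction of sites drawn with localization
#'   probability below 0.75.
#' @param frac_contaminant,frac_reverse fractions (of `n_sites`) of decoy
#'   contaminant / reversed-sequence rows appended to each site table.
#' @param prm_n_peptides,prm_n_regulated size of the targeted PRM panel and
#'   how many of its peptides map to regulated sites.
#' @param prm_n_transitions integer range (length 2) of transitions per
#'   peptide.
#' @param prm_cv coefficient of variation of transition peak areas.
#' @param prm_injections injection replicates per PRM sample.
#' @param prm_weak_frac expected number of additional "weak" transitions
#'   (generated below 5% of the peptide's maximum transition area) per
#'   informative transition; these exercise the low-intensity QC without
#'   reducing a peptide below its informative transition count.
#' @param prm_base_ratio_meanlog,prm_base_ratio_sdlog log-normal parameters
#'   of the baseline (EGTA) light-to-heavy ratio across peptides.
#' @param rng_seed integer seed; each generator stage derives its own
#'   stream from it, so stages can be regenerated independently.
#' @return an object of class `truth_params` (validated list).
#' @export
truth_params <- function(n_sites = 5258L,
                         n_regulated = 43L,
                         prop_down = 0.6,
                         effect_log2fc_range = c(log2(1.3), log2(3)),
                         channels_per_condition = 3L,
                         n_batches = 2L,
                         base_log2_mean = 16,
                         base_log2_sd = 2,
                         channel_effect_sd = 0.3,
                         noise_sd = 0.25,
                         compression_factor = 1.43,
                         missing_midpoint = 11,
                         missing_scale = 0.5,
                         frac_low_locprob = 0.05,
                         frac_contaminant = 0.01,
                         frac_reverse = 0.01,
                         prm_n_peptides = 26L,
                         prm_n_regulated = 9L,
                         prm_cv = 0.1,
                         prm_n_transitions = c(7L, 12L),
                         prm_injections = 3L,
                         prm_weak_frac = 0.1,
                         prm_base_ratio_meanlog = log(0.3),
                         prm_base_ratio_sdlog = 0.5,
                         rng_seed = 1L) {
  p <- as.list(environment())
  if (p$n_regulated > p$n_sites) {
    stop("n_regulated must not exceed n_sites")
  }
  stopifnot(
    p$compression_factor >= 1,
    p$noise_sd >= 0, p$channel_effect_sd >= 0, p$base_log2_sd >= 0,
    p$prop_down >= 0, p$prop_down <= 1,
    length(p$effect_log2fc_range) == 2L,
    diff(p$effect_log2fc_range) >= 0, p$effect_log2fc_range[1] > 0,
    p$channels_per_condition >= 2L, p$n_batches >= 1L,
    p$prm_n_regulated <= p$prm_n_peptides,
    p$prm_cv >= 0, p$prm_weak_frac >= 0, p$prm_weak_frac < 1,
    p$prm_n_transitions[1] >= 1L
  )
  p$rng_seed <- as.integer(p$rng_seed)
  class(p) <- "truth_params"
  p
}

#' Channel design of a simulated TMT-6plex batch
#'
#' @param params a `truth_params` object.
#' @param batch batch number.
#' @return data.frame with columns `channel`, `condition`, `replicate`,
#'   `batch`; the first `channels_per_condition` channels are Ca2+.
#' @export
tmt_design <- function(params, batch = 1L) {
  k <- params$channels_per_condition
  data.frame(
    channel = seq_len(2L * k),
    condition = rep(c("Ca", "EGTA"), each = k),
    replicate = rep(seq_len(k), 2L),
    batch = as.integer(batch),
    stringsAsFactors = FALSE
  )
}

.random_window <- function(n, flank = 6L) {
  width <- 2L * flank + 1L
  w <- matrix(sample(.AA, n * width, replace = TRUE), nrow = n)
  w[, flank + 1L] <- "K"
  apply(w, 1L, paste0, collapse = "")
}

#' Generate a ground-truth ubiquitinome
#'
#' Draws the per-site truths all downstream generators share: baseline
#' log2 abundance, regulated flags with signed effect sizes, per-channel
#' loading effects (centred within batch), and the targeted PRM panel with
#' its true light-to-heavy ratios per condition (the Ca/EGTA ratio of true
#' ratios equals `2^true_log2fc`, uncompressed).
#'
#' @param params a `truth_params` object.
#' @return an object of class `ground_truth`: list with elements `sites`
#'   (data.frame: site_id, protein_id, position, sequence_window,
#'   baseline_log2, true_log2fc, regulated), `channel_effects`
#'   (batch x channel matrix, rows mean-zero), `prm_peptides` (data.frame:
#'   peptide_seq, site_id, true_log2fc, ratio_EGTA, ratio_Ca) and `params`.
#' @export
generate_ground_truth <- function(params = truth_params()) {
  stopifnot(inherits(params, "truth_params"))
  set.seed(.stage_seed(params$rng_seed, "truth"))
  n <- params$n_sites

  # skewed sites-per-protein allocation so inventory rankings are non-trivial
  n_prot <- max(1L, ceiling(n / 3))
  prot_w <- rexp(n_prot) + 0.05
  protein_id <- sprintf("P%05d", sample.int(n_prot, n, replace = TRUE,
                                            prob = prot_w))
  position <- integer(n)
  for (p in unique(protein_id)) {
    idx <- which(protein_id == p)
    position[idx] <- sort(sample.int(2000L, length(idx)))
  }

  true_log2fc <- numeric(n)
  regulated <- rep(FALSE, n)
  if (params$n_regulated > 0L) {
    reg <- sample.int(n, params$n_regulated)
    regulated[reg] <- TRUE
    sgn <- ifelse(runif(params$n_regulated) < params$prop_down, -1, 1)
    mag <- runif(params$n_regulated,
                 params$effect_log2fc_range[1], params$effect_log2fc_range[2])
    true_log2fc[reg] <- sgn * mag
  }

  sites <- data.frame(
    site_id = sprintf("site_%05d", seq_len(n)),
    protein_id = protein_id,
    position = position,
    sequence_window = .random_window(n),
    baseline_log2 = rnorm(n, params$base_log2_mean, params$base_log2_sd),
    true_log2fc = true_log2fc,
    regulated = regulated,
    stringsAsFactors = FALSE
  )

  nch <- 2L * params$channels_per_condition
  ce <- matrix(rnorm(params$n_batches * nch, 0, params$channel_effect_sd),
               nrow = params$n_batches)
  ce <- ce - rowMeans(ce)        # mean channel effect zero within batch
  dimnames(ce) <- list(paste0("batch", seq_len(params$n_batches)),
                       paste0("channel", seq_len(nch)))

  # targeted panels are assembled from reliably quantifiable sites, so the
  # panel is drawn from the upper half of the abundance distribution
  quantifiable <- sites$baseline_log2 >= params$base_log2_mean
  pick <- function(pool, k) {
    pool <- if (sum(pool & quantifiable) >= k) which(pool & quantifiable) else
      which(pool)
    sample(pool, min(k, length(pool)))
  }
  n_prm_reg <- min(params$prm_n_regulated, sum(regulated))
  prm_idx <- c(pick(regulated, n_prm_reg),
               pick(!regulated, params$prm_n_peptides - n_prm_reg))
  base_ratio <- exp(rnorm(length(prm_idx), params$prm_base_ratio_meanlog,
                          params$prm_base_ratio_sdlog))
  prm <- data.frame(
    peptide_seq = paste0(substr(sites$sequence_window[prm_idx], 3, 7),
                         "K[GG]", substr(sites$sequence_window[prm_idx], 9, 12)),
    site_id = sites$site_id[prm_idx],
    true_log2fc = sites$true_log2fc[prm_idx],
    ratio_EGTA = base_ratio,
    ratio_Ca = base_ratio * 2^sites$true_log2fc[prm_idx],
    stringsAsFactors = FALSE
  )

  structure(list(sites = sites, channel_effects = ce, prm_peptides = prm,
                 params = params),
            class = "ground_truth")
}

#' Simulate TMT-6plex GlyGly site tables
#'
#' For each labeling batch, the observed log2 reporter intensity of site i
#' in channel c is
#' `baseline_i + channel_effect_c + I(Ca_c) * true_log2fc_i / compression_factor
#'  + N(0, noise_sd)`.
#' Intensities are then exponentiated; cells are set to exact zero with the
#' logistic left-censoring probability; localization probabilities are drawn
#' so that `frac_low_locprob` of rows fall below 0.75; and decoy
#' contaminant/reversed rows are appended.
#'
#' @param truth a `ground_truth` object.
#' @param params a `truth_params` object (defaults to `truth$params`).
#' @return list with one site-table data.frame per batch (layout of
#'   [read_sites_table()]), each carrying its design as the `design`
#'   attribute.
#' @export
simulate_tmt_experiment <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(.stage_seed(params$rng_seed, "tmt"))
  n <- nrow(truth$sites)
  nch <- 2L * params$channels_per_condition
  out <- vector("list", params$n_batches)

  for (b in seq_len(params$n_batches)) {
    design <- tmt_design(params, b)
    ca <- as.numeric(design$condition == "Ca")
    mu <- outer(truth$sites$baseline_log2, rep(1, nch)) +
      outer(rep(1, n), truth$channel_effects[b, ]) +
      outer(truth$sites$true_log2fc / params$compression_factor, ca)
    obs <- mu + matrix(rnorm(n * nch, 0, params$noise_sd), nrow = n)
    intensity <- 2^obs
    p_zero <- stats::plogis((params$missing_midpoint - obs) /
                              params$missing_scale)
    intensity[matrix(runif(n * nch), nrow = n) < p_zero] <- 0

    low <- runif(n) < params$frac_low_locprob
    locprob <- ifelse(low, runif(n, 0, 0.7499), runif(n, 0.75, 1))

    tab <- data.frame(
      site_id = truth$sites$site_id,
      protein_id = truth$sites$protein_id,
      position = truth$sites$position,
      sequence_window = truth$sites$sequence_window,
      localization_prob = locprob,
      is_reverse = FALSE,
      is_contaminant = FALSE,
      stringsAsFactors = FALSE
    )
    for (j in seq_len(nch)) tab[[.reporter_cols(nch)[j]]] <- intensity[, j]

    n_con <- round(params$frac_contaminant * n)
    n_rev <- round(params$frac_reverse * n)
    if (n_con + n_rev > 0L) {
      nd <- n_con + n_rev
      decoy <- data.frame(
        site_id = sprintf("decoy_b%d_%04d", b, seq_len(nd)),
        protein_id = c(sprintf("CON__Q%05d", seq_len(n_con)),
                       sprintf("REV__P%05d", seq_len(n_rev))),
        position = sample.int(500L, nd, replace = TRUE),
        sequence_window = .random_window(nd),
        localization_prob = runif(nd, 0.75, 1),
        is_reverse = rep(c(FALSE, TRUE), c(n_con, n_rev)),
        is_contaminant = rep(c(TRUE, FALSE), c(n_con, n_rev)),
        stringsAsFactors = FALSE
      )
      dint <- 2^rnorm(nd * nch, params$base_log2_mean, params$base_log2_sd)
      dint <- matrix(dint, nrow = nd)
      for (j in seq_len(nch)) decoy[[.reporter_cols(nch)[j]]] <- dint[, j]
      tab <- rbind(tab, decoy)
    }
    rownames(tab) <- NULL
    attr(tab, "design") <- design
    out[[b]] <- tab
  }
  names(out) <- paste0("batch", seq_len(params$n_batches))
  out
}

#' Simulate a PRM transition report
#'
#' Each panel peptide receives a random number of transitions (fragment
#' ions); per-fragment heavy areas are log-normal around a peptide-level
#' scale, and light areas are `heavy * true_ratio * exp(N(0, sdlog))` with
#' `sdlog = sqrt(log(1 + prm_cv^2))`, so at `prm_cv = 0` every transition
#' ratio equals the true ratio exactly. A fraction `prm_weak_frac` of
#' transitions is generated "weak", below 5% of the peptide's maximum
#' transition area, to exercise the low-intensity QC.
#'
#' @param truth a `ground_truth` object (uses `truth$prm_peptides`).
#' @param params a `truth_params` object.
#' @return transition data.frame in the layout of
#'   [read_transition_report()].
#' @export
simulate_prm_experiment <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(.stage_seed(params$rng_seed, "prm"))
  sdlog <- sqrt(log(1 + params$prm_cv^2))
  pep <- truth$prm_peptides
  runs <- expand.grid(condition = c("Ca", "EGTA"),
                      batch = seq_len(params$n_batches),
                      bio_replicate = seq_len(params$channels_per_condition),
                      injection = seq_len(params$prm_injections),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- vector("list", nrow(pep))
  for (i in seq_len(nrow(pep))) {
    k_good <- sample(seq(params$prm_n_transitions[1],
                         params$prm_n_transitions[2]), 1L)
    n_weak <- stats::rbinom(1L, k_good, params$prm_weak_frac)
    k <- k_good + n_weak
    weak <- rep(c(FALSE, TRUE), c(k_good, n_weak))
    scale <- numeric(k)
    scale[!weak] <- 1e5 * runif(k_good, 0.15, 1)
    if (n_weak > 0L) scale[weak] <- max(scale) * runif(n_weak, 0.005, 0.04)
    frag <- paste0("y", seq_len(k) + 2L)
    ratio <- c(Ca = pep$ratio_Ca[i], EGTA = pep$ratio_EGTA[i])
    per_run <- lapply(seq_len(nrow(runs)), function(r) {
      heavy <- scale * exp(rnorm(k, 0, sdlog))
      light <- heavy * ratio[[runs$condition[r]]] * exp(rnorm(k, 0, sdlog))
      data.frame(
        peptide_seq = pep$peptide_seq[i],
        peptidoform = "ub_only",
        label = rep(c("light", "heavy"), each = k),
        fragment_id = rep(frag, 2L),
        peak_area = c(light, heavy),
        condition = runs$condition[r],
        bio_replicate = runs$bio_replicate[r],
        injection = runs$injection[r],
        batch = runs$batch[r],
        phosphatase_treated = FALSE,
        stringsAsFactors = FALSE
      )
    })
    res[[i]] <- do.call(rbind, per_run)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Peptidoform pool specification for the crosstalk simulator
#'
#' Describes, per condition, the total ubiquitinated pool of a peptide (in
#' light-to-heavy ratio units) and the fraction of that pool that is also
#' phosphorylated. Defaults reproduce the CaMKII-alpha K291/T286 scenario:
#' in the resting (EGTA) condition the singly ubiquitinated and doubly
#' modified forms sit at ratios 0.27 and 0.034 (total 0.304), and after
#' Ca2+ stimulation at 0.14 and 0.1 (total 0.24).
#'
#' @param total_EGTA,total_Ca total ubiquitinated pool per condition.
#' @param phospho_frac_EGTA,phospho_frac_Ca phosphorylated fraction of the
#'   pool, in \[0, 1\].
#' @return data.frame with columns `condition`, `total`,
#'   `phospho_fraction`.
#' @export
crosstalk_pools <- function(total_EGTA = 0.304,
                            phospho_frac_EGTA = 0.034 / 0.304,
                            total_Ca = 0.24,
                            phospho_frac_Ca = 0.1 / 0.24) {
  fr <- c(phospho_frac_EGTA, phospho_frac_Ca)
  if (any(fr < 0 | fr > 1)) {
    stop("phosphorylated fraction must lie in [0, 1]")
  }
  stopifnot(total_EGTA >= 0, total_Ca >= 0)
  data.frame(condition = c("EGTA", "Ca"),
             total = c(total_EGTA, total_Ca),
             phospho_fraction = fr,
             stringsAsFactors = FALSE)
}

#' Simulate crosstalk observations (peptidoform ratios +/- phosphatase)
#'
#' Emits light-to-heavy ratios of the singly ubiquitinated
#' (`single = total * (1 - phospho_fraction)`) and doubly modified
#' (`double = total * phospho_fraction`) peptidoforms per condition, plus
#' the phosphatase-treated single-form measurement in which the doubly
#' modified pool is added back exactly (`pptase = total`). Optional
#' multiplicative log-normal measurement noise is applied per cell.
#'
#' @param pool_truth pool specification from [crosstalk_pools()].
#' @param params a `truth_params` object (seed source).
#' @param n_obs number of replicate observations.
#' @param noise_cv coefficient of variation of measurement noise (0 = off).
#' @return data.frame of class `crosstalk_observation`, one row per
#'   observation, columns `E_single`, `E_double`, `C_single`, `C_double`,
#'   `E_pptase`, `C_pptase`.
#' @export
simulate_crosstalk_dataset <- function(pool_truth = crosstalk_pools(),
                                       params = truth_params(),
                                       n_obs = 1L, noise_cv = 0) {
  if (any(pool_truth$phospho_fraction < 0 | pool_truth$phospho_fraction > 1)) {
    stop("phosphorylated fraction must lie in [0, 1]")
  }
  set.seed(.stage_seed(params$rng_seed, "crosstalk"))
  g <- function(cond, what) {
    row <- pool_truth[pool_truth$condition == cond, ]
    switch(what,
           single = row$total * (1 - row$phospho_fraction),
           double = row$total * row$phospho_fraction,
           pptase = row$total)
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function() if (noise_cv > 0) exp(rnorm(n_obs, 0, sdlog)) else 1
  out <- data.frame(
    E_single = g("EGTA", "single") * noise(),
    E_double = g("EGTA", "double") * noise(),
    C_single = g("Ca", "single") * noise(),
    C_double = g("Ca", "double") * noise(),
    E_pptase = g("EGTA", "pptase") * noise(),
    C_pptase = g("Ca", "pptase") * noise()
  )
  class(out) <- c("crosstalk_observation", "data.frame")
  out
}
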