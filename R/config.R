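#' Analysis configuration
#'
#' Collects the tunable constants of the quantification pipeline: the
#' site-level QC thresholds of the TMT stage, the transition-level QC
#' thresholds of the PRM stage, the dual fold-change/q-value significance
#' thresholds, and the sequence-window geometry used for cross-dataset site
#' matching.
#'
#' Defaults follow the analysis conventions of diGly profiling studies:
#' sites below 0.75 localization probability are discarded, rows with more
#' than three empty channels per TMT-6plex are dropped, median polish runs
#' for at most three iterations, TMT calls require at least a 1.15-fold
#' change at q < 0.05, PRM calls at least a 1.23-fold change at q < 0.05,
#' PRM peptides need at least 7 transitions after removing transitions whose
#' heavy-channel area is below 5% of the peptide maximum, and sequence
#' windows span six residues either side of the modified lysine.
#'
#' @param min_localization_prob minimum site localization probability kept.
#' @param max_zero_channels maximum number of zero-intensity channels per
#'   6-plex row before the row is excluded.
#' @param median_polish_max_iter iteration cap for the Tukey median polish.
#' @param tmt_fc_threshold minimum fold change (ratio scale, > 1) for a TMT
#'   regulated call.
#' @param prm_fc_threshold minimum fold change for a PRM regulated call.
#' @param q_threshold q-value cutoff (strict) for regulated calls.
#' @param min_transitions minimum surviving transitions per PRM peptide.
#' @param low_intensity_fraction transitions whose heavy area falls below
#'   this fraction of the peptide's maximum heavy transition area are
#'   excluded before summing.
#' @param flank_len residues flanking the modified lysine in a sequence
#'   window; the window length is `2 * flank_len + 1`.
#' @param remnant_mass monoisotopic mass (Da) of the Gly-Gly remnant left on
#'   the modified lysine after tryptic digestion; informational constant.
#' @param pi0_lambda tuning parameter lambda for the Storey pi0 estimate.
#' @param rng_seed integer seed recorded in run manifests.
#' @return an object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$tmt_fc_threshold
#' @export
pipeline_config <- function(min_localization_prob = 0.75,
                            max_zero_channels = 3L,
                            median_polish_max_iter = 3L,
                            tmt_fc_threshold = 1.15,
                            prm_fc_threshold = 1.23,
                            q_threshold = 0.05,
                            min_transitions = 7L,
                            low_intensity_fraction = 0.05,
                            flank_len = 6L,
                            remnant_mass = 114.04,
                            pi0_lambda = 0.5,
                            rng_seed = 1L) {
  cfg <- list(
    min_localization_prob = min_localization_prob,
    max_zero_channels = as.integer(max_zero_channels),
    median_polish_max_iter = as.integer(median_polish_max_iter),
    tmt_fc_threshold = tmt_fc_threshold,
    prm_fc_threshold = prm_fc_threshold,
    q_threshold = q_threshold,
    min_transitions = as.integer(min_transitions),
    low_intensity_fraction = low_intensity_fraction,
    flank_len = as.integer(flank_len),
    remnant_mass = remnant_mass,
    pi0_lambda = pi0_lambda,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$min_localization_prob >= 0, cfg$min_localization_prob <= 1,
    cfg$max_zero_channels >= 0,
    cfg$median_polish_max_iter >= 1,
    cfg$tmt_fc_threshold > 1, cfg$prm_fc_threshold > 1,
    cfg$q_threshold > 0, cfg$q_threshold <= 1,
    cfg$min_transitions >= 1,
    cfg$low_intensity_fraction >= 0, cfg$low_intensity_fraction < 1,
    cfg$flank_len >= 1,
    cfg$pi0_lambda > 0, cfg$pi0_lambda < 1
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path path to a YAML file of `key: value` pairs.
#' @return a `pipeline_config` object.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("diGly pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
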