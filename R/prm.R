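# Targeted-stage PRM quantification: transition QC, light-to-heavy
# ratio-of-sums summarization, injection-replicate averaging, and
# batch-aware moderated differential testing.

.peptide_key_cols <- c("peptide_seq", "peptidoform", "phosphatase_treated")

.paste_key <- function(df, cols) {
  do.call(paste, c(unname(df[cols]), sep = "\r"))
}

#' Quality-control filter for PRM transitions
#'
#' Within each peptide (sequence + peptidoform + phosphatase state), the
#' heavy-channel area of every fragment is summed across all runs; fragments
#' whose summed heavy area falls below `low_intensity_fraction` (default 5%)
#' of the peptide's maximum fragment are excluded. Peptides left with fewer
#' than `min_transitions` (default 7) fragments are dropped entirely. QC is
#' judged on the heavy (standard) channel only, so it cannot bias the
#' light/heavy ratio. All removals are logged with a reason.
#'
#' @param rows transition data.frame ([read_transition_report()] layout).
#' @param config a [pipeline_config()].
#' @return list with `kept` (data.frame) and `rejected` (data.frame:
#'   peptide_seq, peptidoform, phosphatase_treated, fragment_id, reason).
#' @export
qc_filter_transitions <- function(rows, config = pipeline_config()) {
  pkey <- .paste_key(rows, .peptide_key_cols)
  keep <- rep(TRUE, nrow(rows))
  logs <- list()
  for (pk in unique(pkey)) {
    idx <- which(pkey == pk)
    sub <- rows[idx, , drop = FALSE]
    heavy <- sub[sub$label == "heavy", , drop = FALSE]
    tot <- tapply(heavy$peak_area, heavy$fragment_id, sum)
    weak <- names(tot)[tot < config$low_intensity_fraction * max(tot)]
    surviving <- setdiff(names(tot), weak)
    info <- sub[!duplicated(sub$fragment_id),
                c(.peptide_key_cols, "fragment_id"), drop = FALSE]
    if (length(weak) > 0L) {
      w <- info[info$fragment_id %in% weak, , drop = FALSE]
      w$reason <- "low-intensity transition (heavy area < fraction of peptide max)"
      logs[[length(logs) + 1L]] <- w
      keep[idx][sub$fragment_id %in% weak] <- FALSE
    }
    if (length(surviving) < config$min_transitions) {
      w <- info[info$fragment_id %in% surviving, , drop = FALSE]
      if (nrow(w)) {
        w$reason <- sprintf("peptide has fewer than %d surviving transitions",
                            config$min_transitions)
        logs[[length(logs) + 1L]] <- w
      }
      keep[idx] <- FALSE
    }
  }
  rejected <- if (length(logs)) do.call(rbind, logs) else
    data.frame(peptide_seq = character(0), peptidoform = character(0),
               phosphatase_treated = logical(0), fragment_id = character(0),
               reason = character(0))
  rownames(rejected) <- NULL
  list(kept = rows[keep, , drop = FALSE], rejected = rejected)
}

#' Summarize light-to-heavy peptide ratios per injection
#'
#' Ratio-of-sums estimator: within each (peptide, condition, batch,
#' biological replicate, injection) cell, the surviving light transition
#' areas are summed and divided by the summed heavy areas. The estimator is
#' invariant to common scaling of a run and to transition order.
#'
#' @param rows QC-passed transition data.frame.
#' @return data.frame, one row per peptide x injection: peptide key
#'   columns, `condition`, `batch`, `bio_replicate`, `injection`,
#'   `light_sum`, `heavy_sum`, `ratio`, `n_transitions_used`.
#' @export
summarize_peptide_ratio <- function(rows) {
  gcols <- c(.peptide_key_cols, "condition", "batch", "bio_replicate",
             "injection")
  key <- .paste_key(rows, gcols)
  split_idx <- split(seq_len(nrow(rows)), key)
  out <- lapply(split_idx, function(idx) {
    sub <- rows[idx, , drop = FALSE]
    light <- sum(sub$peak_area[sub$label == "light"])
    heavy <- sum(sub$peak_area[sub$label == "heavy"])
    if (heavy == 0) {
      stop("summed heavy area is zero for peptide ", sub$peptide_seq[1L],
           " (replicate ", sub$bio_replicate[1L], ", injection ",
           sub$injection[1L], ")")
    }
    cbind(sub[1L, gcols, drop = FALSE],
          data.frame(light_sum = light, heavy_sum = heavy,
                     ratio = light / heavy,
                     n_transitions_used = length(unique(sub$fragment_id))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(.paste_key(out, gcols)), , drop = FALSE]
}

#' Average injection replicates to one ratio per biological replicate
#'
#' Arithmetic mean of the light-to-heavy ratios across injections of the
#' same biological replicate.
#'
#' @param quants output of [summarize_peptide_ratio()].
#' @param log_scale average on the log2 scale instead (geometric mean).
#' @return data.frame, one row per peptide x biological replicate, with
#'   `ratio` (the averaged value) and `n_injections`.
#' @export
average_injection_replicates <- function(quants, log_scale = FALSE) {
  gcols <- c(.peptide_key_cols, "condition", "batch", "bio_replicate")
  key <- .paste_key(quants, gcols)
  out <- lapply(split(seq_len(nrow(quants)), key), function(idx) {
    sub <- quants[idx, , drop = FALSE]
    r <- if (log_scale) 2^mean(log2(sub$ratio)) else mean(sub$ratio)
    cbind(sub[1L, gcols, drop = FALSE],
          data.frame(ratio = r, n_injections = nrow(sub),
                     n_transitions_used = sub$n_transitions_used[1L]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(.paste_key(out, gcols)), , drop = FALSE]
}

#' Batch-aware differential test on PRM peptide ratios
#'
#' Models `log2(ratio) ~ condition + batch` per peptide across biological
#' replicates, with empirical-Bayes variance moderation shared across the
#' peptide panel ([moderated_linear_test()]), Storey q-values, and
#' regulated calls at |fold| >= `prm_fc_threshold` (1.23) and
#' q < `q_threshold`.
#'
#' @param reps output of [average_injection_replicates()] (one ratio per
#'   peptide and biological replicate).
#' @param config a [pipeline_config()].
#' @param prior_df optional fixed prior df for the moderated test.
#' @return data.frame, one row per peptide: key columns, `log2FC`
#'   (Ca - EGTA), `statistic`, `p`, `q`, `call`.
#' @export
prm_differential_test <- function(reps, config = pipeline_config(),
                                  prior_df = NULL) {
  if (length(unique(reps$condition)) < 2L) {
    stop("both conditions must be present in the PRM design")
  }
  scols <- c("condition", "batch", "bio_replicate")
  sample_key <- unique(reps[scols])
  sample_key <- sample_key[order(.paste_key(sample_key, scols)), ,
                           drop = FALSE]
  sid <- .paste_key(sample_key, scols)
  pkey <- .paste_key(reps, .peptide_key_cols)
  peptides <- unique(reps[.peptide_key_cols])
  rownames(peptides) <- NULL

  vals <- matrix(NA_real_, nrow = nrow(peptides), ncol = nrow(sample_key),
                 dimnames = list(.paste_key(peptides, .peptide_key_cols), sid))
  vals[cbind(match(pkey, rownames(vals)),
             match(.paste_key(reps, scols), sid))] <- log2(reps$ratio)
  complete <- rowSums(is.na(vals)) == 0L
  if (!all(complete)) {
    warning(sum(!complete), " peptide(s) dropped: not quantified in every ",
            "replicate")
    vals <- vals[complete, , drop = FALSE]
    peptides <- peptides[complete, , drop = FALSE]
  }

  design <- data.frame(condition = sample_key$condition,
                       replicate = sample_key$bio_replicate,
                       batch = sample_key$batch, stringsAsFactors = FALSE)
  stats <- moderated_linear_test(site_matrix(vals, design),
                                 batch_aware = TRUE, prior_df = prior_df)
  stats$q <- as.numeric(estimate_qvalues(stats$p, lambda = config$pi0_lambda))
  stats <- call_regulated_sites(stats, config,
                                fc_threshold = config$prm_fc_threshold)
  out <- cbind(peptides, stats[setdiff(names(stats), "site_id")])
  rownames(out) <- NULL
  out
}

#' Fit the full PRM targeted analysis
#'
#' Chains transition QC, ratio-of-sums summarization, injection-replicate
#' averaging and the batch-aware moderated differential test.
#'
#' @param transitions transition data.frame
#'   ([read_transition_report()] layout).
#' @param config a [pipeline_config()].
#' @param prior_df optional fixed prior df for the moderated test.
#' @return object of class `prm_fit` with elements `stats`, `replicates`
#'   (per-replicate averaged ratios), `injections` (per-injection ratios),
#'   `qc_log` and `config`.
#' @export
prm_fit <- function(transitions, config = pipeline_config(),
                    prior_df = NULL) {
  qc <- qc_filter_transitions(transitions, config)
  if (nrow(qc$kept) == 0L) stop("no peptides survive transition QC")
  inj <- summarize_peptide_ratio(qc$kept)
  reps <- average_injection_replicates(inj)
  stats <- prm_differential_test(reps, config, prior_df = prior_df)
  structure(list(stats = stats, replicates = reps, injections = inj,
                 qc_log = qc$rejected, config = config),
            class = "prm_fit")
}

#' @export
print.prm_fit <- function(x, ...) {
  cat("PRM light/heavy peptidoform quantification\n")
  cat(sprintf("  peptides tested: %d (transitions removed in QC: %d)\n",
              nrow(x$stats),
              sum(x$qc_log$reason != "" & !duplicated(
                paste(x$qc_log$peptide_seq, x$qc_log$fragment_id)))))
  cat(sprintf("  regulated calls (|fold| >= %.2f, q < %.2g): %d up, %d down\n",
              x$config$prm_fc_threshold, x$config$q_threshold,
              sum(x$stats$call == "up"), sum(x$stats$call == "down")))
  invisible(x)
}

#' Extract per-peptide log2 fold changes from a PRM fit
#'
#' @param object a `prm_fit`.
#' @param ... unused.
#' @return named numeric vector of log2FC (Ca - EGTA) per peptide.
#' @export
coef.prm_fit <- function(object, ...) {
  setNames(object$stats$log2FC, object$stats$peptide_seq)
}

#' @export
summary.prm_fit <- function(object, ...) {
  cat("PRM fit summary\n  calls:\n")
  print(table(factor(object$stats$call, levels = c("down", "none", "up"))))
  invisible(object)
}
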