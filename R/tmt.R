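# Discovery-stage TMT quantification: site QC, left-censored imputation,
# median-polish channel normalization, moderated linear-model testing,
# q-values, and dual fold-change/q regulated-site calls.

#' Construct a site x channel log2 matrix with its design
#'
#' @param values numeric matrix of log2 intensities, rows named by site id.
#' @param design data.frame mapping channels to (condition, replicate,
#'   batch); one row per column of `values`.
#' @return object of class `site_matrix`.
#' @export
site_matrix <- function(values, design) {
  stopifnot(is.matrix(values), nrow(design) == ncol(values),
            all(c("condition", "replicate", "batch") %in% names(design)))
  if (any(!is.finite(values))) stop("site matrix values must be finite")
  structure(list(values = values, design = design), class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("site_matrix: %d sites x %d channels (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$design$condition)),
                            table(x$design$condition)), collapse = ", ")))
  invisible(x)
}

.intensity_matrix <- function(rows, n_channels) {
  as.matrix(rows[.reporter_cols(n_channels)])
}

#' Filter GlyGly sites before quantification
#'
#' Drops contaminant and reversed-sequence rows, sites with localization
#' probability below the threshold (0.75 by default; a site at exactly 0.75
#' is kept), and rows with more than `max_zero_channels` zero intensities
#' in the 6-plex (a row with exactly three zeros is kept). Every dropped
#' row is logged with one reason.
#'
#' @param rows site-table data.frame for one TMT-6plex experiment.
#' @param config a [pipeline_config()].
#' @param n_channels channels expected per row (a different count is a
#'   design error).
#' @return list with `kept` (data.frame) and `rejected` (data.frame:
#'   site_id, reason).
#' @export
filter_sites <- function(rows, config = pipeline_config(), n_channels = 6L) {
  have <- sum(names(rows) %in% .reporter_cols(64L))
  if (have != n_channels) {
    stop("expected ", n_channels, " reporter channels per row, found ", have)
  }
  zeros <- rowSums(.intensity_matrix(rows, n_channels) == 0)
  reason <- character(nrow(rows))
  pick <- function(cond, msg) reason[cond & !nzchar(reason)] <<- msg
  pick(rows$is_contaminant, "potential contaminant")
  pick(rows$is_reverse, "reversed sequence")
  pick(rows$localization_prob < config$min_localization_prob,
       sprintf("localization probability < %g", config$min_localization_prob))
  pick(zeros > config$max_zero_channels,
       sprintf("more than %d zero channels", config$max_zero_channels))
  drop <- nzchar(reason)
  list(kept = rows[!drop, , drop = FALSE],
       rejected = data.frame(site_id = rows$site_id[drop],
                             reason = reason[drop],
                             stringsAsFactors = FALSE))
}

#' Impute left-censored zeros at the channel minimum and log2-transform
#'
#' Each remaining zero is replaced by the minimum nonzero intensity of its
#' own channel (column), after which all intensities are log2-transformed.
#'
#' @param rows filtered site-table data.frame (each row has at most
#'   `max_zero_channels` zeros).
#' @param design channel design data.frame (condition, replicate, batch).
#' @return a [site_matrix()] of log2 intensities.
#' @export
impute_missing <- function(rows, design) {
  n_channels <- nrow(design)
  x <- .intensity_matrix(rows, n_channels)
  rownames(x) <- rows$site_id
  for (j in seq_len(ncol(x))) {
    nz <- x[, j] > 0
    if (!any(nz)) {
      stop("channel ", j, " has no nonzero intensity; cannot impute")
    }
    x[!nz, j] <- min(x[nz, j])
  }
  site_matrix(log2(x), design)
}

#' Tukey median polish
#'
#' Decomposes a matrix into `overall + row + column + residual` by
#' alternately sweeping out row medians then column medians, for at most
#' `max_iter` full iterations (the iteration cap, not a convergence
#' tolerance, is the binding stop rule).
#'
#' @param x numeric matrix (>= 2 rows and columns, finite).
#' @param max_iter iteration cap (default 3).
#' @return list with `overall` (scalar), `row`, `col` (effect vectors) and
#'   `residuals` (matrix); the decomposition reconstructs `x` exactly.
#' @export
median_polish <- function(x, max_iter = 3L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  if (any(!is.finite(x))) stop("median polish requires finite input")
  fit <- suppressWarnings(
    stats::medpolish(x, eps = 1e-12, maxiter = max_iter, trace.iter = FALSE)
  )
  list(overall = fit$overall, row = fit$row, col = fit$col,
       residuals = fit$residuals)
}

#' Normalize a log2 site matrix by median polish
#'
#' Removes the overall level and the column (channel loading) effects from
#' each labeling experiment while retaining row (site) effects:
#' `normalized = value - overall - column effect`. Channels are the
#' nuisance; the biology stays in the rows.
#'
#' @param sm a [site_matrix()] from one labeling batch.
#' @param config a [pipeline_config()] (supplies the iteration cap).
#' @return the normalized `site_matrix`.
#' @export
normalize_by_median_polish <- function(sm, config = pipeline_config()) {
  stopifnot(inherits(sm, "site_matrix"))
  mp <- median_polish(sm$values, max_iter = config$median_polish_max_iter)
  vals <- sweep(sm$values - mp$overall, 2L, mp$col)
  site_matrix(vals, sm$design)
}

#' Combine normalized site matrices from several labeling batches
#'
#' Joins on the sites quantified in every batch (channels accumulate
#' column-wise); sites missing from any batch are dropped, since the
#' downstream model allows no missing cells.
#'
#' @param matrices list of [site_matrix()] objects.
#' @return one combined `site_matrix`.
#' @export
combine_site_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  if (length(matrices) == 1L) return(matrices[[1L]])
  common <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(common) == 0L) stop("no sites shared across batches")
  vals <- do.call(cbind, lapply(matrices, function(m) m$values[common, ,
                                                               drop = FALSE]))
  design <- do.call(rbind, lapply(matrices, function(m) m$design))
  rownames(design) <- NULL
  site_matrix(vals, design)
}

#' Moderated linear-model test for a condition contrast
#'
#' Fits, per site, an ordinary least-squares linear model of the log2
#' values on condition (Ca2+ vs EGTA; the reported effect is Ca - EGTA)
#' and, optionally, labeling batch. Residual variances are shrunk toward a
#' pooled scaled inverse-chi-square prior fitted by method of moments
#' ([squeeze_variances()]); the moderated t statistic
#' `effect / sqrt(s2_post * v)` is referred to a t distribution with
#' `d + d0` degrees of freedom. When the prior df estimate is non-finite
#' (no detectable variance heterogeneity), ordinary t statistics are
#' reported with a warning instead of forcing an infinite prior.
#'
#' @param sm a combined, normalized [site_matrix()].
#' @param batch_aware include a batch covariate when more than one batch is
#'   present (default TRUE).
#' @param prior_df optional fixed prior df (0 recovers the ordinary t test;
#'   Inf replaces every variance by the pooled prior variance).
#' @return data.frame (one row per site): `site_id`, `log2FC`,
#'   `statistic`, `p`, `df_residual`, `df_prior`, `s2`, `s2_post`;
#'   attributes `d0` and `s0_2`.
#' @export
moderated_linear_test <- function(sm, batch_aware = TRUE, prior_df = NULL) {
  stopifnot(inherits(sm, "site_matrix"))
  design <- sm$design
  if (length(unique(design$condition)) < 2L) {
    stop("both conditions must be present in the design")
  }
  if (min(table(design$condition)) < 2L) {
    stop("at least 2 replicate channels per condition are required")
  }
  condition <- factor(design$condition, levels = c("EGTA", "Ca"))
  use_batch <- batch_aware && length(unique(design$batch)) > 1L
  X <- if (use_batch) {
    stats::model.matrix(~ condition + factor(design$batch))
  } else {
    stats::model.matrix(~ condition)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  d <- nrow(X) - ncol(X)
  if (d < 1L) stop("zero residual degrees of freedom")

  Y <- sm$values
  if (is.null(rownames(Y))) rownames(Y) <- paste0("site_", seq_len(nrow(Y)))
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi                       # sites x coefficients
  res <- Y - B %*% t(X)
  s2 <- rowSums(res^2) / d
  j <- which(colnames(X) == "conditionCa")
  effect <- B[, j]
  v <- XtXi[j, j]

  sq <- squeeze_variances(s2, d, prior_df = prior_df)
  if (!sq$estimable) {
    warning("prior degrees of freedom not estimable; ",
            "reporting ordinary t statistics")
    d0_used <- 0
    s2_post <- s2
  } else {
    d0_used <- sq$d0
    s2_post <- sq$s2_post
  }
  df_total <- if (is.infinite(d0_used)) Inf else d + d0_used
  tstat <- effect / sqrt(s2_post * v)
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[s2_post == 0] <- 0                         # exact fits: infinite t

  out <- data.frame(site_id = rownames(Y), log2FC = effect,
                    statistic = tstat, p = p,
                    df_residual = d, df_prior = d0_used,
                    s2 = s2, s2_post = s2_post,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- sq$d0
  attr(out, "s0_2") <- sq$s0_2
  out
}

#' Call regulated sites at dual fold-change / q-value thresholds
#'
#' A site is called `up` when `log2FC >= log2(fc_threshold)` (inclusive)
#' and `q < q_threshold` (strict), `down` for the mirrored negative bound,
#' `none` otherwise.
#'
#' @param stats data.frame with columns `log2FC` and `q`.
#' @param config a [pipeline_config()].
#' @param fc_threshold fold-change threshold (defaults to the TMT one).
#' @return `stats` with a `call` column added.
#' @export
call_regulated_sites <- function(stats, config = pipeline_config(),
                                 fc_threshold = config$tmt_fc_threshold) {
  lfc <- log2(fc_threshold)
  sig <- stats$q < config$q_threshold
  stats$call <- ifelse(sig & stats$log2FC >= lfc, "up",
                       ifelse(sig & stats$log2FC <= -lfc, "down", "none"))
  stats
}

#' Fit the full TMT discovery-stage analysis
#'
#' Runs, per labeling batch, site filtering, left-censored imputation at
#' the channel minimum and median-polish normalization; joins the batches
#' on shared sites; fits the moderated linear model with a batch
#' covariate; computes Storey q-values; and calls regulated sites at the
#' dual |fold| >= 1.15 / q < 0.05 thresholds.
#'
#' @param batches list of site-table data.frames (one per TMT-6plex
#'   labeling experiment), each carrying its channel design as the
#'   `design` attribute, or supplied via `designs`.
#' @param config a [pipeline_config()].
#' @param designs optional list of design data.frames overriding the
#'   attributes.
#' @param batch_term include the batch covariate in the linear model.
#' @param prior_df optional fixed prior df passed to the moderated test.
#' @return an object of class `tmt_fit` with elements `stats` (per-site
#'   results incl. q-values and calls), `rejections` (per-batch QC logs),
#'   `matrix` (the combined normalized [site_matrix()]), `config`, and
#'   `notes` (warnings recorded during fitting).
#' @seealso [coef.tmt_fit()], [summary.tmt_fit()], [plot.tmt_fit()]
#' @export
tmt_fit <- function(batches, config = pipeline_config(), designs = NULL,
                    batch_term = TRUE, prior_df = NULL) {
  if (is.data.frame(batches)) batches <- list(batches)
  if (is.null(designs)) designs <- lapply(batches, attr, "design")
  stopifnot(length(designs) == length(batches),
            !vapply(designs, is.null, logical(1)))

  rejections <- vector("list", length(batches))
  mats <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    flt <- filter_sites(batches[[b]], config, n_channels = nrow(designs[[b]]))
    rejections[[b]] <- flt$rejected
    sm <- impute_missing(flt$kept, designs[[b]])
    mats[[b]] <- normalize_by_median_polish(sm, config)
  }
  combined <- combine_site_matrices(mats)

  notes <- character(0)
  stats <- withCallingHandlers(
    moderated_linear_test(combined, batch_aware = batch_term,
                          prior_df = prior_df),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  stats$q <- as.numeric(estimate_qvalues(stats$p, lambda = config$pi0_lambda))
  stats <- call_regulated_sites(stats, config,
                                fc_threshold = config$tmt_fc_threshold)

  structure(list(stats = stats, rejections = rejections, matrix = combined,
                 config = config, notes = notes,
                 d0 = attr(stats, "d0"), s0_2 = attr(stats, "s0_2")),
            class = "tmt_fit")
}

#' @export
print.tmt_fit <- function(x, ...) {
  n_rej <- sum(vapply(x$rejections, nrow, integer(1)))
  cat("TMT diGly site quantification\n")
  cat(sprintf("  sites tested: %d (rejected in QC: %d)\n",
              nrow(x$stats), n_rej))
  cat(sprintf("  regulated calls (|fold| >= %.2f, q < %.2g): %d up, %d down\n",
              x$config$tmt_fc_threshold, x$config$q_threshold,
              sum(x$stats$call == "up"), sum(x$stats$call == "down")))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Summarize a TMT fit
#'
#' @param object a `tmt_fit`.
#' @param ... unused.
#' @return list of class `summary.tmt_fit` with call counts, QC rejection
#'   tallies by reason, and the variance-prior hyperparameters.
#' @export
summary.tmt_fit <- function(object, ...) {
  rej <- do.call(rbind, object$rejections)
  out <- list(
    n_sites = nrow(object$stats),
    calls = table(factor(object$stats$call, levels = c("down", "none", "up"))),
    rejections = if (!is.null(rej) && nrow(rej)) table(rej$reason) else table(character(0)),
    d0 = object$d0, s0_2 = object$s0_2,
    pi0 = attr(object$stats$q, "pi0")
  )
  class(out) <- "summary.tmt_fit"
  out
}

#' @export
print.summary.tmt_fit <- function(x, ...) {
  cat("TMT fit summary\n")
  cat("  sites tested:", x$n_sites, "\n  calls:\n")
  print(x$calls)
  if (length(x$rejections)) {
    cat("  QC rejections:\n")
    print(x$rejections)
  }
  cat(sprintf("  variance prior: d0 = %s, s0^2 = %s\n",
              format(x$d0, digits = 4), format(x$s0_2, digits = 4)))
  invisible(x)
}

#' Extract per-site log2 fold changes
#'
#' @param object a `tmt_fit`.
#' @param ... unused.
#' @return named numeric vector of log2FC (Ca - EGTA) per site.
#' @export
coef.tmt_fit <- function(object, ...) {
  setNames(object$stats$log2FC, object$stats$site_id)
}

#' Volcano plot of a TMT fit
#'
#' @param x a `tmt_fit`.
#' @param ... passed to [plot()].
#' @export
plot.tmt_fit <- function(x, ...) {
  s <- x$stats
  col <- ifelse(s$call == "none", "grey60", "firebrick")
  plot(s$log2FC, -log10(pmax(s$q, 1e-300)), pch = 20, col = col,
       xlab = expression(log[2] ~ "fold change (Ca - EGTA)"),
       ylab = expression(-log[10] ~ "q-value"), ...)
  abline(v = c(-1, 1) * log2(x$config$tmt_fc_threshold), lty = 2)
  abline(h = -log10(x$config$q_threshold), lty = 2)
  invisible(x)
}
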