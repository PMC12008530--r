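# Peptidoform-crosstalk conservation model.
#
# When a phosphosite and a ubiquitination site share one tryptic peptide
# (the CaMKII-alpha T286/K291 case), stimulation-induced phosphorylation
# converts the singly ubiquitinated peptidoform into the doubly modified
# one without changing the total ubiquitinated pool. An apparent decrease
# of the single form therefore decomposes exactly into a conversion part
# (growth of the double form) and a net-deubiquitination part (loss of the
# total pool); a phosphatase control collapses both forms back onto the
# single form and reads out the total pool directly.

#' Construct a crosstalk observation
#'
#' Light-to-heavy ratios of the singly ubiquitinated and doubly modified
#' (phospho + ubiquitin) peptidoforms in the reference (EGTA) and
#' stimulated (Ca2+) conditions, optionally with measured post-phosphatase
#' single-form ratios. Because each peptidoform carries its own heavy
#' standard at the same spike amount, the ratios are comparable absolute
#' abundance proxies across forms and conditions.
#'
#' @param E_single,E_double reference-condition ratios of the single and
#'   double forms.
#' @param C_single,C_double stimulated-condition ratios.
#' @param E_pptase,C_pptase optional measured post-phosphatase single-form
#'   ratios per condition.
#' @return object of class `crosstalk_observation`.
#' @export
crosstalk_observation <- function(E_single, E_double, C_single, C_double,
                                  E_pptase = NA_real_, C_pptase = NA_real_) {
  ratios <- c(E_single, E_double, C_single, C_double)
  if (any(ratios < 0)) stop("light/heavy ratios must be non-negative")
  structure(list(E_single = E_single, E_double = E_double,
                 C_single = C_single, C_double = C_double,
                 E_pptase = E_pptase, C_pptase = C_pptase),
            class = "crosstalk_observation")
}

#' @export
print.crosstalk_observation <- function(x, ...) {
  cat("Crosstalk observation (light/heavy ratios)\n")
  cat(sprintf("  EGTA: single %.4g, double %.4g\n", x$E_single, x$E_double))
  cat(sprintf("  Ca2+: single %.4g, double %.4g\n", x$C_single, x$C_double))
  if (!all(is.na(c(x$E_pptase, x$C_pptase)))) {
    cat(sprintf("  post-phosphatase: EGTA %.4g, Ca2+ %.4g\n",
                x$E_pptase, x$C_pptase))
  }
  invisible(x)
}

.as_crosstalk_obs <- function(obs) {
  if (inherits(obs, "crosstalk_observation")) return(obs)
  if (is.data.frame(obs) && nrow(obs) == 1L) {
    return(crosstalk_observation(obs$E_single, obs$E_double, obs$C_single,
                                 obs$C_double,
                                 if (!is.null(obs$E_pptase)) obs$E_pptase else NA_real_,
                                 if (!is.null(obs$C_pptase)) obs$C_pptase else NA_real_))
  }
  stop("expected a crosstalk_observation or a one-row observation data.frame")
}

#' Total ubiquitinated pool of a peptide
#'
#' The sum of the singly ubiquitinated and doubly modified peptidoform
#' ratios — the quantity a phosphatase-treated measurement of the single
#' form reports, independent of phosphorylation status.
#'
#' @param single,double non-negative light/heavy ratios of the two forms.
#' @return `single + double`.
#' @examples
#' total_modified_pool(0.27, 0.034)  # 0.304
#' @export
total_modified_pool <- function(single, double) {
  if (any(c(single, double) < 0)) stop("ratios must be non-negative")
  single + double
}

#' Predict the post-phosphatase fold change from untreated peptidoforms
#'
#' Under pool conservation, phosphatase treatment converts the doubly
#' modified form back into the single form, so the treated single-form
#' measurement equals the total pool; the predicted reference/stimulated
#' fold decrease is `(E_single + E_double) / (C_single + C_double)`. A
#' pure conversion event (single decreases, double increases by the same
#' amount) predicts a fold change of exactly 1 even when the single form
#' alone drops by 100%.
#'
#' @param obs a [crosstalk_observation()].
#' @return predicted fold decrease (reference over stimulated).
#' @examples
#' obs <- crosstalk_observation(0.27, 0.034, 0.14, 0.1)
#' predict_phosphatase_fold_change(obs)  # about 1.27
#' @export
predict_phosphatase_fold_change <- function(obs) {
  obs <- .as_crosstalk_obs(obs)
  stim <- total_modified_pool(obs$C_single, obs$C_double)
  if (stim <= 0) stop("stimulated total pool must be positive")
  total_modified_pool(obs$E_single, obs$E_double) / stim
}

#' Decompose an apparent single-form change into conversion and net change
#'
#' Splits the apparent decrease of the singly ubiquitinated form,
#' `delta_apparent = E_single - C_single`, into the conversion component
#' `delta_conversion = C_double - E_double` (molecules that merely gained a
#' phosphate) and the net component
#' `delta_net = (E_single + E_double) - (C_single + C_double)` (true loss
#' of the ubiquitinated pool). The identity
#' `delta_conversion + delta_net = delta_apparent` holds exactly on all
#' inputs.
#'
#' @param obs a [crosstalk_observation()].
#' @param tol absolute ratio tolerance below which a component is treated
#'   as zero (default 0.02 ratio units).
#' @return object of class `crosstalk_decomposition`: the three deltas,
#'   the component fractions of the apparent change, and `mechanism`, one
#'   of `"conversion_only"`, `"net_change_only"`, `"both"`, `"increase"`
#'   (apparent increase of the single form) or `"none"`.
#' @examples
#' decompose_apparent_change(crosstalk_observation(0.27, 0.034, 0.14, 0.1))
#' @export
decompose_apparent_change <- function(obs, tol = 0.02) {
  obs <- .as_crosstalk_obs(obs)
  d_app <- obs$E_single - obs$C_single
  d_conv <- obs$C_double - obs$E_double
  d_net <- total_modified_pool(obs$E_single, obs$E_double) -
    total_modified_pool(obs$C_single, obs$C_double)
  mechanism <- if (d_app < -tol) {
    "increase"
  } else if (d_conv > tol && d_net > tol) {
    "both"
  } else if (d_conv > tol && abs(d_net) <= tol) {
    "conversion_only"
  } else if (d_net > tol && abs(d_conv) <= tol) {
    "net_change_only"
  } else {
    "none"
  }
  structure(list(delta_apparent = d_app, delta_conversion = d_conv,
                 delta_net = d_net,
                 fraction_conversion = if (d_app != 0) d_conv / d_app else NA_real_,
                 fraction_net = if (d_app != 0) d_net / d_app else NA_real_,
                 mechanism = mechanism, tol = tol),
            class = "crosstalk_decomposition")
}

#' @export
print.crosstalk_decomposition <- function(x, ...) {
  cat("Crosstalk decomposition of the apparent single-form change\n")
  cat(sprintf("  apparent change:   %+.4g\n", x$delta_apparent))
  cat(sprintf("  conversion part:   %+.4g (fraction %s)\n", x$delta_conversion,
              format(x$fraction_conversion, digits = 3)))
  cat(sprintf("  net (de)ub part:   %+.4g (fraction %s)\n", x$delta_net,
              format(x$fraction_net, digits = 3)))
  cat("  mechanism:", x$mechanism, "\n")
  invisible(x)
}

#' Check measured phosphatase controls against the conservation model
#'
#' Compares the measured post-phosphatase single-form ratios with the
#' totals predicted from the untreated peptidoforms (`single + double`,
#' per condition) and flags each condition at a relative-discrepancy
#' tolerance.
#'
#' @param obs a [crosstalk_observation()] carrying `E_pptase` and
#'   `C_pptase`.
#' @param tol relative discrepancy tolerance (default 0.15).
#' @return data.frame with one row per condition: `predicted`, `measured`,
#'   `discrepancy` (relative), `pass`; overall flag in attribute `pass`.
#' @export
check_phosphatase_consistency <- function(obs, tol = 0.15) {
  obs <- .as_crosstalk_obs(obs)
  if (any(is.na(c(obs$E_pptase, obs$C_pptase)))) {
    stop("post-phosphatase measurements are required")
  }
  predicted <- c(EGTA = total_modified_pool(obs$E_single, obs$E_double),
                 Ca = total_modified_pool(obs$C_single, obs$C_double))
  measured <- c(EGTA = obs$E_pptase, Ca = obs$C_pptase)
  disc <- abs(measured - predicted) / predicted
  out <- data.frame(condition = names(predicted), predicted = unname(predicted),
                    measured = unname(measured), discrepancy = unname(disc),
                    pass = unname(disc <= tol), stringsAsFactors = FALSE)
  attr(out, "pass") <- all(out$pass)
  out
}
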