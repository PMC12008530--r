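# Cross-method and cross-dataset comparisons: TMT-vs-PRM ratio-compression
# regression, flanking sequence-window site matching, and sites-per-protein
# inventories.

#' Estimate the isobaric ratio-compression factor
#'
#' Ordinary least squares through the origin of one method's log2 fold
#' changes on the other's, over sites quantified by both. With the default
#' orientation (PRM, treated as the accurate reference, regressed on TMT)
#' a slope above 1 measures how strongly TMT underestimates fold changes.
#'
#' @param pairs data.frame with columns `log2fc_tmt` and `log2fc_prm`
#'   (and optionally `site_id`); at least 3 pairs with nonzero spread.
#' @param orientation `"prm_on_tmt"` (default) or `"tmt_on_prm"`.
#' @return object of class `compression_fit`: `slope`, `se`, `r_squared`,
#'   `n`, `orientation`.
#' @export
compression_slope <- function(pairs, orientation = c("prm_on_tmt",
                                                     "tmt_on_prm")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("log2fc_tmt", "log2fc_prm") %in% names(pairs)))
  if (any(!is.finite(pairs$log2fc_tmt)) || any(!is.finite(pairs$log2fc_prm))) {
    stop("paired fold changes must be finite")
  }
  if (nrow(pairs) < 3L) stop("at least 3 paired fold changes are required")
  x <- if (orientation == "prm_on_tmt") pairs$log2fc_tmt else pairs$log2fc_prm
  y <- if (orientation == "prm_on_tmt") pairs$log2fc_prm else pairs$log2fc_tmt
  sxx <- sum(x^2)
  if (sxx == 0) stop("predictor fold changes are all zero; cannot fit")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  n <- length(x)
  se <- sqrt(rss / (n - 1L) / sxx)
  r2 <- 1 - rss / sum(y^2)
  structure(list(slope = slope, se = se, r_squared = r2, n = n,
                 orientation = orientation),
            class = "compression_fit")
}

#' @export
print.compression_fit <- function(x, ...) {
  cat("Fold-change compression regression (through the origin)\n")
  cat(sprintf("  orientation: %s, n = %d\n", x$orientation, x$n))
  cat(sprintf("  slope = %.3f (se %.3f), R^2 = %.3f\n",
              x$slope, x$se, x$r_squared))
  invisible(x)
}

#' @export
coef.compression_fit <- function(object, ...) {
  c(slope = object$slope)
}

#' Build a flanking sequence window around a modified lysine
#'
#' Extracts the `2 * flank_len + 1`-residue window centred on `position`,
#' padding with `'_'` beyond the protein termini (MaxQuant convention,
#' 1-based positions).
#'
#' @param protein_seq protein residue string.
#' @param position 1-based residue index of the modified lysine.
#' @param flank_len flanking residues on each side (default 6).
#' @return the window string; a warning is issued (and the window still
#'   returned) when the centre residue is not `K`.
#' @examples
#' make_sequence_window("MKAAAAAAK", 2, 6)  # "_____MKAAAAAA"
#' @export
make_sequence_window <- function(protein_seq, position, flank_len = 6L) {
  n <- nchar(protein_seq)
  if (position < 1L || position > n) {
    stop("position ", position, " outside protein of length ", n)
  }
  if (substr(protein_seq, position, position) != "K") {
    warning("residue at position ", position, " is not K")
  }
  idx <- (position - flank_len):(position + flank_len)
  chars <- ifelse(idx < 1L | idx > n, "_",
                  substring(protein_seq, pmax(idx, 1L), pmax(idx, 1L)))
  paste0(chars, collapse = "")
}

#' Match ubiquitination sites between datasets by sequence window
#'
#' Two windows match when their centres agree and the Hamming distance over
#' positions where both carry a residue (padding `'_'` is never penalized)
#' is at most `max_mismatches`. Each query window is paired with at most
#' one best target window; ties are broken by lowest distance, then by
#' lexicographic order of the target window. A small mismatch allowance
#' absorbs cross-species substitutions in the flanks.
#'
#' @param setA,setB character vectors of equal-length windows.
#' @param max_mismatches maximum flank mismatches tolerated (default 1).
#' @return list with `matches` (data.frame: window_a, window_b, distance),
#'   `n_matched`, `unmatched_a`, `unmatched_b`.
#' @export
match_site_windows <- function(setA, setB, max_mismatches = 1L) {
  widths <- unique(nchar(c(setA, setB)))
  if (length(widths) > 1L) stop("all windows must have the same length")
  width <- widths
  centre <- (width + 1L) %/% 2L
  a_mat <- do.call(rbind, strsplit(setA, ""))
  b_mat <- do.call(rbind, strsplit(setB, ""))
  matches <- data.frame(window_a = character(0), window_b = character(0),
                        distance = integer(0), stringsAsFactors = FALSE)
  used_b <- logical(length(setB))
  for (i in seq_along(setA)) {
    a <- a_mat[i, ]
    informative <- t(b_mat) != "_" & a != "_"
    dist <- colSums((t(b_mat) != a) & informative)
    ok <- b_mat[, centre] == a[centre] & dist <= max_mismatches
    if (!any(ok)) next
    cand <- which(ok)
    cand <- cand[order(dist[cand], setB[cand])]
    best <- cand[1L]
    used_b[best] <- TRUE
    matches <- rbind(matches,
                     data.frame(window_a = setA[i], window_b = setB[best],
                                distance = as.integer(dist[best]),
                                stringsAsFactors = FALSE))
  }
  list(matches = matches, n_matched = nrow(matches),
       unmatched_a = setdiff(setA, matches$window_a),
       unmatched_b = setB[!used_b])
}

#' Rank proteins by their number of ubiquitination sites
#'
#' Counts distinct (protein, position) pairs per protein and returns the
#' inventory sorted by descending site count, ties broken by accession.
#'
#' @param rows site-table data.frame with `protein_id` and `position`.
#' @return data.frame with columns `protein_id`, `n_sites`, `rank`.
#' @export
sites_per_protein_rank <- function(rows) {
  if (nrow(rows) == 0L) {
    return(data.frame(protein_id = character(0), n_sites = integer(0),
                      rank = integer(0)))
  }
  uniq <- unique(rows[c("protein_id", "position")])
  counts <- table(uniq$protein_id)
  out <- data.frame(protein_id = names(counts),
                    n_sites = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sites, out$protein_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
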