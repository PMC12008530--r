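#' @importFrom stats median pt var setNames coef rnorm runif rexp rbinom plogis
#' @importFrom stats model.matrix medpolish
#' @importFrom graphics abline plot
#' @importFrom utils read.delim write.table
NULL

# canonical internal column names for the two tabular dialects
.site_cols <- c("site_id", "protein_id", "position", "sequence_window",
                "localization_prob", "is_reverse", "is_contaminant")

.transition_cols <- c("peptide_seq", "peptidoform", "label", "fragment_id",
                      "peak_area", "condition", "bio_replicate", "injection",
                      "batch", "phosphatase_treated")

# MaxQuant-style header -> internal name, for the GlyGly site table dialect
.site_header_map <- c(
  "id" = "site_id",
  "Protein" = "protein_id",
  "Position" = "position",
  "Sequence window" = "sequence_window",
  "Localization prob" = "localization_prob",
  "Reverse" = "is_reverse",
  "Potential contaminant" = "is_contaminant"
)

.reporter_cols <- function(n_channels) {
  paste0("reporter_intensity_", seq_len(n_channels))
}

.site_file_reporter_cols <- function(n_channels) {
  paste("Reporter intensity corrected", seq_len(n_channels))
}

#' Read a MaxQuant-style GlyGly site table
#'
#' Parses a tab-separated site table into one row per ubiquitination site.
#' Decoy status is taken from the "+"-style `Reverse` / `Potential
#' contaminant` columns and, additionally, from `REV__` / `CON__` accession
#' prefixes — either marks the row. Empty intensity cells are read as exact
#' zeros (the left-censored missing-value convention), never as `NA`.
#'
#' Rows that violate the site-table invariants (sequence window not
#' `2 * flank + 1` characters with the modified lysine centred, localization
#' probability outside \[0, 1\], position below 1, or a non-numeric
#' intensity cell) are quarantined, not silently dropped: they are returned
#' in the `rejected` attribute together with the 1-based file line number
#' and a reason.
#'
#' @param path path to a tab-separated site table.
#' @param n_channels number of reporter channels expected (default 6).
#' @param flank_len flanking residues expected in the sequence window.
#' @return a data.frame with columns `site_id`, `protein_id`, `position`,
#'   `sequence_window`, `localization_prob`, `is_reverse`,
#'   `is_contaminant` and `reporter_intensity_1 ... n_channels`, with a
#'   `rejected` attribute (data.frame of line, site_id, reason).
#' @export
read_sites_table <- function(path, n_channels = 6L, flank_len = 6L) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
  needed <- c(names(.site_header_map), .site_file_reporter_cols(n_channels))
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("site table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }

  out <- data.frame(
    site_id = raw[["id"]],
    protein_id = raw[["Protein"]],
    position = suppressWarnings(as.integer(raw[["Position"]])),
    sequence_window = raw[["Sequence window"]],
    localization_prob = suppressWarnings(as.numeric(raw[["Localization prob"]])),
    is_reverse = raw[["Reverse"]] == "+" | startsWith(raw[["Protein"]], "REV__"),
    is_contaminant = raw[["Potential contaminant"]] == "+" |
      startsWith(raw[["Protein"]], "CON__"),
    stringsAsFactors = FALSE
  )
  bad_intensity <- rep(FALSE, nrow(out))
  for (j in seq_len(n_channels)) {
    cell <- raw[[.site_file_reporter_cols(n_channels)[j]]]
    val <- suppressWarnings(as.numeric(cell))
    val[!nzchar(trimws(cell))] <- 0            # empty cell -> missing -> 0
    bad_intensity <- bad_intensity | (nzchar(trimws(cell)) & is.na(val))
    out[[.reporter_cols(n_channels)[j]]] <- val
  }

  width <- 2L * flank_len + 1L
  reason <- character(nrow(out))
  flag <- function(cond, msg) {
    cond <- !is.na(cond) & cond
    reason[cond & !nzchar(reason)] <<- msg
  }
  flag(bad_intensity, "non-numeric intensity")
  flag(is.na(out$position) | out$position < 1L, "invalid position")
  flag(nchar(out$sequence_window) != width,
       sprintf("sequence window not %d characters", width))
  flag(nchar(out$sequence_window) == width &
         substr(out$sequence_window, flank_len + 1L, flank_len + 1L) != "K",
       "modified residue not a centred K")
  flag(is.na(out$localization_prob) | out$localization_prob < 0 |
         out$localization_prob > 1, "localization probability outside [0,1]")

  bad <- nzchar(reason)
  rejected <- data.frame(line = which(bad) + 1L,   # +1 for the header line
                         site_id = out$site_id[bad],
                         reason = reason[bad],
                         stringsAsFactors = FALSE)
  kept <- out[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "rejected") <- rejected
  kept
}

#' Write a site table in the MaxQuant-style dialect
#'
#' Inverse of [read_sites_table()]: flag columns are written as `"+"` /
#' `""`, zero intensities as `0`. The written file reads back to the same
#' data frame.
#'
#' @param sites data.frame as returned by [read_sites_table()] or
#'   [simulate_tmt_experiment()].
#' @param path output path (tab-separated, UTF-8).
#' @return `path`, invisibly.
#' @export
write_sites_table <- function(sites, path) {
  n_channels <- sum(startsWith(names(sites), "reporter_intensity_"))
  out <- data.frame(
    id = sites$site_id,
    Protein = sites$protein_id,
    Position = sites$position,
    `Sequence window` = sites$sequence_window,
    `Localization prob` = .num_str(sites$localization_prob),
    Reverse = ifelse(sites$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(sites$is_contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(n_channels)) {
    out[[.site_file_reporter_cols(n_channels)[j]]] <-
      .num_str(sites[[.reporter_cols(n_channels)[j]]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a Skyline-style PRM transition report
#'
#' Accepts comma- or tab-separated files (the delimiter is sniffed from the
#' header line). Every light transition is expected to have a heavy partner
#' with the same (peptide, peptidoform, phosphatase, fragment, condition,
#' replicate, injection, batch) key; unpaired keys are reported in the
#' `unpaired` attribute with a warning, never silently dropped. Rows with a
#' negative peak area are quarantined into the `rejected` attribute.
#'
#' @param path path to a delimited transition report.
#' @return data.frame with columns `peptide_seq`, `peptidoform`, `label`,
#'   `fragment_id`, `peak_area`, `condition`, `bio_replicate`, `injection`,
#'   `batch`, `phosphatase_treated`; attributes `rejected` and `unpaired`.
#' @export
read_transition_report <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  missing <- setdiff(.transition_cols, names(raw))
  if (length(missing) > 0L) {
    stop("transition report is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- raw[.transition_cols]
  bad_label <- !out$label %in% c("light", "heavy")
  if (any(bad_label)) {
    stop("unknown isotope label value(s): ",
         paste(unique(out$label[bad_label]), collapse = ", "))
  }
  out$peak_area <- as.numeric(out$peak_area)
  out$bio_replicate <- as.integer(out$bio_replicate)
  out$injection <- as.integer(out$injection)
  out$batch <- as.integer(out$batch)
  out$phosphatase_treated <- as.logical(out$phosphatase_treated)

  bad <- is.na(out$peak_area) | out$peak_area < 0
  rejected <- data.frame(line = which(bad) + 1L,
                         reason = rep("negative or non-numeric peak area",
                                      sum(bad)),
                         stringsAsFactors = FALSE)
  kept <- out[!bad, , drop = FALSE]
  rownames(kept) <- NULL

  key <- interaction(kept[setdiff(.transition_cols, c("label", "peak_area"))],
                     drop = TRUE)
  has_light <- tapply(kept$label == "light", key, any)
  has_heavy <- tapply(kept$label == "heavy", key, any)
  unpaired <- names(has_light)[!(has_light & has_heavy)]
  if (length(unpaired) > 0L) {
    warning(length(unpaired), " transition key(s) lack a light/heavy partner")
  }
  attr(kept, "rejected") <- rejected
  attr(kept, "unpaired") <- unpaired
  kept
}

#' Write a PRM transition report
#'
#' @param transitions data.frame in the layout of
#'   [read_transition_report()].
#' @param path output path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(transitions, path, sep = ",") {
  out <- transitions[.transition_cols]
  out$peak_area <- .num_str(out$peak_area)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write differential-testing results
#'
#' Writes a tab-separated results table with a fixed column order
#' (`id`, `log2FC`, `statistic`, `p`, `q`, `call`). Numbers are written
#' with 12 significant digits so the file round-trips to within 1e-12
#' relative precision.
#'
#' @param stats data.frame carrying at least the columns above (extra
#'   columns are ignored).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(stats, path) {
  cols <- c("id", "log2FC", "statistic", "p", "q", "call")
  missing <- setdiff(cols, names(stats))
  if (length(missing) > 0L) {
    stop("results are missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- stats[cols]
  for (nm in c("log2FC", "statistic", "p", "q")) out[[nm]] <- .num_str(out[[nm]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path path to a results TSV.
#' @return data.frame with columns `id`, `log2FC`, `statistic`, `p`, `q`,
#'   `call`.
#' @export
read_results <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character", call = "character"))
  out
}

# decimal string with 12 significant digits; NA -> "NA"
.num_str <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", as.numeric(x)))
}

#' Write a machine-readable run manifest
#'
#' Records the parameters, seed and software versions of a pipeline run as
#' JSON next to its outputs, so a run can be reproduced exactly.
#'
#' @param path output path for the JSON manifest.
#' @param params named list of parameters (e.g. a `pipeline_config`).
#' @param seed integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, seed) {
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = unclass(params),
    versions = list(
      R = paste(R.version$major, R.version$minor, sep = "."),
      diglyq = as.character(utils::packageVersion("diglyq"))
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
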