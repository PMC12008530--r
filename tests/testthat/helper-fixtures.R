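# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# site-table data.frame in the internal layout, 6 channels
make_site_rows <- function(n = 3L,
                           intensities = NULL,
                           localization_prob = rep(0.95, n),
                           is_contaminant = rep(FALSE, n),
                           is_reverse = rep(FALSE, n),
                           protein_id = sprintf("P%05d", seq_len(n)),
                           position = seq_len(n) + 10L) {
  if (is.null(intensities)) {
    intensities <- matrix(1000 + seq_len(n * 6L), nrow = n)
  }
  out <- data.frame(
    site_id = sprintf("s%03d", seq_len(n)),
    protein_id = protein_id,
    position = position,
    sequence_window = replicate(n, paste0(
      paste(sample(LETTERS[1:8], 6, replace = TRUE), collapse = ""), "K",
      paste(sample(LETTERS[1:8], 6, replace = TRUE), collapse = ""))),
    localization_prob = localization_prob,
    is_reverse = is_reverse,
    is_contaminant = is_contaminant,
    stringsAsFactors = FALSE
  )
  for (j in 1:6) out[[paste0("reporter_intensity_", j)]] <- intensities[, j]
  out
}

default_design <- function(batch = 1L) {
  tmt_design(truth_params(n_sites = 10L, n_regulated = 0L), batch = batch)
}

# paired light/heavy transition rows for one peptide
make_transitions <- function(peptide = "PEPTIDEK[GG]R",
                             heavy_areas,
                             ratio = 0.5,
                             condition = "EGTA",
                             bio_replicate = 1L,
                             injection = 1L,
                             batch = 1L,
                             light_areas = heavy_areas * ratio) {
  k <- length(heavy_areas)
  data.frame(
    peptide_seq = peptide,
    peptidoform = "ub_only",
    label = rep(c("light", "heavy"), each = k),
    fragment_id = rep(paste0("y", seq_len(k) + 2L), 2L),
    peak_area = c(light_areas, heavy_areas),
    condition = condition,
    bio_replicate = bio_replicate,
    injection = injection,
    batch = batch,
    phosphatase_treated = FALSE,
    stringsAsFactors = FALSE
  )
}

# independent brute-force oracle for window matching: all-pairs scan,
# written without reference to the implementation
oracle_match_windows <- function(a, b, max_mm) {
  centre <- (nchar(a[1]) + 1L) %/% 2L
  n_matched <- 0L
  pairs <- list()
  for (wa in a) {
    best <- NULL
    best_d <- Inf
    ca <- strsplit(wa, "")[[1]]
    for (wb in sort(b)) {            # lexicographic tie-break by target
      cb <- strsplit(wb, "")[[1]]
      if (ca[centre] != cb[centre]) next
      use <- ca != "_" & cb != "_"
      d <- sum(ca[use] != cb[use])
      if (d <= max_mm && d < best_d) {
        best <- wb
        best_d <- d
      }
    }
    if (!is.null(best)) {
      n_matched <- n_matched + 1L
      pairs[[length(pairs) + 1L]] <- c(wa, best, best_d)
    }
  }
  list(n_matched = n_matched, pairs = pairs)
}

random_windows <- function(n, width = 13L) {
  aa <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]
  sapply(seq_len(n), function(i) {
    w <- sample(aa, width, replace = TRUE)
    w[(width + 1L) %/% 2L] <- "K"
    paste0(w, collapse = "")
  })
}
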