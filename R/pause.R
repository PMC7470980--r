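# A-site offset calibration and pause scores.
#
# The A-site of the ribosome producing a footprint sits a fixed number of
# nucleotides upstream of the footprint's 3' end; the offset (11 nt for the
# data this models) is calibrated from start/stop-anchored metagene
# profiles. Pause score at a nucleotide = its density divided by the mean
# density over the gene's trimmed analysis window, so every profile
# averages to 1 over the window.

#' Start- or stop-anchored metagene density profile
#'
#' Averages RPM density across included ORFs at each offset relative to the
#' anchor. Anchor position 0 is the first nucleotide of the start codon
#' (`anchor = "start"`) or of the stop codon (`anchor = "stop"`). At each
#' offset the mean is taken over the ORFs long enough to contain that
#' position.
#'
#' @param density A `ribo_density` tibble.
#' @param windows An `orf_windows` tibble naming the included ORFs (only its
#'   `orf_id` and `length` columns are used).
#' @param anchor `"start"` or `"stop"`.
#' @param offsets Integer vector of offsets relative to the anchor.
#' @return Tibble of class `ribo_metagene`: `anchor`, `offset`,
#'   `mean_density`, `n_orfs`.
#' @export
metagene_profile <- function(density, windows,
                             anchor = c("start", "stop"),
                             offsets = if (anchor[1] == "start") 0:30 else -30:2) {
  anchor <- match.arg(anchor)
  d <- density |>
    inner_join(as_tibble(windows)[, c("orf_id", "length")], by = "orf_id")
  pos_of <- function(off, len) if (anchor == "start") off else len - 3L + off
  out <- lapply(offsets, function(off) {
    p <- pos_of(off, d$length)
    sel <- d$position == p  # positions outside [0, len) never match
    in_range <- p >= 0 & p < d$length
    n_orfs <- length(unique(d$orf_id[in_range]))
    tibble(
      anchor = anchor, offset = off,
      mean_density = if (n_orfs == 0) NA_real_ else
        sum(d$rpm[sel]) / n_orfs,
      n_orfs = n_orfs
    )
  }) |> list_rbind()
  class(out) <- c("ribo_metagene", class(out))
  out
}

#' Calibrate the 3'-end to A-site offset from metagene profiles
#'
#' Builds the start-anchored metagene profile and finds the candidate
#' offset at which average density first steps up from the upstream
#' baseline: the position where the 3' ends of initiation-region footprints
#' accumulate, i.e. the A-site-to-3'-end shift. Ties go to the smaller
#' candidate. The stop-anchored profile provides a reading-frame
#' consistency check: the 3'-most position carrying density upstream of the
#' stop codon must agree with the calibrated offset modulo 3 (ORF-local
#' tracks truncate footprints whose 3' ends fall past the stop).
#'
#' @param density A `ribo_density` tibble.
#' @param windows An `orf_windows` tibble of included ORFs (>= 10 required).
#' @param candidate_range Integer candidates for the offset, default 5--20 nt.
#' @return An object of class `ribo_offset_calibration`: list with `offset`,
#'   `start_profile`, `stop_profile`, `scores` (per-candidate step height),
#'   `stop_frame_consistent`.
#' @export
calibrate_offset <- function(density, windows, candidate_range = 5:20) {
  if (nrow(windows) < 10) {
    abort(sprintf("offset calibration needs >= 10 included ORFs, got %d",
                  nrow(windows)))
  }
  cand <- sort(unique(as.integer(candidate_range)))
  if (min(cand) < 3) abort("candidate offsets must be >= 3")
  start_prof <- metagene_profile(density, windows, "start",
                                 offsets = 0:(max(cand) + 2L))
  m <- start_prof$mean_density
  # density at the candidate offset itself minus the mean over the three
  # positions upstream: 3'-end pileups are codon-periodic, so a 1-nt-wide
  # contrast is needed to resolve the onset position exactly
  step <- vapply(cand, function(dd) {
    m[dd + 1] - mean(m[dd + (-2:0)])  # m[i] is offset i-1
  }, numeric(1))
  overall <- mean(m, na.rm = TRUE)
  if (!any(is.finite(step)) || overall == 0 ||
      max(step, na.rm = TRUE) <= 0.5 * overall) {
    abort(paste0(
      "flat metagene profile: no discernible initiation onset; ",
      "supply the A-site offset manually"))
  }
  best <- cand[which.max(step)]  # which.max takes the first (smallest) on ties
  stop_prof <- metagene_profile(density, windows, "stop",
                                offsets = -(max(cand) + 3L):2L)
  nz <- stop_prof$offset[!is.na(stop_prof$mean_density) &
                           stop_prof$mean_density > 0]
  frame_ok <- if (length(nz) == 0) NA else (max(nz) %% 3L) == (best %% 3L)
  if (isFALSE(frame_ok)) {
    warn(sprintf(
      "stop-anchored profile frame-inconsistent with calibrated offset %d", best))
  }
  structure(list(
    offset = best,
    start_profile = start_prof,
    stop_profile = stop_prof,
    scores = tibble(candidate = cand, step = step),
    stop_frame_consistent = frame_ok
  ), class = "ribo_offset_calibration")
}

#' @export
print.ribo_offset_calibration <- function(x, ...) {
  cat("A-site offset calibration\n")
  cat("  calibrated 3'-end offset:", x$offset, "nt\n")
  cat("  stop-anchor frame consistent:", x$stop_frame_consistent, "\n")
  invisible(x)
}

#' Per-nucleotide pause scores over trimmed analysis windows
#'
#' Divides each nucleotide's density by the mean density over the ORF's
#' analysis window; scores therefore average to exactly 1 over the window
#' and are invariant to library-depth rescaling.
#'
#' @param density A `ribo_density` tibble.
#' @param windows An `orf_windows` tibble (from [filter_orfs()]).
#' @return Tibble of class `ribo_pause_profiles`: `orf_id`, `position`
#'   (ORF-local, within the window), `score`.
#' @export
pause_scores <- function(density, windows) {
  d <- density |>
    inner_join(as_tibble(windows)[, c("orf_id", "window_start", "window_end")],
               by = "orf_id") |>
    filter(.data$position >= .data$window_start,
           .data$position < .data$window_end)
  means <- d |>
    group_by(.data$orf_id) |>
    summarise(mean_rpm = mean(.data$rpm), .groups = "drop")
  zero <- means$orf_id[means$mean_rpm == 0]
  if (length(zero) > 0) {
    abort(sprintf(
      "ORF '%s' has zero density in its analysis window; it should have been filtered out",
      zero[1]))
  }
  out <- d |>
    inner_join(means, by = "orf_id") |>
    mutate(score = .data$rpm / .data$mean_rpm) |>
    select(all_of(c("orf_id", "position", "score")))
  attr(out, "windows") <- as_tibble(windows)
  class(out) <- c("ribo_pause_profiles", class(out))
  out
}

#' Mean A-site pause score per codon and per amino acid
#'
#' A footprint 3' end at ORF-local position p reports an A-site whose first
#' nucleotide is at p - offset; equivalently, the codon starting at a is
#' scored by the mean of the three per-nucleotide pause scores at
#' a + offset .. a + offset + 2. Occurrences whose shifted positions fall
#' outside the analysis window are skipped (counted in the `n_skipped`
#' attribute). Stop codons are excluded.
#'
#' @param profiles A `ribo_pause_profiles` tibble from [pause_scores()].
#' @param orfs The `orf_annotations` (for codon identities).
#' @param offset The calibrated 3'-end to A-site offset in nt.
#' @param top_n Optionally restrict to the `top_n` ORFs with the highest
#'   mean density per codon (requires `windows` attribute carrying
#'   `mean_count_per_codon`); default uses all ORFs in `profiles`.
#' @return Tibble of class `ribo_codon_pause`: `codon`, `aa`, `aa3`,
#'   `n_occurrences`, `mean_pause_score`, sorted by decreasing score.
#' @export
codon_pause_table <- function(profiles, orfs, offset, top_n = NULL) {
  windows <- attr(profiles, "windows", exact = TRUE)
  ids <- unique(profiles$orf_id)
  if (!is.null(top_n)) {
    if (is.null(windows) || !("mean_count_per_codon" %in% names(windows))) {
      abort("top_n filtering needs window metadata from filter_orfs()")
    }
    ranked <- windows |>
      filter(.data$orf_id %in% ids) |>
      arrange(dplyr::desc(.data$mean_count_per_codon))
    ids <- ranked$orf_id[seq_len(min(top_n, nrow(ranked)))]
  }
  sc <- sense_codons()
  orfs <- as_tibble(orfs)
  n_skipped <- 0L
  rows <- lapply(ids, function(id) {
    seq_o <- orfs$sequence[orfs$orf_id == id]
    len <- nchar(seq_o)
    p <- profiles[profiles$orf_id == id, ]
    lookup <- rep(NA_real_, len)
    lookup[p$position + 1L] <- p$score
    cods <- split_codons(seq_o)
    a <- 3L * (seq_along(cods) - 1L)          # first nt of each codon
    shifted <- a + offset
    s1 <- lookup[shifted + 1L]
    s2 <- lookup[shifted + 2L]
    s3 <- lookup[shifted + 3L]
    occ <- (s1 + s2 + s3) / 3
    sense <- !(cods %in% STOP_CODONS)
    usable <- sense & !is.na(occ) & shifted + 3L <= len
    n_skipped <<- n_skipped + sum(sense & !usable)
    tibble(codon = cods[usable], score = occ[usable])
  }) |> list_rbind()
  if (nrow(rows) == 0) abort("no codon occurrences fall inside the analysis windows")
  out <- rows |>
    group_by(.data$codon) |>
    summarise(n_occurrences = n(),
              mean_pause_score = mean(.data$score), .groups = "drop") |>
    inner_join(sc, by = "codon") |>
    select(all_of(c("codon", "aa", "aa3", "n_occurrences",
                    "mean_pause_score"))) |>
    arrange(dplyr::desc(.data$mean_pause_score))
  attr(out, "n_skipped") <- n_skipped
  attr(out, "offset") <- offset
  class(out) <- c("ribo_codon_pause", class(out))
  out
}

#' Aggregate a codon pause table per amino acid
#'
#' The amino-acid score is the occurrence-weighted mean of its codons'
#' scores.
#'
#' @param codon_table A `ribo_codon_pause` tibble.
#' @return Tibble: `aa`, `aa3`, `n_occurrences`, `mean_pause_score`, sorted
#'   by decreasing score.
#' @export
aa_pause_table <- function(codon_table) {
  codon_table |>
    as_tibble() |>
    group_by(.data$aa, .data$aa3) |>
    summarise(
      mean_pause_score = sum(.data$mean_pause_score * .data$n_occurrences) /
        sum(.data$n_occurrences),
      n_occurrences = sum(.data$n_occurrences),
      .groups = "drop"
    ) |>
    select(all_of(c("aa", "aa3", "n_occurrences", "mean_pause_score"))) |>
    arrange(dplyr::desc(.data$mean_pause_score))
}

#' A-site position from a toeprint (reverse-transcriptase stall) position
#'
#' In toeprinting, reverse transcriptase stalls a fixed distance downstream
#' of the codon in the A-site of the arrested ribosome: the first
#' nucleotide of the A-site codon lies `offset` (13) nt upstream of the
#' stall position. Coordinates are 1-based and the same system is returned.
#'
#' @param stall_position 1-based position(s) of reverse-transcriptase stall.
#' @param offset Distance in nt (default 13).
#' @return `stall_position - offset` (vectorised).
#' @export
toeprint_asite <- function(stall_position, offset = 13L) {
  out <- stall_position - offset
  if (any(out < 1)) {
    abort("stall position must exceed the toeprint offset (result would be < 1)")
  }
  out
}
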