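# Footprint alignments: IO, read-level filters, 3'-end density, ORF filters.
#
# A footprint alignment is identified by the genomic coordinate of its
# 3'-most aligned base (0-based) plus strand and length. Density is the
# per-nucleotide count of footprint 3' ends, normalised to reads per million
# uniquely mapped (RPM).

#' Read a BED-like footprint alignment table
#'
#' @param path Tab-separated file with header columns `contig`, `pos3`
#'   (0-based genome coordinate of the 3'-most aligned base), `strand`,
#'   `length`, `read_id`. `#` lines are comments.
#' @return A tibble with those columns.
#' @export
read_footprints <- function(path) {
  tab <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      contig = readr::col_character(),
      pos3 = readr::col_integer(),
      strand = readr::col_character(),
      length = readr::col_integer(),
      read_id = readr::col_character()
    ),
    progress = FALSE
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed alignment row at line %d of '%s'",
                  prob$row[1], path))
  }
  if (any(tab$length < 1)) abort("alignment length must be >= 1")
  tab
}

#' Filter footprint alignments by read length
#'
#' Retains alignments with `min_len <= length <= max_len` (both boundaries
#' inclusive): reads shorter than 15 nt or longer than 40 nt are excluded by
#' default. Attaches a [filter_report()].
#'
#' @param alignments Footprint alignment tibble (see [read_footprints()]).
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return The retained alignments, with a `filter_report` attribute.
#' @export
filter_reads_by_length <- function(alignments, min_len = 15L, max_len = 40L) {
  if (min_len > max_len) {
    abort(sprintf("min_len (%d) exceeds max_len (%d)", min_len, max_len))
  }
  keep <- alignments$length >= min_len & alignments$length <= max_len
  out <- alignments[keep, , drop = FALSE]
  report <- tibble(
    n_reads_in = nrow(alignments),
    n_reads_kept = nrow(out),
    n_too_short = sum(alignments$length < min_len),
    n_too_long = sum(alignments$length > max_len)
  )
  attr(out, "filter_report") <- report
  out
}

#' Per-nucleotide 3'-end footprint density over ORFs
#'
#' For every nucleotide of every ORF, counts footprint 3' ends mapping to
#' that genomic position on the same strand, and normalises by the total
#' number of retained alignments in millions (RPM). Positions are ORF-local
#' (0 = first nt of the start codon); minus-strand ORFs use coding-strand
#' local coordinates. A read whose 3' end falls in several overlapping
#' same-strand ORFs is counted for each of them (reported in the
#' [filter_report()]).
#'
#' @param alignments Length-filtered footprint alignments. `read_id` values
#'   must be unique (input is assumed uniquely mapped).
#' @param orfs An `orf_annotations` tibble.
#' @return A tibble of class `ribo_density` with columns `orf_id`,
#'   `position`, `count`, `rpm`, one row per ORF nucleotide, plus attributes
#'   `total_mapped` and `filter_report`.
#' @export
compute_density <- function(alignments, orfs) {
  if (nrow(alignments) == 0) {
    abort("no alignments: nothing to normalize (total_mapped = 0)")
  }
  if (anyDuplicated(alignments$read_id)) {
    dup <- alignments$read_id[duplicated(alignments$read_id)][1]
    abort(sprintf(
      "duplicate read_id '%s': input must be uniquely mapped reads", dup))
  }
  total_mapped <- nrow(alignments)
  scale <- total_mapped / 1e6

  # per-contig sorted position index for fast interval queries
  idx <- split(seq_len(nrow(alignments)), alignments$contig)
  sorted <- lapply(idx, function(i) {
    ord <- order(alignments$pos3[i])
    list(pos = alignments$pos3[i][ord],
         strand = alignments$strand[i][ord],
         row = i[ord])
  })

  n_orfs <- nrow(orfs)
  counts_list <- vector("list", n_orfs)
  assigned_rows <- vector("list", n_orfs)
  for (j in seq_len(n_orfs)) {
    len <- orfs$length[j]
    cts <- integer(len)
    s <- sorted[[orfs$contig[j]]]
    if (!is.null(s) && length(s$pos) > 0) {
      lo <- findInterval(orfs$start[j] - 0.5, s$pos) + 1L
      hi <- findInterval(orfs$end[j] - 0.5, s$pos)
      if (hi >= lo) {
        sel <- lo:hi
        same <- s$strand[sel] == orfs$strand[j]
        sel <- sel[same]
        if (length(sel) > 0) {
          local <- if (orfs$strand[j] == "+") {
            s$pos[sel] - orfs$start[j]
          } else {
            (orfs$end[j] - 1L) - s$pos[sel]
          }
          cts <- tabulate(local + 1L, nbins = len)
          assigned_rows[[j]] <- s$row[sel]
        }
      }
    }
    counts_list[[j]] <- cts
  }

  n_assign <- lengths(assigned_rows)
  uniq_reads <- unique(unlist(assigned_rows, use.names = FALSE))
  out <- tibble(
    orf_id = rep(orfs$orf_id, orfs$length),
    position = unlist(lapply(orfs$length, function(l) seq_len(l) - 1L),
                      use.names = FALSE),
    count = unlist(counts_list, use.names = FALSE)
  )
  out$rpm <- out$count / scale
  attr(out, "total_mapped") <- total_mapped
  attr(out, "filter_report") <- tibble(
    n_reads_in = total_mapped,
    n_reads_in_orfs = length(uniq_reads),
    n_assignments = sum(n_assign),
    n_multi_orf_assignments = sum(n_assign) - length(uniq_reads)
  )
  class(out) <- c("ribo_density", class(out))
  out
}

#' Total mapped reads used for RPM normalisation
#' @param density A `ribo_density` tibble.
#' @return Integer library size.
#' @export
total_mapped <- function(density) attr(density, "total_mapped", exact = TRUE)

#' ORF-level inclusion filter and analysis windows
#'
#' Keeps an ORF iff its length is at least `min_len` nt (ORFs shorter than
#' 170 nt are excluded) and its mean raw footprint count per codon over the
#' full ORF is at least `min_density_per_codon` (1 per codon = 0.33 per nt).
#' The count threshold is applied to raw counts, before RPM normalisation,
#' and before end-trimming. Each kept ORF gets a trimmed analysis window
#' `[trim5, length - trim3)` in ORF-local coordinates.
#'
#' @param density A `ribo_density` tibble from [compute_density()].
#' @param orfs The matching `orf_annotations`.
#' @param min_len Minimum ORF length in nt.
#' @param min_density_per_codon Minimum mean raw footprint count per codon.
#' @param trim5,trim3 Nucleotides removed downstream of the start codon and
#'   upstream of the stop codon when forming the analysis window.
#' @return A tibble of class `orf_windows` with columns `orf_id`, `length`,
#'   `window_start`, `window_end`, `mean_count_per_codon`, plus a
#'   `filter_report` attribute.
#' @export
filter_orfs <- function(density, orfs, min_len = 170L,
                        min_density_per_codon = 1, trim5 = 50L, trim3 = 20L) {
  if (trim5 + trim3 >= min_len) {
    abort(sprintf("trim5 + trim3 (%d) must be < min_len (%d)",
                  trim5 + trim3, min_len))
  }
  per_orf <- density |>
    group_by(.data$orf_id) |>
    summarise(total_count = sum(.data$count), .groups = "drop")
  tab <- orfs |>
    as_tibble() |>
    select(all_of(c("orf_id", "length"))) |>
    left_join(per_orf, by = "orf_id") |>
    mutate(
      total_count = dplyr::coalesce(.data$total_count, 0L),
      mean_count_per_codon = .data$total_count / (.data$length / 3)
    )
  long_enough <- tab$length >= min_len
  dense_enough <- tab$mean_count_per_codon >= min_density_per_codon
  kept <- tab[long_enough & dense_enough, , drop = FALSE] |>
    mutate(
      window_start = as.integer(trim5),
      window_end = as.integer(.data$length - trim3)
    ) |>
    select(all_of(c("orf_id", "length", "window_start", "window_end",
                    "mean_count_per_codon")))
  attr(kept, "filter_report") <- tibble(
    n_orfs_in = nrow(tab),
    n_orfs_kept = nrow(kept),
    n_too_short = sum(!long_enough),
    n_low_density = sum(long_enough & !dense_enough)
  )
  class(kept) <- c("orf_windows", class(kept))
  kept
}

#' ORFs passing filters in both conditions
#'
#' @param included_a,included_b Character vectors of ORF ids (or
#'   `orf_windows` tibbles) from two samples.
#' @return Sorted character vector of the intersection; warns when empty.
#' @export
intersect_conditions <- function(included_a, included_b) {
  ids <- function(x) if (is.data.frame(x)) x$orf_id else x
  out <- sort(intersect(ids(included_a), ids(included_b)))
  if (length(out) == 0) {
    warn("no ORFs pass the filters in both conditions; paired analysis will be empty")
  }
  out
}
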