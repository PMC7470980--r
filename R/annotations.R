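# ORF annotations: reading, validation, sequence extraction.
#
# Internally all coordinates are 0-based, half-open [start, end); the
# GFF-like annotation table on disk is 1-based, inclusive (column headers:
# contig, start, end, strand, orf_id). Sequences are stored on the coding
# strand, so a minus-strand ORF's sequence is the reverse complement of the
# genomic slice.

#' Read ORF annotations and extract coding-strand sequences
#'
#' @param path Path to a tab-separated annotation table with header columns
#'   `contig`, `start`, `end`, `strand`, `orf_id`. Lines starting with `#`
#'   are comments. Coordinates are interpreted per `coords`.
#' @param genome Path to a genome FASTA file, or a named character vector of
#'   contig sequences, or a [Biostrings::DNAStringSet].
#' @param coords `"gff"` (default) for 1-based inclusive start/end on disk,
#'   `"bed"` for 0-based half-open.
#' @return A tibble of class `orf_annotations` with columns `orf_id`,
#'   `contig`, `start`, `end` (0-based half-open), `strand`, `length`,
#'   `sequence`, ordered by (contig, start). ORF lengths must be divisible
#'   by 3 and intervals must lie within their contig.
#' @export
read_annotations <- function(path, genome, coords = c("gff", "bed")) {
  coords <- match.arg(coords)
  tab <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      contig = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      strand = readr::col_character(),
      orf_id = readr::col_character()
    ),
    progress = FALSE
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "malformed annotation row at line %d of '%s': %s",
      prob$row[1], path, prob$expected[1]
    ))
  }
  if (coords == "gff") tab$start <- tab$start - 1
  genome <- load_genome(genome)
  orf_annotations(tab, genome)
}

# accept FASTA path / named character / DNAStringSet -> named character
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    nm <- sub("\\s.*$", "", names(gs))
    return(setNames(as.character(gs), nm))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort("`genome` must be a FASTA path, a named character vector, or a DNAStringSet")
}

#' Construct a validated ORF annotation table
#'
#' @param tab A data frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `orf_id`, and optionally `sequence`.
#' @param genome Named character vector of contig sequences; required when
#'   `tab` has no `sequence` column.
#' @return A tibble of class `orf_annotations` (see [read_annotations()]).
#' @export
orf_annotations <- function(tab, genome = NULL) {
  tab <- as_tibble(tab)
  needed <- c("contig", "start", "end", "strand", "orf_id")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tab$orf_id)) {
    dup <- tab$orf_id[duplicated(tab$orf_id)][1]
    abort(sprintf("duplicate orf_id '%s' in annotation set", dup))
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  len <- tab$end - tab$start
  if (any(len <= 0)) abort("ORF end must exceed start")
  bad3 <- which(len %% 3 != 0)
  if (length(bad3) > 0) {
    abort(sprintf("ORF '%s' has length %d nt, not divisible by 3",
                  tab$orf_id[bad3[1]], len[bad3[1]]))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(tab$contig), names(genome))
    if (length(unknown) > 0) {
      abort(sprintf("contig '%s' absent from genome", unknown[1]))
    }
    clen <- nchar(genome)[match(tab$contig, names(genome))]
    oob <- which(tab$start < 0 | tab$end > clen)
    if (length(oob) > 0) {
      abort(sprintf("ORF '%s' [%d, %d) lies outside contig '%s' (length %d)",
                    tab$orf_id[oob[1]], tab$start[oob[1]], tab$end[oob[1]],
                    tab$contig[oob[1]], clen[oob[1]]))
    }
    if (!("sequence" %in% names(tab))) {
      slice <- substr(genome[match(tab$contig, names(genome))],
                      tab$start + 1, tab$end)
      tab$sequence <- ifelse(tab$strand == "+", slice, revcomp(slice))
    }
  }
  if (!("sequence" %in% names(tab))) {
    abort("no `sequence` column and no genome supplied")
  }
  if (any(nchar(tab$sequence) != len)) {
    abort("sequence length must equal end - start")
  }
  out <- tab |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           length = as.integer(.data$end - .data$start)) |>
    select(all_of(c("orf_id", "contig", "start", "end", "strand",
                    "length", "sequence"))) |>
    arrange(.data$contig, .data$start)
  class(out) <- c("orf_annotations", class(out))
  out
}

#' Write an ORF annotation table (GFF-like, 1-based inclusive)
#'
#' @param orfs An `orf_annotations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(orfs, path) {
  lines <- c(
    "# ribopause ORF annotations; coordinates 1-based inclusive",
    paste("contig", "start", "end", "strand", "orf_id", sep = "\t"),
    paste(orfs$contig, orfs$start + 1, orfs$end, orfs$strand, orfs$orf_id,
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write contig sequences as FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70
  )
  invisible(path)
}
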