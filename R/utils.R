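# Shared constants and small helpers.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Sense codons and the amino acids they encode
#'
#' The 61 sense codons (DNA alphabet, coding strand) of the standard genetic
#' code, with one-letter and three-letter amino-acid codes.
#'
#' @return A tibble with columns `codon`, `aa` (one-letter) and `aa3`.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  keep <- gc != "*"
  one <- gc[keep]
  three <- setNames(
    c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
      "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"),
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  )
  tibble(
    codon = names(one),
    aa = unname(one),
    aa3 = unname(three[one])
  ) |>
    arrange(.data$codon)
}

# reverse complement of DNA strings (vectorised)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a coding sequence into consecutive codons
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

# set the RNG state locally when a seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Retrieve the filter report attached to a filtering result
#'
#' Read- and ORF-level filters attach a one-row tibble of input/kept counts
#' (and per-rule rejection counts) to their result.
#'
#' @param x An object returned by [filter_reads_by_length()],
#'   [filter_orfs()] or [compute_density()].
#' @return A tibble of counters, or `NULL` if none is attached.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report", exact = TRUE)
}
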