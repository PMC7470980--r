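# Seeded ribosome footprint simulator.
#
# Generative model: for ORF o and sense codon k (0-based, start codon is
# codon 0), the expected number of footprints with their A-site at codon k
# is proportional to dwell(codon_k) * (1 - q)^k, where q is the per-codon
# premature drop-off probability (memoryless, geometric survival -- the
# simplest model producing a monotone 3'-ward density decline). Counts are
# Poisson. Each footprint's 3' end sits `offset_3prime` nt downstream of
# the first nucleotide of its A-site codon (optionally +/-1 nt jitter), and
# its length is a rounded Gaussian truncated to the admissible range.

#' Simulation configuration
#'
#' @param seed Integer RNG seed.
#' @param n_orfs Number of ORFs to generate.
#' @param orf_length_range Length range in codons (including start and stop).
#' @param codon_usage Named probability vector over the 61 sense codons used
#'   to draw internal codons; defaults to uniform. Must sum to 1.
#' @param dwell_multipliers Named positive vector codon -> relative dwell
#'   time; unnamed codons default to 1.
#' @param dropoff_per_codon Per-codon drop-off probability q in [0, 1).
#' @param offset_3prime Distance in nt from the first nucleotide of the
#'   A-site codon to the footprint 3' end (default 11).
#' @param length_mean,length_sd,length_range Footprint length distribution:
#'   rounded Gaussian truncated to `length_range` (default 15--40 nt).
#' @param depth Expected total footprint count.
#' @param jitter_3prime If `TRUE`, add uniform -1/0/+1 nt jitter to 3' ends.
#' @param both_strands If `TRUE`, alternate ORFs are placed on the minus
#'   strand; by default all ORFs sit on the plus strand.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_orfs = 50L, orf_length_range = c(100L, 200L),
                       codon_usage = NULL, dwell_multipliers = numeric(),
                       dropoff_per_codon = 0, offset_3prime = 11L,
                       length_mean = 25, length_sd = 3,
                       length_range = c(15L, 40L), depth = 1e5,
                       jitter_3prime = FALSE, both_strands = FALSE) {
  codons <- sense_codons()$codon
  if (is.null(codon_usage)) {
    codon_usage <- setNames(rep(1 / length(codons), length(codons)), codons)
  }
  if (!setequal(names(codon_usage), codons)) {
    abort("codon_usage must be named by the 61 sense codons")
  }
  codon_usage <- codon_usage[codons]
  if (abs(sum(codon_usage) - 1) > 1e-8) abort("codon_usage must sum to 1")
  if (any(codon_usage < 0)) abort("codon_usage must be non-negative")
  mult <- setNames(rep(1, length(codons)), codons)
  if (length(dwell_multipliers) > 0) {
    bad <- setdiff(names(dwell_multipliers), codons)
    if (length(bad) > 0) abort(sprintf("unknown codon '%s' in dwell_multipliers", bad[1]))
    if (any(dwell_multipliers <= 0)) abort("dwell multipliers must be > 0")
    mult[names(dwell_multipliers)] <- dwell_multipliers
  }
  if (dropoff_per_codon < 0 || dropoff_per_codon >= 1) {
    abort("dropoff_per_codon must be in [0, 1)")
  }
  if (length(orf_length_range) != 2 || orf_length_range[1] > orf_length_range[2] ||
      orf_length_range[1] < 10) {
    abort("orf_length_range must be an increasing pair of at least 10 codons")
  }
  if (offset_3prime < 0 || offset_3prime >= length_range[1]) {
    abort("offset_3prime must lie in [0, minimum footprint length)")
  }
  structure(list(
    seed = as.integer(seed), n_orfs = as.integer(n_orfs),
    orf_length_range = as.integer(orf_length_range),
    codon_usage = codon_usage, dwell_multipliers = mult,
    dropoff_per_codon = dropoff_per_codon,
    offset_3prime = as.integer(offset_3prime),
    length_mean = length_mean, length_sd = length_sd,
    length_range = as.integer(length_range), depth = depth,
    jitter_3prime = isTRUE(jitter_3prime), both_strands = isTRUE(both_strands)
  ), class = "sim_config")
}

#' Expand amino-acid dwell multipliers to codons
#'
#' Convenience for configurations such as "Gly codons dwell 5x longer":
#' `dwell_for_aa(c(G = 5))` returns the multiplier vector over the four
#' glycine codons.
#'
#' @param aa_multipliers Named numeric vector, names are one-letter
#'   amino-acid codes.
#' @return Named numeric vector codon -> multiplier.
#' @export
dwell_for_aa <- function(aa_multipliers) {
  sc <- sense_codons()
  bad <- setdiff(names(aa_multipliers), sc$aa)
  if (length(bad) > 0) abort(sprintf("unknown amino acid '%s'", bad[1]))
  keep <- sc[sc$aa %in% names(aa_multipliers), ]
  setNames(unname(aa_multipliers[keep$aa]), keep$codon)
}

#' Generate a synthetic ORF set and genome
#'
#' ORFs start with ATG, end with a stop codon, contain no internal stops
#' (internal codons are drawn from `codon_usage` over sense codons only) and
#' have lengths divisible by 3. ORFs are laid head-to-tail on one contig
#' separated by random 60-nt spacers.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with `orfs` (an `orf_annotations` tibble) and `genome`
#'   (named character vector with one contig).
#' @export
generate_orfs <- function(config, seed = config$seed) {
  with_seed(seed, {
    codons <- names(config$codon_usage)
    len_cand <- seq(config$orf_length_range[1], config$orf_length_range[2])
    n_codons <- len_cand[sample.int(length(len_cand), config$n_orfs,
                                    replace = TRUE)]
    seqs <- vapply(n_codons, function(nc) {
      internal <- sample(codons, nc - 2L, replace = TRUE,
                         prob = config$codon_usage)
      paste0("ATG", paste(internal, collapse = ""), "TAA")
    }, character(1))
    spacer <- function() paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                               collapse = "")
    strands <- if (config$both_strands) {
      rep(c("+", "-"), length.out = config$n_orfs)
    } else {
      rep("+", config$n_orfs)
    }
    pieces <- character(2 * config$n_orfs + 1)
    pieces[1] <- spacer()
    starts <- integer(config$n_orfs)
    pos <- nchar(pieces[1])
    for (i in seq_len(config$n_orfs)) {
      genomic <- if (strands[i] == "+") seqs[i] else revcomp(seqs[i])
      pieces[2 * i] <- genomic
      starts[i] <- pos
      pos <- pos + nchar(genomic)
      pieces[2 * i + 1] <- spacer()
      pos <- pos + 60L
    }
    genome <- c(contig_sim = paste(pieces, collapse = ""))
    orfs <- orf_annotations(tibble(
      orf_id = sprintf("orf%03d", seq_len(config$n_orfs)),
      contig = "contig_sim",
      start = starts,
      end = starts + nchar(seqs),
      strand = strands,
      sequence = seqs
    ))
    list(orfs = orfs, genome = genome)
  })
}

#' Simulate aligned ribosome footprints
#'
#' Draws per-codon footprint counts Poisson with mean proportional to
#' `dwell(codon) * (1 - q)^codon_index`, places each footprint's 3' end at
#' `offset_3prime` nt downstream of its A-site codon's first nucleotide, and
#' samples footprint lengths from the configured distribution (resampling
#' any draw not exceeding the offset). The returned truth table records each
#' read's A-site codon index for parameter-recovery tests.
#'
#' @param orfs An `orf_annotations` tibble (typically from [generate_orfs()]).
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return List with `alignments` (tibble: `contig`, `pos3`, `strand`,
#'   `length`, `read_id`) and `truth` (tibble: `read_id`, `orf_id`,
#'   `a_site_codon` 0-based).
#' @export
simulate_footprints <- function(orfs, config, seed = config$seed + 1L) {
  with_seed(seed, {
    n_sense <- orfs$length %/% 3L - 1L  # sense codons incl. start, excl. stop
    q <- config$dropoff_per_codon
    per_orf <- lapply(seq_len(nrow(orfs)), function(j) {
      cods <- split_codons(orfs$sequence[j])[seq_len(n_sense[j])]
      k <- seq_len(n_sense[j]) - 1L
      w <- unname(config$dwell_multipliers[cods]) * (1 - q)^k
      list(w = w, k = k)
    })
    w_all <- unlist(lapply(per_orf, `[[`, "w"), use.names = FALSE)
    lambda <- config$depth * w_all / sum(w_all)
    counts <- rpois(length(lambda), lambda)

    orf_idx <- rep(seq_len(nrow(orfs)), n_sense)
    k_all <- unlist(lapply(per_orf, `[[`, "k"), use.names = FALSE)
    reads_orf <- rep(orf_idx, counts)
    reads_k <- rep(k_all, counts)
    n_reads <- length(reads_k)
    if (n_reads == 0) {
      return(list(
        alignments = tibble(contig = character(), pos3 = integer(),
                            strand = character(), length = integer(),
                            read_id = character()),
        truth = tibble(read_id = character(), orf_id = character(),
                       a_site_codon = integer())
      ))
    }
    local3 <- 3L * reads_k + config$offset_3prime
    if (config$jitter_3prime) {
      local3 <- local3 + sample(c(-1L, 0L, 1L), n_reads, replace = TRUE)
    }
    pos3 <- ifelse(orfs$strand[reads_orf] == "+",
                   orfs$start[reads_orf] + local3,
                   orfs$end[reads_orf] - 1L - local3)
    len <- as.integer(round(rnorm(n_reads, config$length_mean, config$length_sd)))
    bad <- which(len < config$length_range[1] | len > config$length_range[2] |
                   len <= config$offset_3prime)
    while (length(bad) > 0) {
      len[bad] <- as.integer(round(rnorm(length(bad), config$length_mean,
                                         config$length_sd)))
      bad <- bad[len[bad] < config$length_range[1] |
                   len[bad] > config$length_range[2] |
                   len[bad] <= config$offset_3prime]
    }
    ord <- sample.int(n_reads)  # shuffle so read ids carry no positional info
    read_id <- sprintf("sim%08d", seq_len(n_reads))
    alignments <- tibble(
      contig = orfs$contig[reads_orf][ord],
      pos3 = as.integer(pos3[ord]),
      strand = orfs$strand[reads_orf][ord],
      length = len[ord],
      read_id = read_id
    )
    truth <- tibble(
      read_id = read_id,
      orf_id = orfs$orf_id[reads_orf][ord],
      a_site_codon = reads_k[ord]
    )
    list(alignments = alignments, truth = truth)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the FASTA + GFF-like + BED-like files consumed by the readers, the
#' truth table, and a flat key=value config echo.
#'
#' @param sim Result of [simulate_footprints()].
#' @param orfs,genome From [generate_orfs()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @param config The [sim_config()] used (echoed into `<prefix>_config.txt`).
#' @return Named character vector of the paths written.
#' @export
write_simulated_dataset <- function(sim, orfs, genome, dir, prefix = "sim",
                                    config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, paste0(prefix, "_genome.fa")),
    annotations = file.path(dir, paste0(prefix, "_orfs.tsv")),
    alignments = file.path(dir, paste0(prefix, "_footprints.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    config = file.path(dir, paste0(prefix, "_config.txt"))
  )
  write_genome_fasta(genome, paths["genome"])
  write_annotations(orfs, paths["annotations"])
  al <- sim$alignments
  writeLines(c(
    "# ribopause simulated footprints; pos3 is 0-based",
    paste("contig", "pos3", "strand", "length", "read_id", sep = "\t"),
    paste(al$contig, al$pos3, al$strand, al$length, al$read_id, sep = "\t")
  ), paths["alignments"])
  tr <- sim$truth
  writeLines(c(
    "# ribopause simulation truth; a_site_codon is 0-based",
    paste("read_id", "orf_id", "a_site_codon", sep = "\t"),
    paste(tr$read_id, tr$orf_id, tr$a_site_codon, sep = "\t")
  ), paths["truth"])
  if (!is.null(config)) {
    scalars <- config[!names(config) %in% c("codon_usage", "dwell_multipliers")]
    kv <- vapply(names(scalars), function(nm) {
      paste0(nm, "=", paste(scalars[[nm]], collapse = ","))
    }, character(1))
    non_unit <- config$dwell_multipliers[config$dwell_multipliers != 1]
    if (length(non_unit) > 0) {
      kv <- c(kv, paste0("dwell_multipliers=",
                         paste(names(non_unit), non_unit, sep = ":",
                               collapse = ",")))
    }
    writeLines(kv, paths["config"])
  }
  paths
}
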