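# Builders for small hand-specified objects used across tests.

# a ribo_density tibble from a named list of per-ORF count vectors
density_from_counts <- function(counts, total_mapped = NULL) {
  if (is.null(total_mapped)) {
    total_mapped <- sum(vapply(counts, sum, numeric(1)))
  }
  out <- dplyr::bind_rows(lapply(names(counts), function(id) {
    tibble::tibble(
      orf_id = id,
      position = seq_along(counts[[id]]) - 1L,
      count = as.integer(counts[[id]])
    )
  }))
  out$rpm <- out$count / (total_mapped / 1e6)
  attr(out, "total_mapped") <- as.integer(total_mapped)
  class(out) <- c("ribo_density", class(out))
  out
}

# an orf_windows tibble for hand-built cases
windows_tbl <- function(orf_id, length, window_start, window_end) {
  out <- tibble::tibble(orf_id = orf_id, length = as.integer(length),
                        window_start = as.integer(window_start),
                        window_end = as.integer(window_end))
  class(out) <- c("orf_windows", class(out))
  out
}

# a ribo_pause_profiles tibble from per-ORF score vectors over given windows
profiles_from_scores <- function(scores, windows) {
  out <- dplyr::bind_rows(lapply(names(scores), function(id) {
    w <- windows[windows$orf_id == id, ]
    tibble::tibble(
      orf_id = id,
      position = seq(w$window_start, w$window_end - 1L),
      score = scores[[id]]
    )
  }))
  attr(out, "windows") <- windows
  class(out) <- c("ribo_pause_profiles", class(out))
  out
}

# a ribo_composition tibble from a matrix (rows = ORFs, cols = bins)
composition_from_matrix <- function(mat) {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("orf%02d", seq_len(nrow(mat)))
  }
  out <- dplyr::bind_rows(lapply(rownames(mat), function(id) {
    tibble::tibble(orf_id = id, bin = seq_len(ncol(mat)),
                   part = unname(mat[id, ]))
  }))
  attr(out, "n_bins") <- ncol(mat)
  class(out) <- c("ribo_composition", class(out))
  out
}

# a ribo_ilr tibble from a coordinate matrix (rows = ORFs)
ilr_from_matrix <- function(mat, basis_id = "custom") {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("orf%02d", seq_len(nrow(mat)))
  }
  out <- dplyr::bind_rows(lapply(rownames(mat), function(id) {
    tibble::tibble(orf_id = id, coord = seq_len(ncol(mat)),
                   value = unname(mat[id, ]))
  }))
  attr(out, "basis_id") <- basis_id
  class(out) <- c("ribo_ilr", class(out))
  out
}

# simulate a dataset and run it through density + ORF filtering
sim_density <- function(seed, ..., min_len = 170L, min_density_per_codon = 1) {
  cfg <- sim_config(seed = seed, ...)
  gen <- generate_orfs(cfg)
  sim <- simulate_footprints(gen$orfs, cfg)
  al <- filter_reads_by_length(sim$alignments)
  dens <- compute_density(al, gen$orfs)
  win <- filter_orfs(dens, gen$orfs, min_len = min_len,
                     min_density_per_codon = min_density_per_codon)
  list(config = cfg, orfs = gen$orfs, genome = gen$genome, sim = sim,
       alignments = al, density = dens, windows = win)
}

# independent reverse-complement oracle (no Biostrings)
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# one paired-composition Hotelling replicate over a fixed ORF set:
# simulate both conditions, run the density -> filter -> bin -> ilr ->
# paired T2 path, return the p-value
hotelling_replicate <- function(gen, cfg_a, cfg_b, seed_a, seed_b) {
  sa <- simulate_footprints(gen$orfs, cfg_a, seed = seed_a)
  sb <- simulate_footprints(gen$orfs, cfg_b, seed = seed_b)
  da <- compute_density(filter_reads_by_length(sa$alignments), gen$orfs)
  db <- compute_density(filter_reads_by_length(sb$alignments), gen$orfs)
  wa <- filter_orfs(da, gen$orfs)
  wb <- filter_orfs(db, gen$orfs)
  ids <- intersect_conditions(wa, wb)
  ca <- bin_composition(da, wa[wa$orf_id %in% ids, ])
  cb <- bin_composition(db, wb[wb$orf_id %in% ids, ])
  paired_hotelling(ilr_transform(ca), ilr_transform(cb))$p_value
}

# codon usage putting total probability f on the four Gly codons
gly_usage <- function(f) {
  sc <- sense_codons()
  gly <- sc$codon[sc$aa == "G"]
  usage <- setNames(rep((1 - f) / (61 - 4), 61), sc$codon)
  usage[gly] <- f / 4
  usage
}
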