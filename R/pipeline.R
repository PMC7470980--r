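# End-to-end two-condition analysis.

#' Pipeline configuration
#'
#' @param annotations Path to the GFF-like ORF table.
#' @param genome Path to the genome FASTA.
#' @param alignments Named list of exactly two BED-like footprint table
#'   paths, e.g. `list(toxin = ..., control = ...)`.
#' @param min_read_len,max_read_len Read length filter bounds (nt).
#' @param min_orf_len Minimum ORF length (nt).
#' @param min_density_per_codon Minimum mean raw footprint count per codon.
#' @param trim5,trim3 Analysis-window end trims (nt).
#' @param n_bins Segments for the compositional analysis.
#' @param alpha Significance level for the paired test report.
#' @param offset `"auto"` to calibrate the A-site offset from the data, or
#'   an integer to force it.
#' @param candidate_range Candidate offsets when `offset = "auto"`.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations, genome, alignments,
                            min_read_len = 15L, max_read_len = 40L,
                            min_orf_len = 170L, min_density_per_codon = 1,
                            trim5 = 50L, trim3 = 20L, n_bins = 10L,
                            alpha = 0.01, offset = "auto",
                            candidate_range = 5:20, seed = 1L,
                            out_dir = NULL) {
  if (!is.list(alignments) || length(alignments) != 2 ||
      is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    abort("paired analysis requires exactly two named conditions in `alignments`")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(list(
    annotations = annotations, genome = genome, alignments = alignments,
    min_read_len = min_read_len, max_read_len = max_read_len,
    min_orf_len = min_orf_len,
    min_density_per_codon = min_density_per_codon,
    trim5 = trim5, trim3 = trim3, n_bins = n_bins, alpha = alpha,
    offset = offset, candidate_range = candidate_range, seed = seed,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full two-condition pause and composition analysis
#'
#' Reads annotations and footprints, applies the read-length and ORF
#' filters per condition, intersects the included ORFs, calibrates the
#' A-site offset (or uses the configured one), computes per-condition codon
#' and amino-acid pause tables, the 10-bin compositional profiles and their
#' geometric means, and the paired Hotelling T2 comparison on ilr
#' coordinates. Deterministic given the inputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `ribopause_run` with elements per stage
#'   (`orfs`, `conditions` (per-condition density/windows/pause tables),
#'   `paired_ids`, `calibration`, `offset`, `compositions`, `gm_profiles`,
#'   `hotelling`, `normality`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  orfs <- stage("annotations",
                read_annotations(config$annotations, config$genome))
  conds <- names(config$alignments)
  per_cond <- lapply(conds, function(cc) {
    al <- stage(paste0("read_footprints[", cc, "]"),
                read_footprints(config$alignments[[cc]]))
    al <- stage(paste0("length_filter[", cc, "]"),
                filter_reads_by_length(al, config$min_read_len,
                                       config$max_read_len))
    read_report <- filter_report(al)
    dens <- stage(paste0("density[", cc, "]"), compute_density(al, orfs))
    win <- stage(paste0("orf_filter[", cc, "]"),
                 filter_orfs(dens, orfs, config$min_orf_len,
                             config$min_density_per_codon,
                             config$trim5, config$trim3))
    list(name = cc, density = dens, windows = win,
         read_report = read_report, orf_report = filter_report(win))
  })
  names(per_cond) <- conds

  paired_ids <- stage("intersect_conditions",
                      intersect_conditions(per_cond[[1]]$windows,
                                           per_cond[[2]]$windows))
  calib <- NULL
  if (identical(config$offset, "auto")) {
    calib <- stage("calibrate_offset",
                   calibrate_offset(per_cond[[1]]$density,
                                    per_cond[[1]]$windows,
                                    config$candidate_range))
    offset <- calib$offset
  } else {
    offset <- as.integer(config$offset)
  }

  for (cc in conds) {
    pc <- per_cond[[cc]]
    prof <- stage(paste0("pause_scores[", cc, "]"),
                  pause_scores(pc$density, pc$windows))
    per_cond[[cc]]$pause_profiles <- prof
    per_cond[[cc]]$codon_table <- stage(
      paste0("codon_pause_table[", cc, "]"),
      codon_pause_table(prof, orfs, offset))
    per_cond[[cc]]$aa_table <- aa_pause_table(per_cond[[cc]]$codon_table)
  }

  paired_windows <- lapply(per_cond, function(pc) {
    pc$windows[pc$windows$orf_id %in% paired_ids, , drop = FALSE]
  })
  comps <- lapply(conds, function(cc) {
    stage(paste0("bin_composition[", cc, "]"),
          bin_composition(per_cond[[cc]]$density, paired_windows[[cc]],
                          config$n_bins))
  })
  names(comps) <- conds
  gm <- lapply(comps, geometric_mean_profile)
  ilrs <- lapply(comps, ilr_transform)
  hot <- stage("paired_hotelling", paired_hotelling(ilrs[[1]], ilrs[[2]]))
  norm <- lapply(ilrs, normality_check)

  manifest <- tibble(
    key = c("conditions", "n_orfs_annotated", "n_paired_orfs",
            "offset_mode", "offset_nt", "n_bins", "basis_id", "alpha",
            "hotelling_T2", "hotelling_p", "seed"),
    value = as.character(c(paste(conds, collapse = ","), nrow(orfs),
                           length(paired_ids),
                           if (is.null(calib)) "fixed" else "calibrated",
                           offset, config$n_bins, hot$basis_id,
                           config$alpha, signif(hot$T2, 8),
                           signif(hot$p_value, 8), config$seed))
  )
  res <- structure(list(
    orfs = orfs, conditions = per_cond, paired_ids = paired_ids,
    calibration = calib, offset = offset, compositions = comps,
    gm_profiles = gm, hotelling = hot, normality = norm,
    manifest = manifest, config = config
  ), class = "ribopause_run")
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

#' @export
print.ribopause_run <- function(x, ...) {
  cat("ribopause two-condition run\n")
  cat(sprintf("  conditions: %s\n",
              paste(names(x$conditions), collapse = " vs ")))
  cat(sprintf("  paired ORFs: %d; A-site offset: %d nt (%s)\n",
              length(x$paired_ids), x$offset,
              if (is.null(x$calibration)) "fixed" else "calibrated"))
  cat(sprintf("  paired Hotelling T2 = %.4g, p = %.4g\n",
              x$hotelling$T2, x$hotelling$p_value))
  for (cc in names(x$conditions)) {
    top <- x$conditions[[cc]]$aa_table[1, ]
    cat(sprintf("  top A-site amino acid [%s]: %s (mean pause score %.3f)\n",
                cc, top$aa3, top$mean_pause_score))
  }
  invisible(x)
}

write_tsv_commented <- function(x, path, comment) {
  body <- readr::format_tsv(as_tibble(x))
  writeLines(c(paste0("# ", comment), sub("\n$", "", body)), path)
  invisible(path)
}

# write every result table of a run as TSV with a provenance comment
write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("ribopause %s",
                  as.character(utils::packageVersion("ribopause")))
  for (cc in names(res$conditions)) {
    pc <- res$conditions[[cc]]
    write_tsv_commented(pc$codon_table,
                        file.path(dir, paste0("codon_pause_", cc, ".tsv")), prov)
    write_tsv_commented(pc$aa_table,
                        file.path(dir, paste0("aa_pause_", cc, ".tsv")), prov)
    write_tsv_commented(res$compositions[[cc]],
                        file.path(dir, paste0("composition_", cc, ".tsv")), prov)
    write_tsv_commented(res$gm_profiles[[cc]],
                        file.path(dir, paste0("gm_profile_", cc, ".tsv")), prov)
  }
  ht <- res$hotelling
  write_tsv_commented(
    tibble(T2 = ht$T2, F = ht$F, df1 = ht$df1, df2 = ht$df2,
           p_value = ht$p_value, n_pairs = ht$n_pairs,
           basis_id = ht$basis_id),
    file.path(dir, "hotelling.tsv"), prov)
  write_tsv_commented(res$manifest, file.path(dir, "manifest.tsv"), prov)
  invisible(dir)
}
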