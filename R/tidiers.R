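# broom-style tidiers.

#' Tidy a paired Hotelling T2 result
#'
#' One row per ilr coordinate with the mean paired difference.
#'
#' @param x A `ribo_hotelling` object.
#' @param ... Unused.
#' @return Tibble: `coord`, `mean_diff`.
#' @method tidy ribo_hotelling
#' @export
tidy.ribo_hotelling <- function(x, ...) {
  tibble(coord = seq_along(x$mean_diff), mean_diff = unname(x$mean_diff))
}

#' Glance at a paired Hotelling T2 result
#'
#' @param x A `ribo_hotelling` object.
#' @param ... Unused.
#' @return One-row tibble: `T2`, `statistic` (F), `df1`, `df2`, `p.value`,
#'   `n_pairs`, `basis_id`.
#' @method glance ribo_hotelling
#' @export
glance.ribo_hotelling <- function(x, ...) {
  tibble(T2 = x$T2, statistic = x$F, df1 = x$df1, df2 = x$df2,
         p.value = x$p_value, n_pairs = x$n_pairs, basis_id = x$basis_id)
}

#' Tidy an A-site offset calibration
#'
#' @param x A `ribo_offset_calibration` object.
#' @param ... Unused.
#' @return Tibble of per-candidate step heights: `candidate`, `step`.
#' @method tidy ribo_offset_calibration
#' @export
tidy.ribo_offset_calibration <- function(x, ...) x$scores

#' Glance at an A-site offset calibration
#'
#' @param x A `ribo_offset_calibration` object.
#' @param ... Unused.
#' @return One-row tibble: `offset`, `stop_frame_consistent`.
#' @method glance ribo_offset_calibration
#' @export
glance.ribo_offset_calibration <- function(x, ...) {
  tibble(offset = x$offset, stop_frame_consistent = x$stop_frame_consistent)
}

#' Glance at a full pipeline run
#'
#' @param x A `ribopause_run` object.
#' @param ... Unused.
#' @return One-row tibble with the run's headline numbers.
#' @method glance ribopause_run
#' @export
glance.ribopause_run <- function(x, ...) {
  tibble(
    n_paired_orfs = length(x$paired_ids),
    offset = x$offset,
    T2 = x$hotelling$T2,
    p.value = x$hotelling$p_value,
    top_aa = paste(vapply(x$conditions, function(pc) pc$aa_table$aa3[1],
                          character(1)), collapse = "/")
  )
}
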