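# Compositional along-ORF density analysis.
#
# Each ORF's trimmed window is cut into 10 contiguous segments and the
# percentage of window density per segment forms a 10-part composition.
# Compositions live on the simplex, so central tendency uses geometric
# means and inference happens after the isometric log-ratio (ilr)
# transform, where a paired Hotelling T2 test compares conditions.

#' Per-ORF binned density composition
#'
#' Partitions each analysis window into `n_bins` contiguous segments of
#' near-equal length (the `window length mod n_bins` leftover nucleotides
#' are assigned one each to the 3'-most bins) and expresses each segment's
#' density as a percentage of the window total.
#'
#' @param density A `ribo_density` tibble.
#' @param windows An `orf_windows` tibble.
#' @param n_bins Number of segments (default 10).
#' @return Tibble of class `ribo_composition`: `orf_id`, `bin` (1-based,
#'   5' to 3'), `part` (percent). Parts sum to 100 per ORF.
#' @export
bin_composition <- function(density, windows, n_bins = 10L) {
  windows <- as_tibble(windows)
  wlen <- windows$window_end - windows$window_start
  if (any(wlen < n_bins)) {
    abort(sprintf("window of ORF '%s' is shorter than n_bins",
                  windows$orf_id[which(wlen < n_bins)[1]]))
  }
  d <- density |>
    inner_join(windows[, c("orf_id", "window_start", "window_end")],
               by = "orf_id") |>
    filter(.data$position >= .data$window_start,
           .data$position < .data$window_end) |>
    mutate(
      wpos = .data$position - .data$window_start,
      wlen = .data$window_end - .data$window_start,
      bin = bin_index(.data$wpos, .data$wlen, n_bins)
    )
  totals <- d |>
    group_by(.data$orf_id) |>
    summarise(total = sum(.data$rpm), .groups = "drop")
  zero <- totals$orf_id[totals$total == 0]
  if (length(zero) > 0) {
    abort(sprintf("ORF '%s' has zero density in its window", zero[1]))
  }
  out <- d |>
    group_by(.data$orf_id, .data$bin) |>
    summarise(bin_sum = sum(.data$rpm), .groups = "drop") |>
    inner_join(totals, by = "orf_id") |>
    mutate(part = 100 * .data$bin_sum / .data$total) |>
    select(all_of(c("orf_id", "bin", "part"))) |>
    arrange(.data$orf_id, .data$bin)
  attr(out, "n_bins") <- as.integer(n_bins)
  class(out) <- c("ribo_composition", class(out))
  out
}

# map window-local positions to 1-based bin index; the r = len %% n_bins
# leftover nucleotides enlarge the last (3'-most) r bins by one
bin_index <- function(wpos, wlen, n_bins) {
  base <- wlen %/% n_bins
  r <- wlen %% n_bins
  cut_short <- (n_bins - r) * base  # nt covered by the short bins
  ifelse(wpos < cut_short,
         wpos %/% base + 1L,
         n_bins - r + (wpos - cut_short) %/% (base + 1L) + 1L)
}

# multiplicative simple zero replacement on one composition (percent scale):
# zeros become delta = 65% of the smallest nonzero part (floor 1e-6), the
# nonzero parts shrink multiplicatively, and the result re-closes to 100
replace_zeros <- function(parts, delta_frac = 0.65, floor = 1e-6) {
  z <- parts == 0
  if (!any(z)) return(parts)
  if (all(z)) abort("composition is all zero")
  delta <- max(delta_frac * min(parts[!z]), floor)
  out <- parts
  out[z] <- delta
  out[!z] <- parts[!z] * (1 - sum(z) * delta / 100)
  100 * out / sum(out)
}

#' Geometric-mean composition across ORFs
#'
#' Part-wise geometric mean of per-ORF compositions, re-closed to sum 100
#' -- the standard central-tendency summary for compositional data. Zero
#' parts are first handled per ORF by multiplicative replacement (zeros set
#' to 65% of that composition's smallest nonzero part, floor 1e-6).
#'
#' @param compositions A `ribo_composition` tibble.
#' @return Tibble of class `ribo_gm_profile`: `bin`, `part`, `n_orfs`.
#' @export
geometric_mean_profile <- function(compositions) {
  mat <- composition_matrix(compositions)
  gm <- unname(exp(colMeans(log(mat))))
  out <- tibble(
    bin = seq_len(ncol(mat)),
    part = 100 * gm / sum(gm),
    n_orfs = nrow(mat)
  )
  class(out) <- c("ribo_gm_profile", class(out))
  out
}

# ORFs x bins matrix with zero replacement applied per row
composition_matrix <- function(compositions) {
  wide <- compositions |>
    as_tibble() |>
    pivot_wider(id_cols = "orf_id", names_from = "bin",
                values_from = "part", names_sort = TRUE)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$orf_id
  if (anyNA(mat)) abort("compositions have missing bins")
  t(apply(mat, 1, replace_zeros))
}

#' Orthonormal ilr contrast basis
#'
#' Builds a D x (D-1) orthonormal contrast matrix whose columns sum to
#' zero. `"pivot"` (default, basis_id "pivot-1") uses pivot balances in bin
#' order: coordinate j contrasts part j against the geometric mean of parts
#' j+1..D. `"helmert"` uses normalised Helmert contrasts and exists mainly
#' to demonstrate basis-invariance of the Hotelling statistic.
#'
#' @param D Number of parts.
#' @param type `"pivot"` or `"helmert"`.
#' @return Matrix with attribute `basis_id`.
#' @export
ilr_basis <- function(D, type = c("pivot", "helmert")) {
  type <- match.arg(type)
  V <- matrix(0, nrow = D, ncol = D - 1)
  if (type == "pivot") {
    for (j in seq_len(D - 1)) {
      r <- D - j
      V[j, j] <- sqrt(r / (r + 1))
      V[(j + 1):D, j] <- -sqrt(r / (r + 1)) / r
    }
    attr(V, "basis_id") <- "pivot-1"
  } else {
    H <- stats::contr.helmert(D)          # D x (D-1), columns orthogonal
    V <- sweep(H, 2, sqrt(colSums(H^2)), "/")
    attr(V, "basis_id") <- "helmert"
  }
  V
}

#' Isometric log-ratio coordinates of binned compositions
#'
#' Maps each D-part composition to D-1 unconstrained real coordinates,
#' `coords = t(V) %*% log(parts)` for an orthonormal zero-sum contrast
#' matrix V (closure-invariant, so rescaling a composition changes
#' nothing). Zero parts are replaced first (see
#' [geometric_mean_profile()]).
#'
#' @param compositions A `ribo_composition` tibble.
#' @param basis An [ilr_basis()] matrix, or `NULL` for the default pivot
#'   basis.
#' @return Tibble of class `ribo_ilr`: `orf_id`, `coord` (1..D-1), `value`;
#'   attributes `basis_id` and `basis`.
#' @export
ilr_transform <- function(compositions, basis = NULL) {
  mat <- composition_matrix(compositions)
  if (any(mat <= 0)) abort("non-positive part after zero replacement")
  D <- ncol(mat)
  if (is.null(basis)) basis <- ilr_basis(D, "pivot")
  if (nrow(basis) != D) abort("basis dimension does not match the composition")
  coords <- log(mat) %*% basis   # row-wise t(V) %*% log(x)
  out <- tibble(
    orf_id = rep(rownames(mat), each = D - 1),
    coord = rep(seq_len(D - 1), times = nrow(mat)),
    value = as.vector(t(coords))
  )
  attr(out, "basis_id") <- attr(basis, "basis_id") %||% "custom"
  attr(out, "basis") <- basis
  class(out) <- c("ribo_ilr", class(out))
  out
}

# ORFs x coords matrix from a ribo_ilr tibble
ilr_matrix <- function(ilr) {
  wide <- ilr |>
    as_tibble() |>
    pivot_wider(id_cols = "orf_id", names_from = "coord",
                values_from = "value", names_sort = TRUE)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$orf_id
  mat
}

#' Paired Hotelling T2 test on ilr coordinates
#'
#' Multivariate paired comparison of two conditions: per-ORF coordinate
#' differences d_i give T2 = n * t(dbar) solve(S) dbar with S the sample
#' covariance of the differences, F = T2 (n - p) / (p (n - 1)) on (p, n -
#' p) degrees of freedom. The statistic is invariant under any change of
#' orthonormal ilr basis.
#'
#' @param ilr_a,ilr_b `ribo_ilr` tibbles over the same ORFs (from
#'   [intersect_conditions()]-matched samples).
#' @return Object of class `ribo_hotelling`: list with `T2`, `F`, `df1`,
#'   `df2`, `p_value`, `n_pairs`, `basis_id`, `mean_diff`.
#' @export
paired_hotelling <- function(ilr_a, ilr_b) {
  A <- ilr_matrix(ilr_a)
  B <- ilr_matrix(ilr_b)
  if (!setequal(rownames(A), rownames(B))) {
    abort("conditions cover different ORF sets; pair them with intersect_conditions() first")
  }
  B <- B[rownames(A), , drop = FALSE]
  D <- A - B
  n <- nrow(D)
  p <- ncol(D)
  if (n <= p) {
    abort(sprintf(
      "insufficient paired ORFs for %d-dimensional test (n = %d <= p)", p, n))
  }
  dbar <- colMeans(D)
  if (all(D == 0)) {
    # identical paired samples: no difference at all
    T2 <- 0
  } else {
    S <- cov(D)
    Sinv <- tryCatch(solve(S), error = function(e) {
      abort("singular covariance of paired differences; consider fewer bins")
    })
    T2 <- n * as.numeric(t(dbar) %*% Sinv %*% dbar)
  }
  Fstat <- T2 * (n - p) / (p * (n - 1))
  structure(list(
    T2 = T2, F = Fstat, df1 = p, df2 = n - p,
    p_value = pf(Fstat, p, n - p, lower.tail = FALSE),
    n_pairs = n,
    basis_id = attr(ilr_a, "basis_id") %||% "custom",
    mean_diff = dbar
  ), class = "ribo_hotelling")
}

#' @export
print.ribo_hotelling <- function(x, ...) {
  cat("Paired Hotelling T2 test on ilr coordinates\n")
  cat(sprintf("  T2 = %.4g, F(%d, %d) = %.4g, p = %.4g, n = %d pairs (basis %s)\n",
              x$T2, x$df1, x$df2, x$F, x$p_value, x$n_pairs, x$basis_id))
  invisible(x)
}

#' Mardia's multivariate-normality checks on ilr coordinates
#'
#' Advisory goodness-of-fit for the normality assumption behind the
#' Hotelling test: Mardia's multivariate skewness (chi-squared) and
#' kurtosis (normal) statistics on the ilr sample. Never used to gate the
#' pipeline.
#'
#' @param ilr A `ribo_ilr` tibble (or a numeric matrix, observations in
#'   rows).
#' @return Tibble with rows `skewness` and `kurtosis`: `test`, `statistic`,
#'   `p_value`.
#' @export
normality_check <- function(ilr) {
  X <- if (is.matrix(ilr)) ilr else ilr_matrix(ilr)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort(sprintf("need n > p observations (n = %d, p = %d)", n, p))
  C <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(C) / n  # MLE covariance, Mardia's convention
  Sinv <- solve(S)
  M <- C %*% Sinv %*% t(C)
  b1 <- sum(M^3) / n^2
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  b2 <- mean(diag(M)^2)
  kurt_stat <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  tibble(
    test = c("skewness", "kurtosis"),
    statistic = c(skew_stat, kurt_stat),
    p_value = c(
      pchisq(skew_stat, skew_df, lower.tail = FALSE),
      2 * pnorm(abs(kurt_stat), lower.tail = FALSE)
    )
  )
}
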