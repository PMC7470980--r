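# In-silico RNase T1 digestion and RNA fragment mass computation.
#
# RNase T1 cleaves single-stranded RNA 3' of unmodified guanosine, leaving
# a 3'-phosphate (hydrolysed cyclic intermediate) on the upstream fragment
# and a 5'-OH on the downstream one. Masses are average masses by default
# (MALDI-TOF in linear mode measures average mass), computed from elemental
# formulas. MH+ ions add one proton. Aminoacyl adducts esterified to the
# 3'-terminal ribose add the amino-acid residue mass (glycyl: +57.05 Da);
# N-acetylation of the aminoacyl alpha-amino group adds +42.04 Da.

ATOMIC_MASS <- list(
  average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
              P = 30.974, S = 32.06),
  monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)
)

# elemental formulas as c(C=, H=, N=, O=, P=, S=)
NUCLEOSIDE_FORMULA <- list(
  A = c(C = 10, H = 13, N = 5, O = 4, P = 0, S = 0),
  C = c(C = 9, H = 13, N = 3, O = 5, P = 0, S = 0),
  G = c(C = 10, H = 13, N = 5, O = 5, P = 0, S = 0),
  U = c(C = 9, H = 12, N = 2, O = 6, P = 0, S = 0)
)

# amino-acid residue formulas (residue = amino acid - H2O)
RESIDUE_FORMULA <- list(
  Ala = c(C = 3, H = 5, N = 1, O = 1, P = 0, S = 0),
  Arg = c(C = 6, H = 12, N = 4, O = 1, P = 0, S = 0),
  Asn = c(C = 4, H = 6, N = 2, O = 2, P = 0, S = 0),
  Asp = c(C = 4, H = 5, N = 1, O = 3, P = 0, S = 0),
  Cys = c(C = 3, H = 5, N = 1, O = 1, P = 0, S = 1),
  Gln = c(C = 5, H = 8, N = 2, O = 2, P = 0, S = 0),
  Glu = c(C = 5, H = 7, N = 1, O = 3, P = 0, S = 0),
  Gly = c(C = 2, H = 3, N = 1, O = 1, P = 0, S = 0),
  His = c(C = 6, H = 7, N = 3, O = 1, P = 0, S = 0),
  Ile = c(C = 6, H = 11, N = 1, O = 1, P = 0, S = 0),
  Leu = c(C = 6, H = 11, N = 1, O = 1, P = 0, S = 0),
  Lys = c(C = 6, H = 12, N = 2, O = 1, P = 0, S = 0),
  Met = c(C = 5, H = 9, N = 1, O = 1, P = 0, S = 1),
  Phe = c(C = 9, H = 9, N = 1, O = 1, P = 0, S = 0),
  Pro = c(C = 5, H = 7, N = 1, O = 1, P = 0, S = 0),
  Ser = c(C = 3, H = 5, N = 1, O = 2, P = 0, S = 0),
  Thr = c(C = 4, H = 7, N = 1, O = 2, P = 0, S = 0),
  Trp = c(C = 11, H = 10, N = 2, O = 1, P = 0, S = 0),
  Tyr = c(C = 9, H = 9, N = 1, O = 2, P = 0, S = 0),
  Val = c(C = 5, H = 9, N = 1, O = 1, P = 0, S = 0)
)

ACETYL_FORMULA <- c(C = 2, H = 2, N = 0, O = 1, P = 0, S = 0)
HPO3_FORMULA <- c(C = 0, H = 1, N = 0, O = 3, P = 1, S = 0)
H2O_FORMULA <- c(C = 0, H = 2, N = 0, O = 1, P = 0, S = 0)

formula_mass <- function(formula, mode = "average") {
  am <- ATOMIC_MASS[[mode]]
  sum(formula * am[names(formula)])
}

# normalise an RNA sequence; printed T is read as unmodified U
normalize_rna <- function(sequence) {
  s <- toupper(sequence)
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) > 0 && nzchar(bad)) {
    abort(sprintf("non-RNA character '%s' in sequence", bad))
  }
  s
}

#' Construct an RNA fragment with terminal chemistry and adducts
#'
#' @param sequence RNA string over A, C, G, U (a printed T is read as
#'   unmodified U).
#' @param five_prime `"OH"` or `"phosphate"`.
#' @param three_prime `"OH"`, `"linear_phosphate"` or `"cyclic_phosphate"`.
#' @param adducts Character vector from `"glycyl"`, `"acetyl"`, or
#'   `"aminoacyl-Xaa"` (three-letter code, e.g. `"aminoacyl-Ile"`).
#'   `"acetyl"` is only valid together with an aminoacyl adduct, since the
#'   acetyl group goes on the alpha-amino group of the esterified amino
#'   acid.
#' @return A list of class `rna_fragment`.
#' @export
rna_fragment <- function(sequence, five_prime = c("OH", "phosphate"),
                         three_prime = c("OH", "linear_phosphate",
                                         "cyclic_phosphate"),
                         adducts = character()) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) == 0) abort("fragment sequence must be non-empty")
  validate_adducts(adducts)
  structure(list(sequence = sequence, five_prime = five_prime,
                 three_prime = three_prime, adducts = adducts),
            class = "rna_fragment")
}

validate_adducts <- function(adducts) {
  if (length(adducts) == 0) return(invisible(TRUE))
  aa_like <- grepl("^aminoacyl-", adducts) | adducts == "glycyl"
  known <- aa_like | adducts == "acetyl"
  if (!all(known)) {
    abort(sprintf("unknown adduct '%s'", adducts[!known][1]))
  }
  aa_named <- sub("^aminoacyl-", "", adducts[grepl("^aminoacyl-", adducts)])
  bad <- setdiff(aa_named, names(RESIDUE_FORMULA))
  if (length(bad) > 0) abort(sprintf("unknown amino acid '%s'", bad[1]))
  if ("acetyl" %in% adducts && !any(aa_like)) {
    abort("acetyl adduct requires an aminoacyl adduct (acetylation is of its alpha-amino group)")
  }
  invisible(TRUE)
}

#' @export
print.rna_fragment <- function(x, ...) {
  cat(sprintf("RNA fragment 5'-%s %s %s-3'", x$five_prime, x$sequence,
              x$three_prime))
  if (length(x$adducts) > 0) cat(" +", paste(x$adducts, collapse = " +"))
  cat(sprintf("  [MH+ %.2f Da]\n", average_mass(x)))
  invisible(x)
}

adduct_mass <- function(adducts, mode) {
  if (length(adducts) == 0) return(0)
  vapply(adducts, function(a) {
    if (a == "acetyl") return(formula_mass(ACETYL_FORMULA, mode))
    aa <- if (a == "glycyl") "Gly" else sub("^aminoacyl-", "", a)
    formula_mass(RESIDUE_FORMULA[[aa]], mode)
  }, numeric(1)) |> sum()
}

#' MH+ (or neutral) mass of an RNA fragment
#'
#' Sums nucleoside masses, one phosphodiester bridge (HPO3 - H2O) per
#' internucleotide linkage, terminal phosphates (+HPO3 each; a 2',3'-cyclic
#' phosphate is the linear one minus H2O), adduct masses, and one proton
#' for the MH+ ion. Average masses by default; `mode = "monoisotopic"` is
#' available.
#'
#' @param fragment An [rna_fragment()], or an RNA string (then the
#'   terminus/adduct arguments apply).
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @param ion `"MH+"` (default) or `"neutral"`.
#' @param five_prime,three_prime,adducts Used when `fragment` is a string.
#' @return Mass in Da.
#' @export
average_mass <- function(fragment, mode = c("average", "monoisotopic"),
                         ion = c("MH+", "neutral"),
                         five_prime = "OH", three_prime = "OH",
                         adducts = character()) {
  mode <- match.arg(mode)
  ion <- match.arg(ion)
  if (!inherits(fragment, "rna_fragment")) {
    fragment <- rna_fragment(fragment, five_prime, three_prime, adducts)
  }
  bases <- strsplit(fragment$sequence, "")[[1]]
  n <- length(bases)
  mass <- sum(vapply(bases, function(b) {
    formula_mass(NUCLEOSIDE_FORMULA[[b]], mode)
  }, numeric(1)))
  bridge <- formula_mass(HPO3_FORMULA, mode) - formula_mass(H2O_FORMULA, mode)
  mass <- mass + (n - 1) * bridge
  if (fragment$five_prime == "phosphate") {
    mass <- mass + formula_mass(HPO3_FORMULA, mode)
  }
  if (fragment$three_prime != "OH") {
    mass <- mass + formula_mass(HPO3_FORMULA, mode)
    if (fragment$three_prime == "cyclic_phosphate") {
      mass <- mass - formula_mass(H2O_FORMULA, mode)
    }
  }
  mass <- mass + adduct_mass(fragment$adducts, mode)
  if (ion == "MH+") mass <- mass + ATOMIC_MASS[[mode]][["H"]]
  mass
}

#' In-silico RNase T1 digestion
#'
#' Cleaves after every unprotected G. Upstream/internal fragments carry a
#' 3' linear phosphate (set `cyclic = TRUE` for 2',3'-cyclic ends) and all
#' fragments except the first get a 5'-OH; the 3'-terminal fragment keeps
#' the molecule's native 3' terminus.
#'
#' @param rna RNA string (T read as U).
#' @param protected_positions 1-based positions of G residues exempt from
#'   cleavage (modelling modified guanosines or missed cleavages).
#' @param native_three_prime 3' terminus of the input molecule (default
#'   `"OH"`, as for tRNA).
#' @param five_prime 5' terminus of the input molecule (default `"OH"`).
#' @param cyclic If `TRUE`, cleaved fragments keep 2',3'-cyclic phosphates.
#' @return Tibble of class `ribo_t1_digest`: `fragment_index`, `start`,
#'   `end` (1-based inclusive), `sequence`, `five_prime`, `three_prime`.
#' @export
t1_digest <- function(rna, protected_positions = integer(),
                      native_three_prime = "OH", five_prime = "OH",
                      cyclic = FALSE) {
  s <- normalize_rna(rna)
  n <- nchar(s)
  gpos <- gregexpr("G", s, fixed = TRUE)[[1]]
  gpos <- gpos[gpos > 0]
  bad <- setdiff(protected_positions, gpos)
  if (length(bad) > 0) {
    abort(sprintf("protected position %d is not a G", bad[1]))
  }
  cuts <- setdiff(gpos, protected_positions)
  cuts <- cuts[cuts < n]  # a 3'-terminal G yields no downstream fragment
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  cleaved_3p <- if (cyclic) "cyclic_phosphate" else "linear_phosphate"
  out <- tibble(
    fragment_index = seq_along(starts),
    start = starts,
    end = ends,
    sequence = substring(s, starts, ends),
    five_prime = c(five_prime, rep("OH", length(cuts))),
    three_prime = c(rep(cleaved_3p, length(cuts)), native_three_prime)
  )
  class(out) <- c("ribo_t1_digest", class(out))
  out
}

#' Theoretical MH+ masses for a digest or fragment table
#'
#' @param fragments A `ribo_t1_digest` tibble (or any tibble with
#'   `sequence`, `five_prime`, `three_prime` columns).
#' @param adducts Adducts applied to every fragment (rarely useful; default
#'   none).
#' @param mode `"average"` or `"monoisotopic"`.
#' @return The input with a `theoretical_mz` column added.
#' @export
fragment_masses <- function(fragments, adducts = character(),
                            mode = "average") {
  fragments$theoretical_mz <- purrr::pmap_dbl(
    fragments[, c("sequence", "five_prime", "three_prime")],
    function(sequence, five_prime, three_prime) {
      average_mass(rna_fragment(sequence, five_prime, three_prime, adducts),
                   mode = mode)
    }
  )
  fragments
}

#' Match observed m/z peaks to candidate fragments
#'
#' Each observed peak is matched to the candidate with the nearest
#' theoretical MH+ within `tolerance` (the measurement accuracy, 1 Da for
#' linear-mode average mass); exact ties go to the lower mass. Unmatched
#' peaks are reported with `matched = FALSE`.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param candidates Tibble with a `theoretical_mz` column (see
#'   [fragment_masses()]) and optionally a `species` column, or a numeric
#'   vector of theoretical m/z.
#' @param tolerance Maximum |delta| in Da (default 1.0).
#' @return Tibble: `observed_mz`, `theoretical_mz`, `species`, `delta`,
#'   `matched`.
#' @export
match_peaks <- function(observed, candidates, tolerance = 1.0) {
  if (tolerance <= 0) abort("tolerance must be > 0")
  if (is.numeric(candidates)) {
    candidates <- tibble(theoretical_mz = candidates)
  }
  if (nrow(candidates) == 0) abort("empty candidate list")
  if (!("species" %in% names(candidates))) {
    candidates$species <- candidates$sequence %||%
      sprintf("candidate%d", seq_len(nrow(candidates)))
  }
  th <- candidates$theoretical_mz
  rows <- lapply(observed, function(mz) {
    delta <- mz - th
    a <- abs(delta)
    near <- which(a - min(a) <= 1e-9)  # nearest; float-safe tie detection
    i <- near[which.min(th[near])]     # tie -> lower mass
    hit <- abs(delta[i]) <= tolerance
    tibble(
      observed_mz = mz,
      theoretical_mz = if (hit) th[i] else NA_real_,
      species = if (hit) candidates$species[i] else NA_character_,
      delta = if (hit) delta[i] else NA_real_,
      matched = hit
    )
  })
  list_rbind(rows)
}

#' Mass series of a fragment through charging, acetylation and Pth release
#'
#' Models the sequential treatment of a tRNA 3'-terminal fragment:
#' unmodified, aminoacylated (default glycyl, +57.05 Da), N-acetyl-
#' aminoacylated (further +42.04 Da), and after peptidyl-tRNA hydrolase
#' (Pth), which removes the N-acetyl-aminoacyl moiety and restores the
#' unmodified mass.
#'
#' @param fragment An [rna_fragment()] without adducts.
#' @param amino_acid Three-letter code of the esterified amino acid
#'   (default `"Gly"`).
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Tibble: `species`, `adducts`, `mh` (Da).
#' @export
modification_series <- function(fragment, amino_acid = "Gly",
                                mode = "average") {
  if (!inherits(fragment, "rna_fragment")) fragment <- rna_fragment(fragment)
  if (length(fragment$adducts) > 0) abort("fragment must start unmodified")
  aa_adduct <- if (amino_acid == "Gly") "glycyl" else
    paste0("aminoacyl-", amino_acid)
  with_adducts <- function(ad) {
    f <- fragment
    f$adducts <- ad
    average_mass(f, mode = mode)
  }
  tibble(
    species = c("unmodified", "aminoacyl", "acetyl-aminoacyl", "after_pth"),
    adducts = c("", aa_adduct, paste(aa_adduct, "acetyl", sep = "+"), ""),
    mh = c(with_adducts(character()), with_adducts(aa_adduct),
           with_adducts(c(aa_adduct, "acetyl")), with_adducts(character()))
  )
}
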