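# Bundled two-condition synthetic dataset used by examples and tests.

#' Generate the standard two-condition synthetic fixture
#'
#' Simulates a shared ORF set and two footprint libraries over it: a
#' "toxin" condition with 5x dwell at glycine codons and per-codon
#' drop-off q = 0.004 (elevated Gly A-site pausing plus a 3'-ward density
#' decline) and a "control" condition with 2x dwell at serine codons and no
#' drop-off (the hungry-Ser pattern of unstressed bacterial Ribo-seq).
#' Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory.
#' @param seed Base RNG seed (default 42).
#' @param n_orfs,depth Fixture size (defaults: 40 ORFs, 60,000 footprints
#'   per condition).
#' @return Named list with per-condition file paths (`toxin`, `control`),
#'   shared `genome`/`annotations` paths, and the `orfs` tibble, invisibly.
#' @export
make_fixtures <- function(dir, seed = 42L, n_orfs = 40L, depth = 6e4) {
  base <- sim_config(seed = seed, n_orfs = n_orfs,
                     orf_length_range = c(80L, 200L), depth = depth)
  gen <- generate_orfs(base)
  toxin_cfg <- sim_config(seed = seed, n_orfs = n_orfs,
                          orf_length_range = c(80L, 200L), depth = depth,
                          dwell_multipliers = dwell_for_aa(c(G = 5)),
                          dropoff_per_codon = 0.004)
  control_cfg <- sim_config(seed = seed, n_orfs = n_orfs,
                            orf_length_range = c(80L, 200L), depth = depth,
                            dwell_multipliers = dwell_for_aa(c(S = 2)))
  toxin <- simulate_footprints(gen$orfs, toxin_cfg, seed = seed + 1L)
  control <- simulate_footprints(gen$orfs, control_cfg, seed = seed + 2L)
  paths_t <- write_simulated_dataset(toxin, gen$orfs, gen$genome, dir,
                                     prefix = "toxin", config = toxin_cfg)
  paths_c <- write_simulated_dataset(control, gen$orfs, gen$genome, dir,
                                     prefix = "control", config = control_cfg)
  invisible(list(
    toxin = paths_t, control = paths_c,
    genome = unname(paths_t["genome"]),
    annotations = unname(paths_t["annotations"]),
    orfs = gen$orfs
  ))
}
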