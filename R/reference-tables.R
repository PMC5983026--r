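#' Published steady-state kinetic parameters of the Ta thermosome variants
#'
#' Reference table of the steady-state ATPase parameters reported for the
#' recombinant *Thermoplasma acidophilum* thermosome and its ATP-binding and
#' ATP-hydrolysis pocket variants, used as generator templates throughout
#' the package. The wild-type alpha8-beta8 complex is biphasic (two classes
#' of ATP-binding sites: a tight phase and a weak phase); the single mutants
#' and the all-alpha complex are monophasic; binding-blocked variants show
#' no detectable hydrolysis. `k_cat` is in mol ATP hydrolysed per mol active
#' sites per minute; `K_M` in uM. Refolding yields are percent recovery of
#' native substrate activity (the spontaneous refolding yield of the
#' unfolded substrate on this scale is 13 +/- 2 %).
#'
#' @return Tibble with columns `variant`, `complex`, `effect`, `phase`,
#'   `K_M`, `K_M_se`, `k_cat`, `k_cat_se`, `refolding_no_atp`,
#'   `refolding_plus_atp`.
#' @examples
#' ta_kinetic_parameters()
#' @export
ta_kinetic_parameters <- function() {
  tibble::tribble(
    ~variant, ~complex, ~effect, ~phase, ~K_M, ~K_M_se, ~k_cat, ~k_cat_se,
    ~refolding_no_atp, ~refolding_plus_atp,
    "WT", "a8b8", "none", 1L, 15, 1.65, 2.15, 0.12, 68, 95,
    "WT", "a8b8", "none", 2L, 370, 46, 3.2, 0.15, 68, 95,
    "WTa16", "a16", "none", 1L, 140, 15.7, 0.33, 0.015, 33, 44,
    "D94Ka", "a16", "hydrolysis_blocked", NA_integer_, NA, NA, NA, NA, 21, 31,
    "D94Aa", "a8b8", "hydrolysis_blocked", 1L, 82, 8.7, 2.4, 0.09, 17, 32,
    "D93Kb", "a8b8", "hydrolysis_blocked", 1L, 285, 35, 1.7, 0.14, 28.5, 43,
    "T97Va", "a16", "binding_blocked", NA_integer_, NA, NA, NA, NA, NA, NA,
    "T96Vb", "a16", "binding_blocked", NA_integer_, NA, NA, NA, NA, NA, NA,
    "T157Aa", "a8b8", "binding_blocked", NA_integer_, NA, NA, NA, NA, 24, 30.5,
    "T158Ab", "a8b8", "binding_blocked", NA_integer_, NA, NA, NA, NA, 57, 62.6
  )
}

#' Kinetic model for a named variant
#'
#' Builds a [kinetic_model()] from the reference parameters of
#' [ta_kinetic_parameters()]. Variants with no detectable hydrolysis have no
#' kinetic model and raise an error.
#'
#' @param variant Variant name, e.g. `"WT"` (two-phase) or `"WTa16"`.
#' @param sites Sites per phase (default 8).
#' @return A [kinetic_model()].
#' @export
kinetic_model_from_variant <- function(variant, sites = 8L) {
  tab <- ta_kinetic_parameters()
  rows <- tab[tab$variant == variant & !is.na(tab$K_M), ]
  if (nrow(rows) == 0) {
    abort(
      paste0("No kinetic parameters for variant '", variant, "' (unknown or no detectable hydrolysis)."),
      class = "thermoring_lookup_error"
    )
  }
  kinetic_model(K_M = rows$K_M, k_cat = rows$k_cat, sites = sites)
}

#' Published interface-energy summary of the thermosome assemblies
#'
#' Reference aggregates of docking-engine interface energies (kJ/mol) for
#' the simulated wild-type and mutant assemblies: mean and sd of the
#' intraring (side-by-side) interface energy, of the interring (facing)
#' interface energy and of its alpha-alpha / beta-beta split; the mean
#' per-subunit global energy against the whole assembly (`nrg_from_subs`);
#' the mean per-subunit sum of nearest-interface energies
#' (`nrg_from_seps`); and their difference — the weight of the diagonal
#' interactions in the interring interface. These published aggregates obey
#' the same bookkeeping identities this package computes (see
#' [interface_identity_check()]); their absolute values come from an
#' external force field and are not reproduced by the stand-in potential.
#'
#' @return Tibble with columns `assembly` (`alpha-beta`, `alpha-alpha`,
#'   `beta-beta`), `variant`, `intraring`, `intraring_sd`, `interring`,
#'   `interring_sd`, `inter_alpha`, `inter_alpha_sd`, `inter_beta`,
#'   `inter_beta_sd`, `nrg_from_subs`, `nrg_from_seps`, `difference`.
#' @export
ta_interface_energies <- function() {
  tibble::tribble(
    ~assembly, ~variant, ~intraring, ~intraring_sd, ~interring, ~interring_sd,
    ~inter_alpha, ~inter_alpha_sd, ~inter_beta, ~inter_beta_sd,
    ~nrg_from_subs, ~nrg_from_seps, ~difference,
    "alpha-beta", "WT", -450, 12, -114, 11, -114, 12, -114, 9, -1038, -1013, -25,
    "alpha-beta", "D94Aa", -444, 15, -117, 9, -118, 8, -115, 10, -1025, -1005, -20,
    "alpha-beta", "D93Kb", -443, 13, -106, 10, -111, 8, -102, 10, -1015, -992, -23,
    "alpha-beta", "T157Aa", -435, 16, -115, 11, -118, 9, -111, 11, -1009, -986, -23,
    "alpha-beta", "T158Ab", -443, 15, -111, 10, -116, 7, -105, 10, -1022, -997, -24,
    "alpha-beta", "T97Va", -438, 14, -123, 9, -104, 10, -113, 13, -1014, -999, -15,
    "alpha-beta", "T96Vb", -442, 12, -130, 8, -106, 11, -118, 16, -1031, -1015, -16,
    "alpha-beta", "D94Ka", -440, 15, -116, 10, -122, 7, -110, 8, -1025, -997, -28,
    "alpha-alpha", "WTa16", -447, 13, -137, 8, -137, 8, NA, NA, -1047, -1030, -17,
    "alpha-alpha", "D94Aa", -453, 14, -144, 6, -144, 6, NA, NA, -1048, -1050, 2,
    "alpha-alpha", "D94Ka", -445, 13, -141, 10, -141, 10, NA, NA, -1065, -1031, -34,
    "alpha-alpha", "T157Aa", -449, 12, -145, 8, -145, 8, NA, NA, -1063, -1043, -20,
    "alpha-alpha", "T97Aa", -446, 14, -146, 5, -146, 5, NA, NA, -1055, -1037, -18,
    "beta-beta", "WT", -401, 13, -123, 5, NA, NA, -123, 5, -946, -925, -21
  )
}

#' Bookkeeping identities of an interface-energy summary
#'
#' Recomputes, for each row of an interface-energy summary table, the two
#' internal identities of the decomposition: the diagonal contribution
#' `nrg_from_subs - nrg_from_seps` (which the `difference` column reports)
#' and the per-subunit separated energy `2 * intraring + interring` (which,
#' for a uniform assembly, `nrg_from_seps` reports up to the rounding of the
#' published values).
#'
#' @param table A tibble in the layout of [ta_interface_energies()].
#' @return The table with columns `diagonal_contribution`,
#'   `separated_from_interfaces` and `difference_residual`
#'   (`difference - diagonal_contribution`) appended.
#' @examples
#' interface_identity_check(ta_interface_energies())
#' @export
interface_identity_check <- function(table) {
  table <- as_tibble(table)
  table$diagonal_contribution <- table$nrg_from_subs - table$nrg_from_seps
  table$separated_from_interfaces <- 2 * table$intraring + table$interring
  table$difference_residual <- table$difference - table$diagonal_contribution
  table
}
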