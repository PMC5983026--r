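#' Empirical pairwise interface potential
#'
#' Defines the stand-in scoring model used to rank subunit interfaces: a
#' soft-core Lennard-Jones term with Lorentz-Berthelot combining plus a
#' screened Coulomb term with a distance-dependent dielectric
#' `epsilon(r) = 4 r / nm`, both truncated at `cutoff`. Distances below
#' `softcore_floor * sigma_ab` are clamped to that floor, so the score stays
#' finite for overlapping atoms. Formal charges are assigned to the key atoms
#' of charged side chains (Asp OD1/OD2 and Glu OE1/OE2 at -0.5 e each, Lys NZ
#' at +1 e, Arg NH1/NH2 at +0.5 e each, His neutral) and to chain termini
#' (+1 e on the first residue's N, -0.5 e on each of O and OXT of the last).
#'
#' This is an explicit stand-in for the docking-engine force field used to
#' produce published absolute interface energies; any self-consistent
#' parameter set supports the decomposition identities this package computes,
#' and absolute energies from this model are not comparable to published
#' values.
#'
#' @param sigma,epsilon Named per-element van der Waals parameters (nm,
#'   kJ/mol) for C, N, O, S, H.
#' @param cutoff Interaction cutoff in nm (default 1.4, mirroring the
#'   truncation used in the simulations this pipeline consumes).
#' @param softcore_floor Fraction of `sigma_ab` below which distances are
#'   clamped (0 < floor < 1).
#' @return A list of class `energy_model`.
#' @export
energy_model <- function(sigma = c(C = 0.340, N = 0.325, O = 0.296, S = 0.356, H = 0.107),
                         epsilon = c(C = 0.36, N = 0.71, O = 0.88, S = 1.05, H = 0.06),
                         cutoff = 1.4,
                         softcore_floor = 0.8) {
  stopifnot(all(epsilon >= 0), cutoff > 0, softcore_floor > 0, softcore_floor < 1)
  structure(
    list(
      sigma = sigma, epsilon = epsilon, cutoff = cutoff,
      softcore_floor = softcore_floor, coulomb_const = 138.935
    ),
    class = "energy_model"
  )
}

# Formal charges from residue/atom identity plus terminus rules, per subunit.
atom_charges <- function(atoms) {
  q <- numeric(nrow(atoms))
  key <- paste(atoms$resid, atoms$elety)
  q[key %in% c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2")] <- -0.5
  q[key == "LYS NZ"] <- 1
  q[key %in% c("ARG NH1", "ARG NH2")] <- 0.5
  # terminus rules only apply to amino-acid residues
  is_aa <- atoms$resid %in% c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
  )
  if (any(is_aa)) {
    sub_key <- paste(atoms$ring, atoms$position)
    for (sk in unique(sub_key[is_aa])) {
      idx <- which(sub_key == sk & is_aa)
      first_res <- min(atoms$resno[idx])
      last_res <- max(atoms$resno[idx])
      q[idx][atoms$resno[idx] == first_res & atoms$elety[idx] == "N"] <- 1
      q[idx][atoms$resno[idx] == last_res & atoms$elety[idx] %in% c("O", "OXT")] <- -0.5
    }
  }
  q
}

element_param <- function(elements, table, what) {
  out <- unname(table[elements])
  if (anyNA(out)) {
    miss <- unique(elements[is.na(out)])
    abort(
      paste0("No ", what, " parameter for element(s): ", paste(miss, collapse = ", ")),
      class = "thermoring_input_error"
    )
  }
  out
}

#' Interaction energy between two subunits
#'
#' Sums, over all atom pairs within the cutoff, the soft-core Lennard-Jones
#' and screened Coulomb terms of the [energy_model()]. Symmetric in its two
#' arguments; returns 0 when every interatomic distance exceeds the cutoff.
#'
#' @param a,b Atom tibbles of two disjoint subunits.
#' @param model An [energy_model()].
#' @return Energy in kJ/mol.
#' @export
pair_energy <- function(a, b, model = energy_model()) {
  if ("ring" %in% names(a) && "ring" %in% names(b)) {
    shared <- dplyr::intersect(
      dplyr::distinct(a[, c("ring", "position")]),
      dplyr::distinct(b[, c("ring", "position")])
    )
    if (nrow(shared) > 0) {
      abort("`a` and `b` share subunit identities; atom sets must be disjoint.",
        class = "thermoring_input_error"
      )
    }
  }
  ca <- as.matrix(a[, c("x", "y", "z")])
  cb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * tcrossprod(ca, cb)
  r <- sqrt(pmax(d2, 0))
  sig_a <- element_param(a$element, model$sigma, "sigma")
  sig_b <- element_param(b$element, model$sigma, "sigma")
  eps_a <- element_param(a$element, model$epsilon, "epsilon")
  eps_b <- element_param(b$element, model$epsilon, "epsilon")
  sig <- outer(sig_a, sig_b, `+`) / 2
  eps <- sqrt(outer(eps_a, eps_b))
  qa <- atom_charges(a)
  qb <- atom_charges(b)
  qq <- outer(qa, qb)
  rp <- pmax(r, model$softcore_floor * sig)
  sr6 <- (sig / rp)^6
  e_lj <- 4 * eps * (sr6^2 - sr6)
  # distance-dependent dielectric eps(r) = 4 r / nm  =>  q q f / (4 r'^2)
  e_coul <- model$coulomb_const * qq / (4 * rp^2)
  within <- r <= model$cutoff
  sum((e_lj + e_coul)[within])
}

#' Global interface energy of one subunit
#'
#' Energy of a subunit against the union of all other subunits in the
#' snapshot ("docking the subunit back into the whole assembly"). Under the
#' pairwise-additive potential this equals the sum of [pair_energy()] over
#' all other subunits exactly.
#'
#' @param frame Atom tibble of one snapshot.
#' @param ring,position Subunit index.
#' @param model An [energy_model()].
#' @return Energy in kJ/mol.
#' @export
global_energy <- function(frame, ring, position, model = energy_model()) {
  mine <- frame$ring == ring & frame$position == position
  if (!any(mine)) {
    abort(sprintf("Subunit (ring %d, position %d) not present in the frame.", ring, position),
      class = "thermoring_lookup_error"
    )
  }
  pair_energy(frame[mine, ], frame[!mine, ], model)
}
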