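# Idealized side-chain construction: internal-coordinate (Z-matrix style)
# definitions for the non-cyclic standard residues. Each row places one heavy
# atom from three reference atoms: bond length (nm), bond angle and torsion
# (degrees). References may be backbone atoms (N, CA, C) or previously placed
# side-chain atoms. Ring residues (His, Phe, Tyr, Trp) and Pro are not
# constructible by chain extension and are rejected.

sidechain_zmat <- local({
  cb <- function() {
    tibble::tibble(
      name = "CB", parent = "CA", ref2 = "N", ref3 = "C",
      bond = 0.1530, angle = 110.5, torsion = -122.5
    )
  }
  row <- function(name, parent, ref2, ref3, bond, angle, torsion) {
    tibble::tibble(
      name = name, parent = parent, ref2 = ref2, ref3 = ref3,
      bond = bond, angle = angle, torsion = torsion
    )
  }
  list(
    GLY = tibble::tibble(
      name = character(), parent = character(), ref2 = character(),
      ref3 = character(), bond = numeric(), angle = numeric(), torsion = numeric()
    ),
    ALA = cb(),
    SER = dplyr::bind_rows(cb(), row("OG", "CB", "CA", "N", 0.1417, 110.8, 180)),
    CYS = dplyr::bind_rows(cb(), row("SG", "CB", "CA", "N", 0.1808, 114.0, 180)),
    THR = dplyr::bind_rows(
      cb(),
      row("OG1", "CB", "CA", "N", 0.1433, 109.6, 180),
      row("CG2", "CB", "CA", "N", 0.1521, 110.5, -60)
    ),
    VAL = dplyr::bind_rows(
      cb(),
      row("CG1", "CB", "CA", "N", 0.1527, 110.5, 180),
      row("CG2", "CB", "CA", "N", 0.1527, 110.5, -60)
    ),
    ILE = dplyr::bind_rows(
      cb(),
      row("CG1", "CB", "CA", "N", 0.1530, 110.5, 180),
      row("CG2", "CB", "CA", "N", 0.1521, 110.5, -60),
      row("CD1", "CG1", "CB", "CA", 0.1513, 113.8, 180)
    ),
    LEU = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1530, 116.3, 180),
      row("CD1", "CG", "CB", "CA", 0.1521, 110.7, 180),
      row("CD2", "CG", "CB", "CA", 0.1521, 110.7, -60)
    ),
    MET = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1525, 111.0, 180),
      row("SD", "CG", "CB", "CA", 0.1810, 112.7, 180),
      row("CE", "SD", "CG", "CB", 0.1790, 100.9, 180)
    ),
    ASP = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1516, 112.6, 180),
      row("OD1", "CG", "CB", "CA", 0.1249, 118.4, 0),
      row("OD2", "CG", "CB", "CA", 0.1249, 118.4, 180)
    ),
    ASN = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1516, 112.6, 180),
      row("OD1", "CG", "CB", "CA", 0.1231, 120.8, 0),
      row("ND2", "CG", "CB", "CA", 0.1328, 116.4, 180)
    ),
    GLU = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1525, 111.0, 180),
      row("CD", "CG", "CB", "CA", 0.1516, 112.6, 180),
      row("OE1", "CD", "CG", "CB", 0.1249, 118.4, 0),
      row("OE2", "CD", "CG", "CB", 0.1249, 118.4, 180)
    ),
    GLN = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1525, 111.0, 180),
      row("CD", "CG", "CB", "CA", 0.1516, 112.6, 180),
      row("OE1", "CD", "CG", "CB", 0.1231, 120.8, 0),
      row("NE2", "CD", "CG", "CB", 0.1328, 116.4, 180)
    ),
    LYS = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1525, 111.0, 180),
      row("CD", "CG", "CB", "CA", 0.1525, 111.0, 180),
      row("CE", "CD", "CG", "CB", 0.1525, 111.0, 180),
      row("NZ", "CE", "CD", "CG", 0.1489, 112.0, 180)
    ),
    ARG = dplyr::bind_rows(
      cb(),
      row("CG", "CB", "CA", "N", 0.1525, 111.0, 180),
      row("CD", "CG", "CB", "CA", 0.1525, 111.0, 180),
      row("NE", "CD", "CG", "CB", 0.1463, 112.0, 180),
      row("CZ", "NE", "CD", "CG", 0.1329, 124.2, 180),
      row("NH1", "CZ", "NE", "CD", 0.1326, 120.0, 0),
      row("NH2", "CZ", "NE", "CD", 0.1326, 120.0, 180)
    )
  )
})

# Place atom D from references A (ref3), B (ref2), C (parent) given internal
# coordinates: |DC| = bond, angle D-C-B, torsion D-C-B-A (NeRF construction).
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m2 <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d_local <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d_local[1] * bc + d_local[2] * m2 + d_local[3] * n
}

#' Apply an idealized point mutation to a subunit
#'
#' Replaces the side chain of one residue with an idealized side chain of the
#' target amino acid. Atoms shared by name between the old and new side chain
#' (walking outward from CB) keep their coordinates; extra atoms of a larger
#' target are appended with ideal bond lengths/angles and extended (trans,
#' chi = 180 degrees) torsions; a smaller target simply truncates. Backbone
#' atoms (N, CA, C, O, OXT and backbone hydrogens) are never moved. This is a
#' deliberate idealization: no rotamer repacking is attempted.
#'
#' @param atoms Atom tibble of a single subunit (one `ring`/`position`).
#' @param resno Residue number to mutate.
#' @param to_aa Target amino acid, 1-letter code. Cyclic side chains
#'   (H, F, Y, W, P) are not supported by the chain-extension construction.
#' @return The subunit atom tibble with the residue replaced.
#' @examples
#' sub <- make_ideal_residue("ASP", resno = 94)
#' mutated <- apply_point_mutation(sub, 94, "K")
#' @export
apply_point_mutation <- function(atoms, resno, to_aa) {
  stopifnot(length(resno) == 1, length(to_aa) == 1)
  if (length(unique(paste(atoms$ring, atoms$position))) > 1) {
    abort("`atoms` must contain a single subunit.", class = "thermoring_input_error")
  }
  res <- atoms[atoms$resno == resno, ]
  if (nrow(res) == 0) {
    abort(sprintf("Residue %d not found in the subunit.", resno),
      class = "thermoring_lookup_error"
    )
  }
  to3 <- toupper(bio3d::aa123(toupper(to_aa)))
  if (is.na(to3) || !nzchar(to3)) {
    abort(sprintf("Unknown amino-acid code '%s'.", to_aa), class = "thermoring_input_error")
  }
  if (!to3 %in% names(sidechain_zmat)) {
    abort(
      sprintf("Idealized construction is not defined for %s (cyclic side chain).", to3),
      class = "thermoring_input_error"
    )
  }
  from3 <- res$resid[1]
  if (from3 == to3) {
    return(atoms)
  }
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")
  bb <- res[res$elety %in% backbone, ]
  side <- res[!res$elety %in% backbone, ]
  need <- c("N", "CA", "C")
  if (!all(need %in% bb$elety)) {
    abort("Residue lacks the backbone atoms (N, CA, C) needed for construction.",
      class = "thermoring_input_error"
    )
  }
  coords <- list()
  for (nm in bb$elety) {
    coords[[nm]] <- as.numeric(bb[bb$elety == nm, c("x", "y", "z")][1, ])
  }
  zmat <- sidechain_zmat[[to3]]
  kept <- character(0)
  built <- list()
  if (nrow(zmat) > 0) {
    for (k in seq_len(nrow(zmat))) {
      nm <- zmat$name[k]
      parent <- zmat$parent[k]
      parent_ok <- parent %in% c(need, kept, names(built))
      shared <- nm %in% side$elety &&
        (parent %in% need || parent %in% kept)
      if (shared) {
        coords[[nm]] <- as.numeric(side[side$elety == nm, c("x", "y", "z")][1, ])
        kept <- c(kept, nm)
      } else {
        if (!parent_ok) {
          abort("Internal: side-chain parent atom missing.", class = "thermoring_input_error")
        }
        coords[[nm]] <- place_atom(
          A = coords[[zmat$ref3[k]]], B = coords[[zmat$ref2[k]]],
          C = coords[[zmat$parent[k]]],
          bond = zmat$bond[k], angle = zmat$angle[k], torsion = zmat$torsion[k]
        )
        built[[nm]] <- TRUE
      }
    }
  }
  proto <- res[1, ]
  max_eleno <- max(atoms$eleno)
  new_side <- purrr::map_dfr(seq_len(nrow(zmat)), function(k) {
    nm <- zmat$name[k]
    out <- proto
    out$elety <- nm
    out$element <- substr(nm, 1, 1)
    xyz <- coords[[nm]]
    out$x <- xyz[1]
    out$y <- xyz[2]
    out$z <- xyz[3]
    old <- side[side$elety == nm, ]
    out$eleno <- if (nm %in% kept) old$eleno[1] else NA_integer_
    out
  })
  if (nrow(new_side) > 0 && anyNA(new_side$eleno)) {
    new_side$eleno[is.na(new_side$eleno)] <-
      max_eleno + seq_len(sum(is.na(new_side$eleno)))
  }
  new_res <- dplyr::bind_rows(bb, new_side)
  new_res$resid <- to3
  out <- dplyr::bind_rows(atoms[atoms$resno != resno, ], new_res)
  out[order(out$resno, out$eleno), ]
}

#' Build an idealized free-standing residue
#'
#' Constructs a single residue (ideal backbone geometry plus the idealized
#' side chain of [apply_point_mutation()]) as an atom tibble, mainly for
#' tests and examples.
#'
#' @param resid 3-letter residue name (must be constructible, see
#'   [apply_point_mutation()]).
#' @param resno Residue number.
#' @param ring,position Subunit index to stamp on the atoms.
#' @param origin xyz offset (nm) applied to all atoms.
#' @return Atom tibble of one residue.
#' @export
make_ideal_residue <- function(resid, resno = 1, ring = 0L, position = 0L,
                               origin = c(0, 0, 0)) {
  resid <- toupper(resid)
  if (!resid %in% names(sidechain_zmat)) {
    abort(
      sprintf("Idealized construction is not defined for %s.", resid),
      class = "thermoring_input_error"
    )
  }
  # ideal backbone: N, CA, C, O with standard geometry
  coords <- list(
    N = c(0, 0, 0),
    CA = c(0.1458, 0, 0)
  )
  coords$C <- place_atom(
    A = c(-0.1, 0.1, 0), B = coords$N, C = coords$CA,
    bond = 0.1525, angle = 111.2, torsion = -120
  )
  coords$O <- place_atom(
    A = coords$N, B = coords$CA, C = coords$C,
    bond = 0.1231, angle = 120.5, torsion = 0
  )
  zmat <- sidechain_zmat[[resid]]
  if (nrow(zmat) > 0) {
    for (k in seq_len(nrow(zmat))) {
      coords[[zmat$name[k]]] <- place_atom(
        A = coords[[zmat$ref3[k]]], B = coords[[zmat$ref2[k]]],
        C = coords[[zmat$parent[k]]],
        bond = zmat$bond[k], angle = zmat$angle[k], torsion = zmat$torsion[k]
      )
    }
  }
  nm <- names(coords)
  co <- do.call(rbind, coords)
  tibble(
    frame = 1L, time_ns = 0, ring = as.integer(ring), position = as.integer(position),
    type = "alpha", eleno = seq_along(nm), elety = nm, resid = resid,
    resno = as.integer(resno), element = substr(nm, 1, 1),
    x = unname(co[, 1]) + origin[1], y = unname(co[, 2]) + origin[2],
    z = unname(co[, 3]) + origin[3]
  )
}
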