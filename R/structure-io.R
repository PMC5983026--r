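#' Read a multi-model PDB snapshot trajectory
#'
#' Parses a multi-model PDB file (one MODEL record per snapshot, as written
#' by trajectory post-processing) into a long atom tibble, partitioning atoms
#' into subunits through a chain mapping. Coordinates are converted from the
#' PDB's Angstrom to the package's internal nanometre unit.
#'
#' @param path Path to a multi-model PDB file.
#' @param mapping Tibble with columns `chain`, `ring`, `position` assigning
#'   every chain to a subunit of `topology`.
#' @param topology A `ring_topology`; types are joined onto the atoms.
#' @param time_per_model Time spacing between successive models, in ns
#'   (default 0.1: model k is at `k * time_per_model`).
#' @return A tibble with one row per atom per model and columns `frame`,
#'   `time_ns`, `ring`, `position`, `type`, `eleno`, `elety`, `resid`,
#'   `resno`, `element`, `x`, `y`, `z` (nm).
#' @export
read_trajectory <- function(path, mapping, topology, time_per_model = 0.1) {
  mapping <- as_tibble(mapping)
  stopifnot(all(c("chain", "ring", "position") %in% names(mapping)))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- as_tibble(pdb$atom)
  unknown <- setdiff(unique(atom$chain), mapping$chain)
  if (length(unknown) > 0) {
    abort(
      paste0("Chain(s) not covered by the subunit mapping: ", paste(unknown, collapse = ", ")),
      class = "thermoring_mapping_error"
    )
  }
  covered <- dplyr::anti_join(topology[, c("ring", "position")],
    mapping[, c("ring", "position")],
    by = c("ring", "position")
  )
  if (nrow(covered) > 0) {
    abort("The chain mapping does not cover all subunits of the topology.",
      class = "thermoring_mapping_error"
    )
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  n_atoms <- nrow(atom)
  base <- atom[, c("eleno", "elety", "resid", "chain", "resno", "elesy")]
  names(base)[names(base) == "elesy"] <- "element"
  base$element <- ifelse(is.na(base$element) | base$element == "",
    substr(trimws(base$elety), 1, 1), trimws(base$element)
  )
  frames <- purrr::map_dfr(seq_len(n_models), function(k) {
    co <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    df <- base
    df$x <- co[, 1] / 10
    df$y <- co[, 2] / 10
    df$z <- co[, 3] / 10
    df$frame <- k
    df$time_ns <- k * time_per_model
    df
  })
  frames <- dplyr::left_join(frames, mapping, by = "chain")
  frames <- dplyr::left_join(frames,
    as_tibble(topology)[, c("ring", "position", "type")],
    by = c("ring", "position")
  )
  out <- frames[, c(
    "frame", "time_ns", "ring", "position", "type", "chain",
    "eleno", "elety", "resid", "resno", "element", "x", "y", "z"
  )]
  counts <- out |>
    dplyr::count(.data$frame, .data$ring, .data$position, name = "n_atoms") |>
    dplyr::count(.data$ring, .data$position, .data$n_atoms, name = "n_variants")
  if (any(duplicated(counts[, c("ring", "position")]))) {
    abort("Atom counts per subunit differ across models.", class = "thermoring_format_error")
  }
  as_tibble(out)
}

subunit_chain_letters <- function(topology) {
  pool <- c(LETTERS, letters, as.character(0:9))
  topo <- as_tibble(topology)[, c("ring", "position")]
  topo <- topo[order(topo$ring, topo$position), ]
  topo$chain <- pool[seq_len(nrow(topo))]
  topo
}

#' Write an atom trajectory as a multi-model PDB
#'
#' Inverse of [read_trajectory()]: each `frame` becomes one MODEL record.
#' Subunits are written as separate chains (A, B, ... by ring then position,
#' unless the atoms already carry a `chain` column). Coordinates are
#' converted from nm to Angstrom at PDB precision (0.001 A).
#'
#' @param atoms Atom tibble as returned by [read_trajectory()] or
#'   [make_toy_assembly()].
#' @param path Output file path.
#' @return A tibble mapping `chain` to `ring`/`position`, invisibly usable as
#'   the `mapping` argument of [read_trajectory()].
#' @export
write_trajectory <- function(atoms, path) {
  if (!"chain" %in% names(atoms) || anyNA(atoms$chain)) {
    key <- dplyr::distinct(atoms[, c("ring", "position")])
    key <- key[order(key$ring, key$position), ]
    pool <- c(LETTERS, letters, as.character(0:9))
    key$chain <- pool[seq_len(nrow(key))]
    atoms$chain <- NULL
    atoms <- dplyr::left_join(atoms, key, by = c("ring", "position"))
  }
  atoms <- atoms[order(atoms$frame, atoms$ring, atoms$position, atoms$eleno), ]
  first <- atoms[atoms$frame == atoms$frame[1], ]
  frames <- split(atoms, atoms$frame)
  xyz <- do.call(rbind, lapply(frames, function(df) {
    as.numeric(t(as.matrix(df[, c("x", "y", "z")]) * 10))
  }))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = first$resno, resid = first$resid, eleno = first$eleno,
    elety = first$elety, chain = first$chain, elesy = first$element
  )
  invisible(dplyr::distinct(atoms[, c("chain", "ring", "position")]))
}

#' Extract one frame of a trajectory
#' @param atoms Trajectory atom tibble.
#' @param frame Frame number (default: first).
#' @return Atom tibble of a single snapshot.
#' @export
trajectory_frame <- function(atoms, frame = min(atoms$frame)) {
  atoms[atoms$frame == frame, ]
}

backbone_names <- c("N", "CA", "C", "O")

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Pairs atoms of two subunits by residue number and atom name over the
#' shared backbone atoms (N, CA, C, O), then computes the optimal proper
#' rotation (determinant +1) and translation minimising the RMSD, via the
#' SVD form of the Kabsch algorithm.
#'
#' @param mobile,target Atom tibbles of one subunit each.
#' @return A list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (nm, over the paired backbone atoms after the fit) and
#'   `n_paired`. The fitted mobile coordinates are
#'   `rotation %*% x + translation`.
#' @export
superpose_kabsch <- function(mobile, target) {
  mb <- mobile[mobile$elety %in% backbone_names, ]
  tg <- target[target$elety %in% backbone_names, ]
  key <- dplyr::inner_join(
    mb[, c("resno", "elety", "x", "y", "z")],
    tg[, c("resno", "elety", "x", "y", "z")],
    by = c("resno", "elety"), suffix = c("_m", "_t")
  )
  if (nrow(key) < 3) {
    abort("Superposition needs at least 3 paired backbone atoms.",
      class = "thermoring_superposition_error"
    )
  }
  P <- as.matrix(key[, c("x_m", "y_m", "z_m")])
  Q <- as.matrix(key[, c("x_t", "y_t", "z_t")])
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) {
    abort("Paired atoms are collinear; the rotation is not determined.",
      class = "thermoring_superposition_error"
    )
  }
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(tcrossprod(P, R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, n_paired = nrow(key))
}

apply_rigid <- function(atoms, rotation, translation) {
  co <- as.matrix(atoms[, c("x", "y", "z")])
  co <- sweep(tcrossprod(co, rotation), 2, translation, `+`)
  atoms$x <- co[, 1]
  atoms$y <- co[, 2]
  atoms$z <- co[, 3]
  atoms
}

#' Build a homo-oligomeric assembly by superposition
#'
#' Copies one donor subunit onto every position of the assembly by
#' backbone-fit superposition onto the original occupant, the in-silico
#' equivalent of overlaying one subunit type across a crystal-structure
#' template to obtain an all-alpha (or all-beta) hexadecamer.
#'
#' @param frame Atom tibble of one snapshot.
#' @param topology The `ring_topology` of the template.
#' @param donor_ring,donor_position Subunit to replicate.
#' @return A list with `atoms` (the homo-assembly snapshot) and `topology`
#'   (all types set to the donor's type).
#' @export
build_homo_assembly <- function(frame, topology, donor_ring, donor_position) {
  validate_subunit(topology, donor_ring, donor_position)
  donor <- frame[frame$ring == donor_ring & frame$position == donor_position, ]
  donor_type <- donor$type[1]
  subs <- dplyr::distinct(frame[, c("ring", "position")])
  subs <- subs[order(subs$ring, subs$position), ]
  placed <- purrr::pmap_dfr(subs, function(ring, position) {
    occupant <- frame[frame$ring == ring & frame$position == position, ]
    fit <- tryCatch(
      superpose_kabsch(donor, occupant),
      error = function(e) {
        abort(
          sprintf(
            "Superposition of the donor onto (ring %d, position %d) failed: %s",
            ring, position, conditionMessage(e)
          ),
          class = "thermoring_superposition_error"
        )
      }
    )
    out <- apply_rigid(donor, fit$rotation, fit$translation)
    out$ring <- ring
    out$position <- position
    out$type <- donor_type
    if ("chain" %in% names(occupant)) out$chain <- occupant$chain[1]
    out
  })
  topo <- topology
  topo$type <- donor_type
  list(atoms = as_tibble(placed), topology = topo)
}
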