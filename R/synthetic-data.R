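#' Generate a toy double-ring assembly trajectory
#'
#' Builds a synthetic 2 x `n_per_ring` assembly of compact pseudo-subunits
#' placed on two stacked circles, engineered so that the nearest interatomic
#' gap of every interface class hits a stated target exactly: each subunit
#' carries one dedicated contact atom on the axis towards each of its five
#' neighbours, placed so the contact pair across an intraring, facing or
#' diagonal interface is separated by exactly `intraring_gap`, `facing_gap`
#' or `diagonal_gap`. The remaining atoms form a compact core blob shared
#' (in the local subunit frame) by all subunits, which makes every subunit
#' geometrically equivalent under the assembly's dihedral symmetry. Frames
#' beyond the first add seeded Gaussian jitter to every coordinate, standing
#' in for thermal motion in a snapshot trajectory.
#'
#' @param n_per_ring Subunits per ring (>= 3).
#' @param scheme Composition scheme, as in [ring_topology()].
#' @param ring_radius Ring radius (nm); default places intraring centres
#'   3 nm apart.
#' @param ring_separation Centre-plane separation of the two rings (nm).
#' @param atoms_per_subunit Atoms per pseudo-subunit (>= 6: five contact
#'   atoms plus core).
#' @param intraring_gap,facing_gap,diagonal_gap Target nearest-atom gaps per
#'   interface class (nm).
#' @param rotation_offset Rigid rotation of ring 1 by this many positions;
#'   the returned topology's registration records it.
#' @param jitter_sd Per-coordinate Gaussian jitter sd (nm) for frames >= 2.
#' @param n_frames Number of frames.
#' @param time_per_frame Frame spacing (ns).
#' @param seed Integer seed (blob shape and jitter).
#' @return A list with `trajectory` (atom tibble), `topology`
#'   (a `ring_topology` whose registration matches the geometry) and `spec`
#'   (the parameters used).
#' @export
make_toy_assembly <- function(n_per_ring = 8,
                              scheme = "alternating_ab",
                              ring_radius = NULL,
                              ring_separation = 3,
                              atoms_per_subunit = 12,
                              intraring_gap = 0.4,
                              facing_gap = 0.4,
                              diagonal_gap = 0.6,
                              rotation_offset = 0,
                              jitter_sd = 0,
                              n_frames = 1,
                              time_per_frame = 0.1,
                              seed = 1L) {
  stopifnot(
    n_frames >= 1, atoms_per_subunit >= 6, ring_separation > 0,
    intraring_gap > 0, facing_gap > 0, diagonal_gap > 0, jitter_sd >= 0
  )
  n <- as.integer(n_per_ring)
  if (is.null(ring_radius)) ring_radius <- 3 / (2 * sin(pi / n))
  topo <- ring_topology(n, scheme)
  off <- as.integer(rotation_offset) %% n
  for (q in 0:(n - 1L)) {
    i0 <- validate_subunit(topo, 0L, q)
    p1 <- (q + off) %% n
    i1 <- validate_subunit(topo, 1L, p1)
    topo$facing_position[i0] <- p1
    topo$facing_position[i1] <- q
  }

  theta0 <- 2 * pi * (0:(n - 1L)) / n
  centers <- rbind(
    cbind(ring_radius * cos(theta0), ring_radius * sin(theta0), 0),
    cbind(
      ring_radius * cos(2 * pi * ((0:(n - 1L)) - off) / n),
      ring_radius * sin(2 * pi * ((0:(n - 1L)) - off) / n),
      ring_separation
    )
  )
  center_of <- function(ring, position) centers[ring * n + position + 1L, ]

  gaps <- c(
    intra_left = intraring_gap, intra_right = intraring_gap,
    facing = facing_gap,
    diagonal_left = diagonal_gap, diagonal_right = diagonal_gap
  )

  set.seed(as.integer(seed))
  blob_radius <- 0.15
  m_core <- atoms_per_subunit - 5L
  # shared core blob in the local frame; first atom at the centre
  core_local <- matrix(0, nrow = m_core, ncol = 3)
  if (m_core > 1) {
    pts <- matrix(rnorm(3 * (m_core - 1)), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * blob_radius * stats::runif(m_core - 1)^(1 / 3)
    core_local[-1, ] <- pts
  }

  subs <- as_tibble(topo)[, c("ring", "position", "type")]
  frame1 <- purrr::pmap_dfr(subs, function(ring, position, type) {
    cs <- center_of(ring, position)
    nb <- ring_neighbors(topo, ring, position)
    contact <- t(vapply(seq_len(5), function(k) {
      ct <- center_of(nb$ring[k], nb$position[k])
      d <- sqrt(sum((ct - cs)^2))
      g <- gaps[[nb$role[k]]]
      if (g >= d) {
        abort(
          sprintf(
            "Infeasible toy geometry: %s gap %.3g nm >= centre distance %.3g nm.",
            nb$role[k], g, d
          ),
          class = "thermoring_spec_error"
        )
      }
      cs + (ct - cs) / d * (d - g) / 2
    }, numeric(3)))
    # local frame: radial, tangential, axial-towards-other-ring
    e_r <- c(cs[1], cs[2], 0)
    e_r <- e_r / sqrt(sum(e_r^2))
    e_z <- if (ring == 0) c(0, 0, 1) else c(0, 0, -1)
    e_t <- c(
      e_z[2] * e_r[3] - e_z[3] * e_r[2],
      e_z[3] * e_r[1] - e_z[1] * e_r[3],
      e_z[1] * e_r[2] - e_z[2] * e_r[1]
    )
    core <- t(apply(core_local, 1, function(o) cs + o[1] * e_r + o[2] * e_t + o[3] * e_z))
    co <- rbind(core, contact)
    m <- nrow(co)
    tibble(
      ring = ring, position = position, type = type,
      elety = paste0("C", seq_len(m)),
      resid = "TOY", resno = 1L, element = "C",
      x = co[, 1], y = co[, 2], z = co[, 3]
    )
  })
  frame1 <- frame1[order(frame1$ring, frame1$position), ]
  frame1$eleno <- seq_len(nrow(frame1))

  traj <- purrr::map_dfr(seq_len(n_frames), function(f) {
    df <- frame1
    if (f > 1 && jitter_sd > 0) {
      df$x <- df$x + rnorm(nrow(df), sd = jitter_sd)
      df$y <- df$y + rnorm(nrow(df), sd = jitter_sd)
      df$z <- df$z + rnorm(nrow(df), sd = jitter_sd)
    }
    df$frame <- f
    df$time_ns <- f * time_per_frame
    df
  })
  traj <- traj[, c(
    "frame", "time_ns", "ring", "position", "type",
    "eleno", "elety", "resid", "resno", "element", "x", "y", "z"
  )]
  list(
    trajectory = as_tibble(traj),
    topology = topo,
    spec = list(
      n_per_ring = n, scheme = scheme, ring_radius = ring_radius,
      ring_separation = ring_separation, atoms_per_subunit = atoms_per_subunit,
      intraring_gap = intraring_gap, facing_gap = facing_gap,
      diagonal_gap = diagonal_gap, rotation_offset = off,
      jitter_sd = jitter_sd, n_frames = n_frames,
      time_per_frame = time_per_frame, seed = as.integer(seed)
    )
  )
}

#' Generate a synthetic ATPase rate dataset
#'
#' Draws rate-versus-[ATP] data from a [kinetic_model()], optionally adding
#' proportional Gaussian noise and a linear spontaneous-hydrolysis blank
#' (`blank_rate = blank_slope * [ATP]`), which is added to the observed rate
#' and reported alongside so that [blank_correct()] can remove it exactly.
#'
#' @param model A [kinetic_model()].
#' @param conc ATP concentrations (uM); default 20 log-spaced points from 1
#'   to 2000 uM, bracketing both published Michaelis-constant scales.
#' @param noise_sd Gaussian noise sd as a fraction of the true rate.
#' @param blank_slope Blank rate per uM ATP.
#' @param replicates Number of replicate curves.
#' @param enzyme_conc Enzyme concentration stamped on the rows.
#' @param seed Integer seed.
#' @return Tibble with columns `atp_uM`, `rate` (observed), `blank_rate`,
#'   `enzyme_conc`, `replicate` and `rate_true`.
#' @export
make_rate_data <- function(model,
                           conc = NULL,
                           noise_sd = 0,
                           blank_slope = 0,
                           replicates = 1,
                           enzyme_conc = 1,
                           seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"), noise_sd >= 0, replicates >= 1)
  if (is.null(conc)) conc <- exp(seq(log(1), log(2000), length.out = 20))
  set.seed(as.integer(seed))
  purrr::map_dfr(seq_len(replicates), function(rep) {
    v <- model_rate(model, conc)
    noise <- if (noise_sd > 0) rnorm(length(conc), sd = noise_sd * v) else 0
    blank <- blank_slope * conc
    tibble(
      atp_uM = conc,
      rate = v + noise + blank,
      blank_rate = blank,
      enzyme_conc = enzyme_conc,
      replicate = rep,
      rate_true = v
    )
  })
}

cycle_templates <- list(
  WT = list(scheme = "alternating", binding = character(0), hydrolysis = character(0)),
  D94Aa = list(scheme = "alternating", binding = character(0), hydrolysis = "alpha"),
  D93Kb = list(scheme = "alternating", binding = character(0), hydrolysis = "beta"),
  T157Aa = list(scheme = "alternating", binding = "alpha", hydrolysis = character(0)),
  T158Ab = list(scheme = "alternating", binding = "beta", hydrolysis = character(0)),
  WTa16 = list(scheme = "all_alpha", binding = character(0), hydrolysis = character(0)),
  D94Ka16 = list(scheme = "all_alpha", binding = character(0), hydrolysis = "alpha")
)

#' Cycle configuration for a named thermosome variant
#'
#' Maps the characterized variants of the alpha/beta thermosome onto ring
#' cycle configurations: `WT` (alternating, no blocks), `D94Aa`/`D93Kb`
#' (alternating, hydrolysis blocked on alpha / beta), `T157Aa`/`T158Ab`
#' (alternating, ATP binding blocked on alpha / beta), `WTa16` (all-alpha
#' ring) and `D94Ka16` (all-alpha, hydrolysis blocked).
#'
#' @param template Template name (see above).
#' @param n_per_ring Ring size (default 8).
#' @param seed Seed forwarded to the configuration.
#' @param ... Further rate arguments passed to [cycle_config()].
#' @return A [cycle_config()].
#' @export
make_cycle_config <- function(template, n_per_ring = 8, seed = 1L, ...) {
  if (!template %in% names(cycle_templates)) {
    abort(
      paste0(
        "Unknown template '", template, "'. Available: ",
        paste(names(cycle_templates), collapse = ", ")
      ),
      class = "thermoring_lookup_error"
    )
  }
  tpl <- cycle_templates[[template]]
  types <- if (tpl$scheme == "alternating") {
    rep(c("alpha", "beta"), length.out = n_per_ring)
  } else {
    rep("alpha", n_per_ring)
  }
  cycle_config(
    types = types,
    binding_blocked = tpl$binding,
    hydrolysis_blocked = tpl$hydrolysis,
    seed = seed,
    ...
  )
}
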