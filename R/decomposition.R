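#' Interface-energy decomposition of one subunit
#'
#' Splits a subunit's interaction with the rest of the assembly into the
#' *global* energy (the subunit against all others), the *separated* energy
#' (the sum of its three nearest interfaces: the two intraring neighbours and
#' the facing partner), and the *diagonal* remainder
#' `diagonal = global - separated`, which measures what the nearest
#' interfaces miss — chiefly the two diagonal contacts with the intraring
#' neighbours of the facing partner.
#'
#' @param frame Atom tibble of one snapshot.
#' @param topology A `ring_topology`.
#' @param ring,position Subunit index.
#' @param model An [energy_model()].
#' @return A one-row tibble with columns `ring`, `position`, `type`,
#'   `time_ns`, `global`, `intra_left`, `intra_right`, `facing`, `separated`,
#'   `diagonal` (kJ/mol).
#' @export
decompose_subunit <- function(frame, topology, ring, position, model = energy_model()) {
  i <- validate_subunit(topology, ring, position)
  nb <- ring_neighbors(topology, ring, position)
  mine <- frame[frame$ring == ring & frame$position == position, ]
  if (nrow(mine) == 0) {
    abort(sprintf("Subunit (ring %d, position %d) not present in the frame.", ring, position),
      class = "thermoring_lookup_error"
    )
  }
  sub_atoms <- function(r, p) frame[frame$ring == r & frame$position == p, ]
  e_left <- pair_energy(mine, sub_atoms(nb$ring[1], nb$position[1]), model)
  e_right <- pair_energy(mine, sub_atoms(nb$ring[2], nb$position[2]), model)
  e_face <- pair_energy(mine, sub_atoms(nb$ring[3], nb$position[3]), model)
  e_global <- global_energy(frame, ring, position, model)
  separated <- e_left + e_right + e_face
  tibble(
    ring = ring, position = position, type = topology$type[i],
    time_ns = frame$time_ns[1] %||% NA_real_,
    global = e_global,
    intra_left = e_left, intra_right = e_right, facing = e_face,
    separated = separated,
    diagonal = e_global - separated
  )
}

#' Decompose every subunit of one snapshot
#' @inheritParams decompose_subunit
#' @return A tibble with one row per subunit (see [decompose_subunit()]).
#' @export
decompose_frame <- function(frame, topology, model = energy_model()) {
  subs <- as_tibble(topology)[, c("ring", "position")]
  purrr::pmap_dfr(subs, function(ring, position) {
    decompose_subunit(frame, topology, ring, position, model)
  })
}

# all unordered interfaces of a frame, classified
frame_interfaces <- function(frame, topology, model) {
  n <- n_per_ring(topology)
  intra <- purrr::map_dfr(0:1, function(r) {
    purrr::map_dfr(0:(n - 1L), function(p) {
      q <- (p + 1L) %% n
      tibble(
        class = "intraring", ring_a = r, pos_a = p, ring_b = r, pos_b = q,
        type_a = topology$type[validate_subunit(topology, r, p)],
        type_b = topology$type[validate_subunit(topology, r, q)]
      )
    })
  })
  topo0 <- topology[topology$ring == 0, ]
  facing <- purrr::map_dfr(seq_len(nrow(topo0)), function(k) {
    tibble(
      class = "facing",
      ring_a = 0L, pos_a = topo0$position[k],
      ring_b = topo0$facing_ring[k], pos_b = topo0$facing_position[k],
      type_a = topo0$type[k],
      type_b = topology$type[validate_subunit(
        topology, topo0$facing_ring[k], topo0$facing_position[k]
      )]
    )
  })
  ifc <- dplyr::bind_rows(intra, facing)
  ifc$energy <- purrr::pmap_dbl(
    ifc[, c("ring_a", "pos_a", "ring_b", "pos_b")],
    function(ring_a, pos_a, ring_b, pos_b) {
      pair_energy(
        frame[frame$ring == ring_a & frame$position == pos_a, ],
        frame[frame$ring == ring_b & frame$position == pos_b, ],
        model
      )
    }
  )
  ifc$pair_type <- ifelse(ifc$type_a == ifc$type_b,
    paste0(ifc$type_a, "-", ifc$type_b), "alpha-beta"
  )
  ifc
}

subsample_times <- function(times, interval) {
  times <- sort(unique(times))
  spacing <- if (length(times) > 1) min(diff(times)) else Inf
  if (length(times) > 1 && interval < spacing - 1e-9) {
    abort("`sample_interval` must be at least the frame spacing.",
      class = "thermoring_aggregation_error"
    )
  }
  targets <- seq(times[1], times[length(times)] + 1e-9, by = interval)
  picked <- unique(vapply(targets, function(t) times[which.min(abs(times - t))], numeric(1)))
  if (length(picked) == 0) {
    abort("Subsampling produced no frames.", class = "thermoring_aggregation_error")
  }
  picked
}

#' Aggregate the decomposition over a trajectory
#'
#' Subsamples the trajectory at `sample_interval` (default 3 ns), scores
#' every interface and every subunit of each sampled snapshot, and reports
#' the assembly-level aggregate in the conventional layout: mean and sd of
#' the intraring (side-by-side) interface energy, of the facing interring
#' interface energy, and of the facing interfaces split by type pair
#' (alpha-alpha / beta-beta, `NA` when the assembly has none); the mean
#' per-subunit global energy (`nrg_from_subs`); the mean per-subunit
#' separated energy (`nrg_from_seps`); and their difference — the relative
#' weight of the diagonal interactions in the interring interface.
#'
#' Interface columns average each unordered interface once (pooling
#' interfaces and sampled frames); `nrg_from_subs`/`nrg_from_seps` average
#' over subunits and sampled frames. Under this convention a uniform
#' assembly satisfies `nrg_from_seps = 2 * intraring + interring` exactly.
#'
#' @param trajectory Trajectory atom tibble.
#' @param topology A `ring_topology`.
#' @param model An [energy_model()].
#' @param sample_interval Subsampling interval in ns (>= frame spacing).
#' @return An object of class `decomposition_summary`: a list with `table`
#'   (one-row tibble of the aggregates), `per_subunit` (per subunit x frame
#'   decomposition), `interfaces` (per interface x frame energies) and
#'   `meta`.
#' @export
aggregate_decomposition <- function(trajectory, topology, model = energy_model(),
                                    sample_interval = 3) {
  if (nrow(trajectory) == 0) {
    abort("Empty trajectory.", class = "thermoring_aggregation_error")
  }
  times <- subsample_times(unique(trajectory$time_ns), sample_interval)
  frames <- purrr::map(times, function(t) trajectory[trajectory$time_ns == t, ])
  ifc <- purrr::map2_dfr(frames, times, function(f, t) {
    out <- frame_interfaces(f, topology, model)
    out$time_ns <- t
    out
  })
  per_sub <- purrr::map_dfr(frames, function(f) decompose_frame(f, topology, model))
  col_stats <- function(x) {
    if (length(x) == 0) {
      return(c(mean = NA_real_, sd = NA_real_))
    }
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  }
  intra <- col_stats(ifc$energy[ifc$class == "intraring"])
  inter <- col_stats(ifc$energy[ifc$class == "facing"])
  inter_a <- col_stats(ifc$energy[ifc$class == "facing" & ifc$pair_type == "alpha-alpha"])
  inter_b <- col_stats(ifc$energy[ifc$class == "facing" & ifc$pair_type == "beta-beta"])
  subs_mean <- mean(per_sub$global)
  seps_mean <- mean(per_sub$separated)
  table <- tibble(
    intraring = intra[["mean"]], intraring_sd = intra[["sd"]],
    interring = inter[["mean"]], interring_sd = inter[["sd"]],
    inter_alpha = inter_a[["mean"]], inter_alpha_sd = inter_a[["sd"]],
    inter_beta = inter_b[["mean"]], inter_beta_sd = inter_b[["sd"]],
    nrg_from_subs = subs_mean,
    nrg_from_seps = seps_mean,
    difference = subs_mean - seps_mean
  )
  structure(
    list(
      table = table,
      per_subunit = per_sub,
      interfaces = as_tibble(ifc),
      meta = list(
        sample_interval = sample_interval,
        sampled_times = times,
        sd_population = "pooled over interfaces (or subunits) and sampled frames",
        n_frames = length(times)
      )
    ),
    class = "decomposition_summary"
  )
}

#' @export
print.decomposition_summary <- function(x, ...) {
  cat("Interface-energy decomposition (kJ/mol)\n")
  cat(sprintf(
    "  %d sampled frame(s) at %.3g ns interval; sd %s\n",
    x$meta$n_frames, x$meta$sample_interval, x$meta$sd_population
  ))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decomposition_summary <- function(x, ...) {
  tidyr::pivot_longer(x$table, dplyr::everything(),
    names_to = "quantity", values_to = "energy_kJ_mol"
  )
}

#' Per-subunit global-energy time profile
#'
#' Global interface energy of every subunit at every frame of the
#' trajectory, ordered by time, ring, then position — the time-profile view
#' of the decomposition.
#'
#' @inheritParams aggregate_decomposition
#' @return A tibble with columns `time_ns`, `ring`, `position`, `type`,
#'   `global`.
#' @export
profile_timeseries <- function(trajectory, topology, model = energy_model()) {
  times <- sort(unique(trajectory$time_ns))
  out <- purrr::map_dfr(times, function(t) {
    f <- trajectory[trajectory$time_ns == t, ]
    d <- decompose_frame(f, topology, model)
    d$time_ns <- t
    d[, c("time_ns", "ring", "position", "type", "global")]
  })
  out[order(out$time_ns, out$ring, out$position), ]
}

#' Write a decomposition summary as TSV
#'
#' Writes the aggregate table with the conventional column names
#' (Intraring, sd, Interring, sd, Inter-alpha, sd, Inter-beta, sd,
#' NRG from subs, NRG from seps, Difference).
#'
#' @param x A `decomposition_summary`.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(x, path, header = character(0)) {
  tab <- x$table
  names(tab) <- c(
    "Intraring", "sd", "Interring", "sd_1", "Inter-alpha", "sd_2",
    "Inter-beta", "sd_3", "NRG from subs", "NRG from seps", "Difference"
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(paste(vapply(tab[1, ], format, character(1)), collapse = "\t"), con)
  invisible(path)
}

#' Plot the aggregated per-subunit energies
#'
#' Bar chart of each subunit's mean global interface energy (averaged over
#' sampled frames), labelled with 1-based positions.
#'
#' @param object A `decomposition_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.decomposition_summary <- function(object, ...) {
  df <- object$per_subunit |>
    dplyr::group_by(.data$ring, .data$position, .data$type) |>
    dplyr::summarise(global = mean(.data$global), .groups = "drop")
  df$label <- paste0("R", df$ring + 1, ":", df$position + 1)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$global, fill = .data$type
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "subunit (ring:position, 1-based)",
      y = "mean global interface energy (kJ/mol)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-subunit global-energy time profiles
#'
#' @param profiles Tibble from [profile_timeseries()].
#' @return A ggplot object.
#' @export
plot_energy_profiles <- function(profiles) {
  profiles$label <- paste0("R", profiles$ring + 1, ":", profiles$position + 1)
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$time_ns, y = .data$global,
    colour = .data$type, group = .data$label
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (ns)", y = "global interface energy (kJ/mol)") +
    ggplot2::theme_minimal()
}
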