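#' Build the topology of a double-ring assembly
#'
#' Represents a 2 x `n_per_ring` toroidal assembly as a tibble of typed
#' subunits. Each subunit is identified by its `ring` (0 or 1) and its
#' 0-based `position` within the ring; positions are reported 1-based in
#' printed labels and plots. The facing (interring) partner of every subunit
#' is stored explicitly in the `facing_ring`/`facing_position` columns
#' (the *registration*), defaulting to identity: position p in ring 0 faces
#' position p in ring 1.
#'
#' @param n_per_ring Number of subunits per ring (>= 3).
#' @param scheme Composition scheme: `"alternating_ab"` (requires even
#'   `n_per_ring`; types alternate alpha, beta, ... in each ring),
#'   `"all_alpha"` or `"all_beta"`.
#' @param mutations Optional tibble of per-type point mutations with columns
#'   `type` ("alpha"/"beta"), `resno` (positive integer), `from` and `to`
#'   (1-letter amino-acid codes, `from != to`).
#'
#' @return A tibble of class `ring_topology` with one row per subunit and
#'   columns `ring`, `position`, `type`, `facing_ring`, `facing_position`,
#'   plus attributes `n_per_ring`, `scheme` and `mutations`.
#' @examples
#' topo <- ring_topology(8, "alternating_ab")
#' table(topo$type)
#' @export
ring_topology <- function(n_per_ring,
                          scheme = c("alternating_ab", "all_alpha", "all_beta"),
                          mutations = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_per_ring) || length(n_per_ring) != 1 || n_per_ring < 3 ||
      n_per_ring != round(n_per_ring)) {
    abort("`n_per_ring` must be a single integer >= 3.", class = "thermoring_topology_error")
  }
  n <- as.integer(n_per_ring)
  if (scheme == "alternating_ab" && n %% 2L != 0L) {
    abort(
      paste0("An alternating alpha/beta ring requires an even number of subunits, got n = ", n, "."),
      class = "thermoring_composition_error"
    )
  }
  if (!is.null(mutations)) {
    mutations <- as_tibble(mutations)
    stopifnot(all(c("type", "resno", "from", "to") %in% names(mutations)))
    if (any(mutations$resno <= 0) || any(mutations$resno != round(mutations$resno))) {
      abort("Mutation residue numbers must be positive integers.", class = "thermoring_topology_error")
    }
    if (any(mutations$from == mutations$to)) {
      abort("Mutations must change the residue (`from` != `to`).", class = "thermoring_topology_error")
    }
  }
  types <- switch(scheme,
    alternating_ab = rep(c("alpha", "beta"), length.out = n),
    all_alpha = rep("alpha", n),
    all_beta = rep("beta", n)
  )
  topo <- tibble(
    ring = rep(0:1, each = n),
    position = rep(0:(n - 1L), times = 2L),
    type = rep(types, times = 2L),
    facing_ring = rep(1:0, each = n),
    facing_position = rep(0:(n - 1L), times = 2L)
  )
  new_ring_topology(topo, n_per_ring = n, scheme = scheme, mutations = mutations)
}

new_ring_topology <- function(df, n_per_ring, scheme, mutations = NULL) {
  structure(
    df,
    n_per_ring = as.integer(n_per_ring),
    scheme = scheme,
    mutations = mutations,
    class = c("ring_topology", class(tibble()))
  )
}

#' Number of subunits per ring of a topology
#' @param topology A `ring_topology`.
#' @return Integer ring size.
#' @export
n_per_ring <- function(topology) attr(topology, "n_per_ring")

validate_subunit <- function(topology, ring, position) {
  hit <- topology$ring == ring & topology$position == position
  if (!any(hit)) {
    abort(
      sprintf("Subunit (ring %d, position %d) is not part of this topology.", ring, position),
      class = "thermoring_lookup_error"
    )
  }
  which(hit)[1]
}

#' Neighbour set of a subunit
#'
#' Returns the five topological neighbours of a subunit: its two intraring
#' neighbours (positions +/- 1 mod n in the same ring), its facing partner in
#' the other ring (from the registration), and the two diagonal neighbours
#' (the intraring neighbours of the facing partner). For a subunit at
#' position 2 these are the classic "1, 3, 4, 5 and 6" contacts used when a
#' subunit is scored against the rest of the assembly.
#'
#' @param topology A `ring_topology`.
#' @param ring,position Subunit index (0-based).
#' @return A tibble with columns `role` (`intra_left`, `intra_right`,
#'   `facing`, `diagonal_left`, `diagonal_right`), `ring`, `position`, `type`.
#' @examples
#' topo <- ring_topology(8, "alternating_ab")
#' ring_neighbors(topo, 0, 2)
#' @export
ring_neighbors <- function(topology, ring, position) {
  validate_subunit(topology, ring, position)
  n <- n_per_ring(topology)
  i <- validate_subunit(topology, ring, position)
  f_ring <- topology$facing_ring[i]
  f_pos <- topology$facing_position[i]
  out <- tibble(
    role = c("intra_left", "intra_right", "facing", "diagonal_left", "diagonal_right"),
    ring = c(ring, ring, f_ring, f_ring, f_ring),
    position = c(
      (position - 1L) %% n, (position + 1L) %% n,
      f_pos,
      (f_pos - 1L) %% n, (f_pos + 1L) %% n
    )
  )
  out$type <- purrr::map2_chr(out$ring, out$position, function(r, p) {
    topology$type[validate_subunit(topology, r, p)]
  })
  out
}

#' Infer the interring registration from coordinates
#'
#' Replaces the facing-partner assignment of a topology with the one implied
#' by the geometry of a snapshot: each subunit of ring 0 is paired with the
#' ring-1 subunit of minimum centroid distance. Pairs are assigned greedily
#' by ascending distance so that the result is a bijection; exact ties are
#' broken by the lower position index (ring 0 first, then ring 1).
#'
#' @param frame Atom tibble of one snapshot (columns `ring`, `position`,
#'   `x`, `y`, `z`).
#' @param topology A `ring_topology` covering the same subunits.
#' @return The topology with `facing_ring`/`facing_position` replaced.
#' @export
infer_registration <- function(frame, topology) {
  n <- n_per_ring(topology)
  cent <- frame |>
    dplyr::group_by(.data$ring, .data$position) |>
    dplyr::summarise(
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      .groups = "drop"
    )
  missing <- dplyr::anti_join(
    topology[, c("ring", "position")], cent[, c("ring", "position")],
    by = c("ring", "position")
  )
  if (nrow(missing) > 0) {
    abort("`frame` lacks coordinates for some subunits of the topology.",
      class = "thermoring_registration_error"
    )
  }
  c0 <- cent[cent$ring == 0, ]
  c0 <- c0[order(c0$position), ]
  c1 <- cent[cent$ring == 1, ]
  c1 <- c1[order(c1$position), ]
  pairs <- tidyr::expand_grid(p0 = c0$position, p1 = c1$position)
  m0 <- as.matrix(c0[match(pairs$p0, c0$position), c("x", "y", "z")])
  m1 <- as.matrix(c1[match(pairs$p1, c1$position), c("x", "y", "z")])
  pairs$dist <- sqrt(rowSums((m0 - m1)^2))
  pairs <- pairs[order(pairs$dist, pairs$p0, pairs$p1), ]
  taken0 <- logical(n)
  taken1 <- logical(n)
  match01 <- rep(NA_integer_, n)
  for (k in seq_len(nrow(pairs))) {
    i0 <- pairs$p0[k] + 1L
    i1 <- pairs$p1[k] + 1L
    if (!taken0[i0] && !taken1[i1]) {
      taken0[i0] <- TRUE
      taken1[i1] <- TRUE
      match01[i0] <- pairs$p1[k]
    }
  }
  if (anyNA(match01)) {
    abort("Could not resolve a bijective registration from centroid distances.",
      class = "thermoring_registration_error"
    )
  }
  topo <- topology
  for (p0 in 0:(n - 1L)) {
    i <- validate_subunit(topo, 0L, p0)
    j <- validate_subunit(topo, 1L, match01[p0 + 1L])
    topo$facing_ring[i] <- 1L
    topo$facing_position[i] <- match01[p0 + 1L]
    topo$facing_ring[j] <- 0L
    topo$facing_position[j] <- p0
  }
  topo
}

#' Write / read a topology as TSV
#'
#' Plain-text serialization with columns `ring`, `position`, `type`,
#' `mutations` (semicolon-separated `from<resno>to` codes, empty if none),
#' `facing_ring`, `facing_position`. Indices are stored 0-based.
#'
#' @param topology A `ring_topology`.
#' @param path File path.
#' @return `write_topology()` returns `path` invisibly; `read_topology()`
#'   returns a `ring_topology`.
#' @export
write_topology <- function(topology, path) {
  mut <- attr(topology, "mutations")
  mut_str <- function(type) {
    if (is.null(mut)) {
      return("")
    }
    rows <- mut[mut$type == type, ]
    if (nrow(rows) == 0) {
      return("")
    }
    paste0(rows$from, rows$resno, rows$to, collapse = ";")
  }
  df <- as_tibble(topology)
  df$mutations <- vapply(df$type, mut_str, character(1))
  df <- df[, c("ring", "position", "type", "mutations", "facing_ring", "facing_position")]
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      ring = readr::col_integer(), position = readr::col_integer(),
      type = readr::col_character(), mutations = readr::col_character(),
      facing_ring = readr::col_integer(), facing_position = readr::col_integer()
    )
  )
  n <- nrow(df) / 2L
  mut_rows <- df[!is.na(df$mutations) & df$mutations != "", c("type", "mutations")]
  mutations <- NULL
  if (nrow(mut_rows) > 0) {
    mut_rows <- dplyr::distinct(mut_rows)
    parsed <- purrr::pmap_dfr(mut_rows, function(type, mutations) {
      parts <- strsplit(mutations, ";", fixed = TRUE)[[1]]
      tibble(
        type = type,
        resno = as.integer(gsub("^[A-Z]|[A-Z]$", "", parts)),
        from = substr(parts, 1, 1),
        to = substr(parts, nchar(parts), nchar(parts))
      )
    })
    mutations <- parsed
  }
  types_ring0 <- df$type[df$ring == 0][order(df$position[df$ring == 0])]
  scheme <- if (all(types_ring0 == "alpha")) {
    "all_alpha"
  } else if (all(types_ring0 == "beta")) {
    "all_beta"
  } else {
    "alternating_ab"
  }
  new_ring_topology(
    df[, c("ring", "position", "type", "facing_ring", "facing_position")],
    n_per_ring = n, scheme = scheme, mutations = mutations
  )
}
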