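#' Configuration of the neighbour-gated ring ATPase cycle
#'
#' One ring of typed subunits, each cycling through three chemical states —
#' apo, ATP-bound, post-hydrolysis — under a neighbour gate: in
#' `release_gated` mode (the default; product release is the rate-limiting,
#' allosterically controlled step) a subunit may release its hydrolysis
#' products only while at least one intraring neighbour is ATP-bound; in
#' `hydrolysis_gated` mode the gate sits on hydrolysis instead and release
#' is unconditional. Mutant subunit types may be flagged binding-blocked
#' (never leave apo) or hydrolysis-blocked (never leave the ATP-bound
#' state).
#'
#' @param types Character vector of subunit types around the ring
#'   (e.g. `rep(c("alpha","beta"), 4)`); length >= 2.
#' @param binding_blocked,hydrolysis_blocked Character vectors of type names
#'   carrying each block.
#' @param k_bind ATP binding rate constant (per uM per min).
#' @param atp_uM ATP concentration (uM); the binding propensity is
#'   `k_bind * atp_uM`.
#' @param k_hyd Named per-type hydrolysis rates (per min), e.g.
#'   `c(alpha = 1.7, beta = 3.2)`.
#' @param k_rel Product release rate (per min).
#' @param gating `"release_gated"` or `"hydrolysis_gated"`.
#' @param seed Integer seed used by [simulate_cycle()].
#' @return A list of class `cycle_config`.
#' @export
cycle_config <- function(types,
                         binding_blocked = character(0),
                         hydrolysis_blocked = character(0),
                         k_bind = 0.06, atp_uM = 100,
                         k_hyd = c(alpha = 1.7, beta = 3.2),
                         k_rel = 1,
                         gating = c("release_gated", "hydrolysis_gated"),
                         seed = 1L) {
  gating <- match.arg(gating)
  n <- length(types)
  if (n < 2) {
    abort("The ring needs at least 2 subunits.", class = "thermoring_topology_error")
  }
  stopifnot(k_bind >= 0, atp_uM >= 0, all(k_hyd >= 0), k_rel >= 0)
  if (!all(types %in% names(k_hyd))) {
    abort("Every subunit type needs a hydrolysis rate in `k_hyd`.",
      class = "thermoring_input_error"
    )
  }
  structure(
    list(
      types = types, n = n,
      binding_blocked = binding_blocked,
      hydrolysis_blocked = hydrolysis_blocked,
      k_bind = k_bind, atp_uM = atp_uM, k_hyd = k_hyd, k_rel = k_rel,
      gating = gating, seed = as.integer(seed)
    ),
    class = "cycle_config"
  )
}

cycle_states <- c("apo", "atp", "post")

#' Enabled transitions of a cycle state
#'
#' Lists every transition allowed from a state under the gating rules:
#' `bind` (apo to atp) unless the type is binding-blocked; `hydrolyze` (atp
#' to post) unless hydrolysis-blocked, additionally requiring an ATP-bound
#' intraring neighbour in `hydrolysis_gated` mode; `release` (post to apo),
#' requiring an ATP-bound intraring neighbour in `release_gated` mode.
#'
#' @param state Character vector over `c("apo","atp","post")`, one entry per
#'   ring position (1-based).
#' @param config A [cycle_config()].
#' @return Tibble with columns `position`, `transition`, `propensity`
#'   (per min).
#' @export
enabled_transitions <- function(state, config) {
  n <- config$n
  stopifnot(length(state) == n, all(state %in% cycle_states))
  left <- c(n, seq_len(n - 1))
  right <- c(seq_len(n - 1) + 1, 1)
  neighbor_atp <- state[left] == "atp" | state[right] == "atp"
  pos <- integer(0)
  trans <- character(0)
  prop <- numeric(0)
  for (i in seq_len(n)) {
    ty <- config$types[i]
    if (state[i] == "apo" && !ty %in% config$binding_blocked) {
      pos <- c(pos, i)
      trans <- c(trans, "bind")
      prop <- c(prop, config$k_bind * config$atp_uM)
    } else if (state[i] == "atp" && !ty %in% config$hydrolysis_blocked) {
      if (config$gating != "hydrolysis_gated" || neighbor_atp[i]) {
        pos <- c(pos, i)
        trans <- c(trans, "hydrolyze")
        prop <- c(prop, unname(config$k_hyd[ty]))
      }
    } else if (state[i] == "post") {
      if (config$gating != "release_gated" || neighbor_atp[i]) {
        pos <- c(pos, i)
        trans <- c(trans, "release")
        prop <- c(prop, config$k_rel)
      }
    }
  }
  tibble(position = pos, transition = trans, propensity = prop)
}

apply_transition <- function(state, position, transition) {
  state[position] <- switch(transition,
    bind = "atp", hydrolyze = "post", release = "apo"
  )
  state
}

#' Stochastic simulation of the ring ATPase cycle
#'
#' Exact Gillespie simulation of the continuous-time Markov jump process
#' defined by [enabled_transitions()], starting from the all-apo state. If
#' the total propensity reaches zero the ring is deadlocked (a legitimate
#' outcome for binding-blocked mutants) and the simulation stops with the
#' remaining time recorded.
#'
#' @param config A [cycle_config()]; `config$seed` makes runs reproducible.
#' @param t_end End time (min).
#' @return An object of class `cycle_trajectory`: list with `events` (tibble
#'   `time`, `position`, `type`, `transition`), `final_state`, `hydrolysis`
#'   (per-type cumulative counts), `flux` (per-type hydrolyses per subunit
#'   per min, estimated from the second half of the run), `deadlock`,
#'   `deadlock_time` and `config`.
#' @export
simulate_cycle <- function(config, t_end) {
  stopifnot(inherits(config, "cycle_config"), t_end > 0)
  set.seed(config$seed)
  state <- rep("apo", config$n)
  t <- 0
  cap <- 1024L
  ev_time <- numeric(cap)
  ev_pos <- integer(cap)
  ev_trans <- character(cap)
  k <- 0L
  deadlock <- FALSE
  deadlock_time <- NA_real_
  repeat {
    en <- enabled_transitions(state, config)
    total <- sum(en$propensity)
    if (total <= 0) {
      deadlock <- TRUE
      deadlock_time <- t
      break
    }
    dt <- stats::rexp(1, rate = total)
    if (t + dt > t_end) break
    t <- t + dt
    j <- sample.int(nrow(en), 1, prob = en$propensity)
    if (k == cap) {
      cap <- cap * 2L
      length(ev_time) <- cap
      length(ev_pos) <- cap
      length(ev_trans) <- cap
    }
    k <- k + 1L
    ev_time[k] <- t
    ev_pos[k] <- en$position[j]
    ev_trans[k] <- en$transition[j]
    state <- apply_transition(state, en$position[j], en$transition[j])
  }
  events <- tibble(
    time = ev_time[seq_len(k)],
    position = ev_pos[seq_len(k)],
    type = config$types[ev_pos[seq_len(k)]],
    transition = ev_trans[seq_len(k)]
  )
  type_counts <- table(factor(config$types, levels = unique(config$types)))
  hyd <- events[events$transition == "hydrolyze", ]
  hydrolysis <- vapply(names(type_counts), function(ty) sum(hyd$type == ty), numeric(1))
  half <- t_end / 2
  flux <- vapply(names(type_counts), function(ty) {
    sum(hyd$type == ty & hyd$time > half) / (type_counts[[ty]] * (t_end - half))
  }, numeric(1))
  structure(
    list(
      events = events, final_state = state,
      hydrolysis = hydrolysis, flux = flux,
      deadlock = deadlock, deadlock_time = deadlock_time,
      t_end = t_end, config = config
    ),
    class = "cycle_trajectory"
  )
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  cat(sprintf(
    "Ring ATPase cycle: n = %d, gating %s, %d events to t = %g min\n",
    x$config$n, x$config$gating, nrow(x$events), x$t_end
  ))
  if (x$deadlock) cat(sprintf("  DEADLOCK at t = %g min\n", x$deadlock_time))
  cat("  hydrolyses:", paste(names(x$hydrolysis), x$hydrolysis, sep = "=", collapse = ", "), "\n")
  cat(
    "  flux (per subunit per min):",
    paste(names(x$flux), signif(x$flux, 4), sep = "=", collapse = ", "), "\n"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cycle_trajectory <- function(x, ...) {
  tibble(
    type = names(x$flux),
    hydrolyses = unname(x$hydrolysis[names(x$flux)]),
    flux = unname(x$flux),
    deadlock = x$deadlock
  )
}

#' Plot cumulative hydrolysis counts of a cycle simulation
#' @param object A `cycle_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cycle_trajectory <- function(object, ...) {
  hyd <- object$events[object$events$transition == "hydrolyze", ]
  hyd <- hyd |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(cumulative = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(hyd, ggplot2::aes(
    x = .data$time, y = .data$cumulative, colour = .data$type
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "cumulative hydrolyses") +
    ggplot2::theme_minimal()
}

encode_state <- function(state) {
  sum((match(state, cycle_states) - 1L) * 3L^(seq_along(state) - 1L))
}

decode_state <- function(code, n) {
  cycle_states[(code %/% 3L^(0:(n - 1L))) %% 3L + 1L]
}

#' Exact stationary flux of the ring ATPase cycle
#'
#' Builds the full continuous-time Markov chain of the cycle over the states
#' reachable from all-apo, identifies its recurrent classes (strongly
#' connected components without outgoing edges), solves the stationary
#' distribution on each, and returns the exact long-run hydrolysis flux per
#' subunit type. When several recurrent classes are reachable they are
#' weighted by their absorption probabilities from the all-apo start. A ring
#' whose reachable recurrent classes contain no hydrolysis transition has
#' exact flux zero (deadlock).
#'
#' @param config A [cycle_config()] with `n <= 8` (state space `3^n`).
#' @return Tibble with columns `type` and `flux` (hydrolyses per subunit per
#'   min), with attribute `deadlock` (TRUE when the long-run flux is
#'   identically zero because no recurrent class hydrolyses).
#' @export
exact_cycle_flux <- function(config) {
  stopifnot(inherits(config, "cycle_config"))
  n <- config$n
  if (n > 8) {
    abort("Exact analysis is limited to n <= 8 (state space 3^n).",
      class = "thermoring_size_error"
    )
  }
  start <- rep("apo", n)
  # breadth-first enumeration of reachable states
  id_of <- new.env(hash = TRUE)
  states <- list(start)
  assign(as.character(encode_state(start)), 1L, envir = id_of)
  edges_from <- integer(0)
  edges_to <- integer(0)
  edges_rate <- numeric(0)
  edges_hyd_type <- character(0)
  q <- 1L
  while (q <= length(states)) {
    s <- states[[q]]
    en <- enabled_transitions(s, config)
    if (nrow(en) > 0) {
      for (j in seq_len(nrow(en))) {
        s2 <- apply_transition(s, en$position[j], en$transition[j])
        key <- as.character(encode_state(s2))
        id <- get0(key, envir = id_of, ifnotfound = NA_integer_)
        if (is.na(id)) {
          states[[length(states) + 1L]] <- s2
          id <- length(states)
          assign(key, id, envir = id_of)
        }
        edges_from <- c(edges_from, q)
        edges_to <- c(edges_to, id)
        edges_rate <- c(edges_rate, en$propensity[j])
        edges_hyd_type <- c(
          edges_hyd_type,
          if (en$transition[j] == "hydrolyze") config$types[en$position[j]] else NA_character_
        )
      }
    }
    q <- q + 1L
  }
  n_states <- length(states)
  type_levels <- unique(config$types)
  type_counts <- vapply(type_levels, function(ty) sum(config$types == ty), numeric(1))

  if (length(edges_from) == 0) {
    out <- tibble(type = type_levels, flux = 0)
    attr(out, "deadlock") <- TRUE
    return(out)
  }

  g <- igraph::graph_from_edgelist(
    cbind(edges_from, edges_to),
    directed = TRUE
  )
  if (igraph::vcount(g) < n_states) {
    g <- igraph::add_vertices(g, n_states - igraph::vcount(g))
  }
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # a class is recurrent iff no edge leaves it
  leaves <- memb[edges_from] != memb[edges_to]
  open_classes <- unique(memb[edges_from][leaves])
  # absorbing singleton states with no outgoing edges at all are recurrent too
  recurrent <- setdiff(unique(memb), open_classes)

  class_flux <- function(cl) {
    members <- which(memb == cl)
    if (length(members) == 1 && !any(edges_from == members)) {
      # absorbing deadlock state
      return(setNames(rep(0, length(type_levels)), type_levels))
    }
    idx <- match(seq_len(n_states), members)
    keep <- memb[edges_from] == cl & memb[edges_to] == cl
    i <- idx[edges_from[keep]]
    j <- idx[edges_to[keep]]
    r <- edges_rate[keep]
    m <- length(members)
    Q <- Matrix::sparseMatrix(i = i, j = j, x = r, dims = c(m, m))
    Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
    A <- Matrix::t(Q)
    A[m, ] <- 1
    b <- c(rep(0, m - 1), 1)
    pi_cl <- as.numeric(Matrix::solve(A, b))
    pi_cl <- pmax(pi_cl, 0)
    pi_cl <- pi_cl / sum(pi_cl)
    out <- setNames(rep(0, length(type_levels)), type_levels)
    hyd_keep <- keep & !is.na(edges_hyd_type)
    if (any(hyd_keep)) {
      for (ty in type_levels) {
        sel <- hyd_keep & edges_hyd_type == ty
        out[ty] <- sum(pi_cl[idx[edges_from[sel]]] * edges_rate[sel]) / type_counts[[ty]]
      }
    }
    out
  }

  # absorption probabilities from the start state into each recurrent class
  start_class <- memb[1]
  if (start_class %in% recurrent) {
    weights <- setNames(1, as.character(start_class))
  } else {
    transient <- which(!memb %in% recurrent)
    t_idx <- match(seq_len(n_states), transient)
    out_rate <- vapply(seq_len(n_states), function(v) sum(edges_rate[edges_from == v]), numeric(1))
    p <- edges_rate / out_rate[edges_from] # embedded jump probabilities
    tt <- edges_from %in% transient & edges_to %in% transient
    P_TT <- Matrix::sparseMatrix(
      i = t_idx[edges_from[tt]], j = t_idx[edges_to[tt]], x = p[tt],
      dims = c(length(transient), length(transient))
    )
    weights <- vapply(recurrent, function(cl) {
      tr <- edges_from %in% transient & memb[edges_to] == cl
      rhs <- rep(0, length(transient))
      if (any(tr)) {
        agg <- tapply(p[tr], t_idx[edges_from[tr]], sum)
        rhs[as.integer(names(agg))] <- agg
      }
      h <- as.numeric(Matrix::solve(Matrix::Diagonal(length(transient)) - P_TT, rhs))
      h[t_idx[1]]
    }, numeric(1))
    names(weights) <- as.character(recurrent)
  }

  flux <- setNames(rep(0, length(type_levels)), type_levels)
  for (clname in names(weights)) {
    if (weights[[clname]] > 1e-12) {
      flux <- flux + weights[[clname]] * class_flux(as.integer(clname))
    }
  }
  out <- tibble(type = type_levels, flux = unname(flux))
  attr(out, "deadlock") <- all(flux == 0)
  out
}
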