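test_that("diagonal = global - separated holds at machine precision", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy(n_frames = 3, jitter_sd = 0.05)
  for (fr in 1:3) {
    f <- trajectory_frame(toy$trajectory, fr)
    d <- decompose_frame(f, toy$topology, m)
    expect_equal(d$diagonal, d$global - d$separated, tolerance = 1e-12)
    expect_equal(d$separated, d$intra_left + d$intra_right + d$facing, tolerance = 1e-12)
  }
})

test_that("a toy with far-separated diagonals has zero diagonal energy", {
  m <- energy_model() # cutoff 1.4 nm
  toy <- make_toy_assembly(
    n_per_ring = 4, atoms_per_subunit = 8,
    intraring_gap = 0.45, facing_gap = 0.45, diagonal_gap = 2.0,
    seed = 4
  )
  f <- trajectory_frame(toy$trajectory)
  d <- decompose_frame(f, toy$topology, m)
  expect_equal(d$diagonal, rep(0, 8))
  expect_equal(d$global, d$separated)
  # the nearest interfaces do interact
  expect_true(all(d$separated < 0))
})

test_that("diagonal energy matches the oracle partitioned by neighbour class", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy()
  f <- trajectory_frame(toy$trajectory)
  topo <- toy$topology
  for (p in 0:3) {
    nb <- ring_neighbors(topo, 0, p)
    near <- paste(nb$ring, nb$position)[1:3]
    mine <- f[f$ring == 0 & f$position == p, ]
    subs <- unique(f[, c("ring", "position")])
    far_sum <- 0
    for (k in seq_len(nrow(subs))) {
      key <- paste(subs$ring[k], subs$position[k])
      if (key == paste(0, p) || key %in% near) next
      far_sum <- far_sum + bf_pair_energy(
        mine, f[f$ring == subs$ring[k] & f$position == subs$position[k], ], m
      )
    }
    d <- decompose_subunit(f, topo, 0, p, m)
    expect_equal(d$diagonal, far_sum, tolerance = 1e-9)
  }
})

test_that("summed separated energies count each nearest interface exactly twice", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy()
  f <- trajectory_frame(toy$trajectory)
  d <- decompose_frame(f, toy$topology, m)
  agg <- aggregate_decomposition(toy$trajectory, toy$topology, m, sample_interval = 0.1)
  ifc <- agg$interfaces
  expect_equal(sum(d$separated), 2 * sum(ifc$energy), tolerance = 1e-9)
})

test_that("aggregate table satisfies the uniform-assembly bookkeeping identities", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy()
  agg <- aggregate_decomposition(toy$trajectory, toy$topology, m, sample_interval = 0.1)
  tab <- agg$table
  # uniform single-frame assembly: seps identity exact, difference by definition
  expect_equal(tab$nrg_from_seps, 2 * tab$intraring + tab$interring, tolerance = 1e-9)
  expect_equal(tab$difference, tab$nrg_from_subs - tab$nrg_from_seps, tolerance = 1e-12)
})

test_that("facing interfaces split by type pair; absent pairs report NA", {
  m <- energy_model(cutoff = 10)
  toy_ab <- small_toy()
  agg_ab <- aggregate_decomposition(toy_ab$trajectory, toy_ab$topology, m, sample_interval = 0.1)
  expect_false(is.na(agg_ab$table$inter_alpha))
  expect_false(is.na(agg_ab$table$inter_beta))

  toy_b <- make_toy_assembly(
    n_per_ring = 4, atoms_per_subunit = 8,
    scheme = "all_beta", seed = 11
  )
  agg_b <- aggregate_decomposition(toy_b$trajectory, toy_b$topology, m, sample_interval = 0.1)
  expect_true(is.na(agg_b$table$inter_alpha))
  expect_false(is.na(agg_b$table$inter_beta))
})

test_that("identical frames give zero standard deviations", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy(n_frames = 2, jitter_sd = 0)
  agg <- aggregate_decomposition(toy$trajectory, toy$topology, m, sample_interval = 0.1)
  expect_equal(agg$table$intraring_sd, 0, tolerance = 1e-9)
  expect_equal(agg$table$interring_sd, 0, tolerance = 1e-9)
})

test_that("subsampling respects the interval and rejects empty/over-fine requests", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy(n_frames = 6, jitter_sd = 0.01)
  agg <- aggregate_decomposition(toy$trajectory, toy$topology, m, sample_interval = 0.2)
  expect_equal(agg$meta$sampled_times, c(0.1, 0.3, 0.5))
  expect_error(
    aggregate_decomposition(toy$trajectory, toy$topology, m, sample_interval = 0.01),
    class = "thermoring_aggregation_error"
  )
  expect_error(
    aggregate_decomposition(toy$trajectory[0, ], toy$topology, m),
    class = "thermoring_aggregation_error"
  )
})

test_that("time profiles are complete, ordered and constant for a rigid trajectory", {
  m <- energy_model(cutoff = 10)
  toy <- small_toy(n_frames = 3, jitter_sd = 0)
  prof <- profile_timeseries(toy$trajectory, toy$topology, m)
  expect_equal(nrow(prof), 3 * 8)
  expect_true(!is.unsorted(prof$time_ns))
  per_sub <- prof |>
    dplyr::group_by(.data$ring, .data$position) |>
    dplyr::summarise(spread = diff(range(.data$global)), .groups = "drop")
  expect_true(all(per_sub$spread < 1e-9))
})

test_that("jittered profiles scatter within 3x a Monte-Carlo estimate of the jitter sd", {
  m <- energy_model(cutoff = 10)
  jit <- 0.01
  toy <- small_toy(n_frames = 8, jitter_sd = jit)
  prof <- profile_timeseries(toy$trajectory, toy$topology, m)
  sub_sd <- prof |>
    dplyr::group_by(.data$ring, .data$position) |>
    dplyr::summarise(s = sd(.data$global), .groups = "drop")
  # oracle: regenerate many independently jittered frames of the same toy
  # and measure the induced spread of one subunit's global energy
  set.seed(99)
  base <- trajectory_frame(toy$trajectory)
  draws <- replicate(200, {
    f <- base
    f$x <- f$x + rnorm(nrow(f), sd = jit)
    f$y <- f$y + rnorm(nrow(f), sd = jit)
    f$z <- f$z + rnorm(nrow(f), sd = jit)
    global_energy(f, 0, 0, m)
  })
  oracle_sd <- sd(draws)
  expect_true(all(sub_sd$s < 3 * oracle_sd))
})
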