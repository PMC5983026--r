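test_that("transition gating follows the neighbour rules", {
  cfg <- make_cycle_config("WT", n_per_ring = 4)
  # all-apo ring: only binding is possible
  en <- enabled_transitions(rep("apo", 4), cfg)
  expect_true(all(en$transition == "bind"))
  expect_equal(nrow(en), 4)
  # release gated: post with both neighbours apo cannot release
  en2 <- enabled_transitions(c("post", "apo", "apo", "apo"), cfg)
  expect_false(any(en2$transition == "release"))
  # but with an ATP-bound neighbour it can
  en3 <- enabled_transitions(c("post", "atp", "apo", "apo"), cfg)
  expect_true(any(en3$transition == "release" & en3$position == 1))
  # hydrolysis gated: lone ATP cannot hydrolyze, paired ATP can
  cfg_h <- make_cycle_config("WT", n_per_ring = 4, gating = "hydrolysis_gated")
  en4 <- enabled_transitions(c("atp", "apo", "apo", "apo"), cfg_h)
  expect_false(any(en4$transition == "hydrolyze"))
  en5 <- enabled_transitions(c("atp", "atp", "apo", "apo"), cfg_h)
  expect_equal(sum(en5$transition == "hydrolyze"), 2)
  # blocked flags suppress the corresponding transitions
  cfg_b <- make_cycle_config("T158Ab", n_per_ring = 4)
  en6 <- enabled_transitions(rep("apo", 4), cfg_b)
  expect_true(all(cfg_b$types[en6$position] == "alpha"))
})

test_that("simulation conserves states, keeps ordered event times and reproduces under a seed", {
  cfg <- make_cycle_config("WT", n_per_ring = 6, gating = "hydrolysis_gated", seed = 42)
  tr <- simulate_cycle(cfg, t_end = 50)
  expect_equal(length(tr$final_state), 6)
  expect_true(all(tr$final_state %in% c("apo", "atp", "post")))
  expect_true(!is.unsorted(tr$events$time, strictly = TRUE))
  tr2 <- simulate_cycle(cfg, t_end = 50)
  expect_identical(tr$events, tr2$events)
  tr3 <- simulate_cycle(make_cycle_config("WT",
    n_per_ring = 6,
    gating = "hydrolysis_gated", seed = 43
  ), t_end = 50)
  expect_false(identical(tr$events, tr3$events))
})

test_that("binding-blocked alternating rings deadlock with at most n/2 hydrolyses", {
  for (template in c("T157Aa", "T158Ab")) {
    cfg <- make_cycle_config(template, n_per_ring = 8, seed = 7)
    tr <- simulate_cycle(cfg, t_end = 500)
    expect_true(tr$deadlock)
    expect_lte(sum(tr$hydrolysis), 4)
    expect_equal(unname(tr$flux), c(0, 0))
    ex <- exact_cycle_flux(cfg)
    expect_equal(ex$flux, c(0, 0))
    expect_true(attr(ex, "deadlock"))
  }
})

test_that("hydrolysis-blocked rings carry flux only on the unblocked type", {
  ex_b <- exact_cycle_flux(make_cycle_config("D93Kb", n_per_ring = 8))
  expect_gt(ex_b$flux[ex_b$type == "alpha"], 0)
  expect_equal(ex_b$flux[ex_b$type == "beta"], 0)
  ex_a <- exact_cycle_flux(make_cycle_config("D94Aa", n_per_ring = 8))
  expect_gt(ex_a$flux[ex_a$type == "beta"], 0)
  expect_equal(ex_a$flux[ex_a$type == "alpha"], 0)
  tr <- simulate_cycle(make_cycle_config("D93Kb", n_per_ring = 8, seed = 3), t_end = 300)
  expect_gt(tr$flux[["alpha"]], 0)
  expect_equal(tr$flux[["beta"]], 0)
  expect_false(tr$deadlock)
})

test_that("release-gated rings are eventually absorbed in the all-product state", {
  # the all-post state is reachable and absorbing, so the exact long-run
  # flux of a fully active release-gated ring is zero
  ex <- exact_cycle_flux(make_cycle_config("WT", n_per_ring = 4))
  expect_equal(ex$flux, c(0, 0))
  expect_true(attr(ex, "deadlock"))
})

test_that("hydrolysis-gated WT flux is positive on both types and ordered by k_hyd", {
  cfg <- make_cycle_config("WT", n_per_ring = 4, gating = "hydrolysis_gated")
  ex <- exact_cycle_flux(cfg)
  a <- ex$flux[ex$type == "alpha"]
  b <- ex$flux[ex$type == "beta"]
  expect_gt(a, 0)
  expect_gt(b, a) # default k_hyd_beta > k_hyd_alpha
  # reversing the rate ordering reverses the flux ordering
  cfg_rev <- make_cycle_config("WT",
    n_per_ring = 4, gating = "hydrolysis_gated",
    k_hyd = c(alpha = 3.2, beta = 1.7)
  )
  ex_rev <- exact_cycle_flux(cfg_rev)
  expect_gt(ex_rev$flux[ex_rev$type == "alpha"], ex_rev$flux[ex_rev$type == "beta"])
})

test_that("cumulative hydrolysis counts are non-decreasing in time", {
  cfg <- make_cycle_config("WT", n_per_ring = 4, gating = "hydrolysis_gated", seed = 9)
  tr <- simulate_cycle(cfg, t_end = 100)
  hyd_times <- tr$events$time[tr$events$transition == "hydrolyze"]
  expect_true(!is.unsorted(hyd_times))
  expect_gte(length(hyd_times), 1)
})

test_that("configuration and size limits are enforced", {
  expect_error(cycle_config(types = "alpha"), class = "thermoring_topology_error")
  cfg9 <- cycle_config(types = rep("alpha", 9))
  expect_error(exact_cycle_flux(cfg9), class = "thermoring_size_error")
  expect_error(make_cycle_config("nosuch"), class = "thermoring_lookup_error")
})
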