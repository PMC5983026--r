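test_that("multi-model PDB round-trip preserves coordinates to PDB precision", {
  toy <- small_toy(n_frames = 3, jitter_sd = 0.03)
  path <- withr::local_tempfile(fileext = ".pdb")
  map <- write_trajectory(toy$trajectory, path)
  back <- read_trajectory(path, map, toy$topology)
  expect_equal(length(unique(back$frame)), 3)
  orig <- toy$trajectory[order(
    toy$trajectory$frame, toy$trajectory$ring,
    toy$trajectory$position, toy$trajectory$eleno
  ), ]
  # PDB stores Angstrom to 3 decimals: 0.001 A = 1e-4 nm
  expect_lt(max(abs(back$x - orig$x)), 1e-4)
  expect_lt(max(abs(back$y - orig$y)), 1e-4)
  expect_lt(max(abs(back$z - orig$z)), 1e-4)
})

test_that("frame times follow the model-number scale", {
  toy <- small_toy(n_frames = 5, jitter_sd = 0.01)
  path <- withr::local_tempfile(fileext = ".pdb")
  map <- write_trajectory(toy$trajectory, path)
  back <- read_trajectory(path, map, toy$topology, time_per_model = 0.1)
  expect_equal(sort(unique(back$time_ns)), c(0.1, 0.2, 0.3, 0.4, 0.5))
})

test_that("a chain missing from the mapping is reported by name", {
  toy <- small_toy()
  path <- withr::local_tempfile(fileext = ".pdb")
  map <- write_trajectory(toy$trajectory, path)
  expect_error(
    read_trajectory(path, map[map$chain != "C", ], toy$topology),
    regexp = "C", class = "thermoring_mapping_error"
  )
})

test_that("Kabsch superposition is exact on self and recovers known rotations", {
  sub <- make_ideal_residue("LYS")
  fit <- superpose_kabsch(sub, sub)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  set.seed(1)
  R <- random_rotation()
  moved <- rigid_move(sub, R, c(1, 2, 3))
  fit2 <- superpose_kabsch(moved, sub)
  expect_lt(fit2$rmsd, 1e-9)
  # recovered rotation undoes R
  expect_equal(fit2$rotation %*% R, diag(3), tolerance = 1e-6)
})

test_that("Kabsch never returns a reflection on random point sets", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(4:12, 1)
    a <- tibble::tibble(
      resno = seq_len(n), elety = "CA",
      x = rnorm(n), y = rnorm(n), z = rnorm(n)
    )
    b <- a
    b$x <- rnorm(n)
    b$y <- rnorm(n)
    b$z <- rnorm(n)
    fit <- superpose_kabsch(a, b)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD agrees with an independent superposition routine", {
  set.seed(3)
  n <- 10
  a <- tibble::tibble(resno = 1:n, elety = "CA", x = rnorm(n), y = rnorm(n), z = rnorm(n))
  b <- tibble::tibble(resno = 1:n, elety = "CA", x = rnorm(n), y = rnorm(n), z = rnorm(n))
  ours <- superpose_kabsch(a, b)
  xyz_a <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  xyz_b <- as.numeric(t(as.matrix(b[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_b, mobile = xyz_a))
  ref_rmsd <- bio3d::rmsd(xyz_b, fitted)
  # bio3d stores fitted coordinates at PDB precision, hence the tolerance
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-3)
})

test_that("degenerate superposition inputs raise errors", {
  sub <- make_ideal_residue("ALA")
  expect_error(
    superpose_kabsch(sub[sub$elety %in% c("N", "CA"), ], sub),
    class = "thermoring_superposition_error"
  )
  line <- tibble::tibble(
    resno = 1:4, elety = "CA",
    x = 1:4, y = 0, z = 0
  )
  expect_error(superpose_kabsch(line, line), class = "thermoring_superposition_error")
})

test_that("homo-assembly construction replicates the donor everywhere", {
  toy <- small_toy()
  frame <- trajectory_frame(toy$trajectory)
  # toy atoms lack residue structure for backbone fits, so use residue-built
  # subunits arranged on the toy centres
  subs <- unique(frame[, c("ring", "position", "type")])
  assembly <- purrr::pmap_dfr(subs, function(ring, position, type) {
    centre <- colMeans(frame[frame$ring == ring & frame$position == position, c("x", "y", "z")])
    res <- make_ideal_residue(ifelse(type == "alpha", "ASP", "GLU"),
      ring = ring, position = position, origin = as.numeric(centre)
    )
    res$type <- type
    res
  })
  built <- build_homo_assembly(assembly, toy$topology, 0, 0)
  expect_equal(
    nrow(built$atoms),
    nrow(subs) * sum(assembly$ring == 0 & assembly$position == 0)
  )
  expect_true(all(built$topology$type == "alpha"))
  expect_true(all(built$atoms$resid == "ASP"))
  # the donor placed onto its own position is unchanged
  donor_out <- built$atoms[built$atoms$ring == 0 & built$atoms$position == 0, ]
  donor_in <- assembly[assembly$ring == 0 & assembly$position == 0, ]
  expect_equal(donor_out$x, donor_in$x, tolerance = 1e-9)
  expect_equal(donor_out$z, donor_in$z, tolerance = 1e-9)
})
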