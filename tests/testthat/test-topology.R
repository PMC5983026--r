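test_that("alternating hexadecamer has heterotypic intraring and homotypic facing interfaces", {
  topo <- ring_topology(8, "alternating_ab")
  expect_equal(nrow(topo), 16)
  expect_equal(sum(topo$type == "alpha"), 8)
  expect_equal(sum(topo$type == "beta"), 8)
  for (r in 0:1) {
    for (p in 0:7) {
      i <- which(topo$ring == r & topo$position == p)
      j <- which(topo$ring == r & topo$position == (p + 1) %% 8)
      expect_false(topo$type[i] == topo$type[j])
    }
  }
  # identity registration: facing partners share the position and the type
  for (k in seq_len(16)) {
    f <- which(topo$ring == topo$facing_ring[k] & topo$position == topo$facing_position[k])
    expect_equal(topo$facing_position[k], topo$position[k])
    expect_equal(topo$type[f], topo$type[k])
  }
})

test_that("homotypic schemes and composition errors behave as stated", {
  b16 <- ring_topology(8, "all_beta")
  expect_true(all(b16$type == "beta"))
  expect_error(ring_topology(3, "alternating_ab"), class = "thermoring_composition_error")
  expect_error(ring_topology(2, "all_alpha"), class = "thermoring_topology_error")
  expect_error(
    ring_topology(8, "alternating_ab",
      mutations = tibble::tibble(type = "alpha", resno = 94, from = "D", to = "D")
    ),
    class = "thermoring_topology_error"
  )
})

test_that("the five neighbours of a subunit match the ring geometry", {
  topo <- ring_topology(8, "alternating_ab")
  nb <- ring_neighbors(topo, 0, 2)
  expect_setequal(nb$position[nb$role %in% c("intra_left", "intra_right")], c(1, 3))
  expect_true(all(nb$ring[nb$role %in% c("intra_left", "intra_right")] == 0))
  expect_equal(nb$position[nb$role == "facing"], 2)
  expect_equal(nb$ring[nb$role == "facing"], 1)
  diag <- nb[nb$role %in% c("diagonal_left", "diagonal_right"), ]
  expect_setequal(paste(diag$ring, diag$position), c("1 1", "1 3"))
  expect_error(ring_neighbors(topo, 0, 9), class = "thermoring_lookup_error")
})

test_that("neighbour sets have 5 distinct members down to the minimum ring", {
  for (n in c(3, 4, 8)) {
    topo <- ring_topology(n, "all_alpha")
    for (r in 0:1) {
      for (p in 0:(n - 1)) {
        nb <- ring_neighbors(topo, r, p)
        expect_equal(nrow(dplyr::distinct(nb[, c("ring", "position")])), 5)
      }
    }
  }
})

test_that("intraring and diagonal neighbour relations are reciprocal", {
  topo <- ring_topology(8, "alternating_ab")
  key <- function(r, p) paste(r, p)
  for (k in seq_len(nrow(topo))) {
    r <- topo$ring[k]
    p <- topo$position[k]
    nb <- ring_neighbors(topo, r, p)
    for (role in c("intra_left", "intra_right", "diagonal_left", "diagonal_right")) {
      t_r <- nb$ring[nb$role == role]
      t_p <- nb$position[nb$role == role]
      back <- ring_neighbors(topo, t_r, t_p)
      roles_back <- back$role[paste(back$ring, back$position) == key(r, p)]
      if (startsWith(role, "intra")) {
        expect_true(any(startsWith(roles_back, "intra")))
      } else {
        expect_true(any(startsWith(roles_back, "diagonal")))
      }
    }
  }
})

test_that("registration inference recovers identity and rotated registrations", {
  toy <- make_toy_assembly(n_per_ring = 8, atoms_per_subunit = 8, seed = 2)
  frame <- trajectory_frame(toy$trajectory)
  reg <- infer_registration(frame, ring_topology(8, "alternating_ab"))
  expect_equal(reg$facing_position[reg$ring == 0], reg$position[reg$ring == 0])

  toy1 <- make_toy_assembly(n_per_ring = 8, atoms_per_subunit = 8, rotation_offset = 1, seed = 2)
  reg1 <- infer_registration(trajectory_frame(toy1$trajectory), ring_topology(8, "alternating_ab"))
  expect_equal(
    reg1$facing_position[reg1$ring == 0],
    (reg1$position[reg1$ring == 0] + 1) %% 8
  )
})

test_that("registration inference is invariant under global rigid motion", {
  set.seed(42)
  toy <- make_toy_assembly(n_per_ring = 8, atoms_per_subunit = 8, rotation_offset = 2, seed = 5)
  frame <- trajectory_frame(toy$trajectory)
  moved <- rigid_move(frame, random_rotation(), c(5, -3, 2))
  reg0 <- infer_registration(frame, ring_topology(8, "alternating_ab"))
  reg1 <- infer_registration(moved, ring_topology(8, "alternating_ab"))
  expect_equal(reg0$facing_position, reg1$facing_position)
})

test_that("equidistant facing candidates resolve to the lower position index", {
  topo <- ring_topology(3, "all_alpha")
  cent <- tibble::tibble(
    ring = c(0L, 0L, 0L, 1L, 1L, 1L),
    position = c(0L, 1L, 2L, 0L, 1L, 2L),
    x = c(0, 10, 20, 0, 0, 10),
    y = c(0, 0, 0, 1, -1, 1),
    z = 0
  )
  reg <- infer_registration(cent, topo)
  expect_equal(reg$facing_position[reg$ring == 0 & reg$position == 0], 0L)
})

test_that("topology TSV round-trips including mutations", {
  mut <- tibble::tibble(type = "alpha", resno = 94L, from = "D", to = "K")
  topo <- ring_topology(8, "alternating_ab", mutations = mut)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_equal(as.data.frame(back), as.data.frame(topo))
  expect_equal(attr(back, "mutations")$resno, 94L)
  expect_equal(n_per_ring(back), 8L)
})
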