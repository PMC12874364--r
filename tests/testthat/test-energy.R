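test_that("pair energy reproduces every interaction branch", {
  ts <- random_target_set(25, 2, seed = 5)
  p <- interaction_params(js = -4, jw = -1, mode = "UDI")
  # find a pair adjacent in target 1 with its stored displacement
  mat <- ts$placements[[1]]
  i <- mat[1, 1]; j <- mat[1, 2]
  disp <- c(0L, 1L)
  states <- rep(1L, 25)
  expect_equal(pair_energy(i, j, disp, states, ts, p), -4)        # both match
  states[j] <- 2L
  half <- pair_energy(i, j, disp, states, ts, p)
  # (Js + Jw)/2 unless the pair is also adjacent in target 2 with j matching
  mat2 <- ts$placements[[2]]
  also2 <- {
    pi2 <- which(mat2 == i, arr.ind = TRUE); pj2 <- which(mat2 == j, arr.ind = TRUE)
    sum(abs(pi2 - pj2)) == 1
  }
  expect_equal(half, if (also2) -4 else -2.5)
  states <- rep(2L, 25)
  expect_equal(pair_energy(i, j, disp, states, ts, p),
               if (also2) -4 else -1)                             # neither matches
  expect_error(pair_energy(i, j, c(0L, 2L), states, ts, p), "nearest neighbours")
})

test_that("directed interactions bind the strong bond to the stored orientation", {
  ts <- domino_targets()
  states <- c(1L, 1L)
  p_udi <- interaction_params(-4, -1, "UDI")
  p_di <- interaction_params(-4, -1, "DI")
  # stored displacement of 2 relative to 1 is (0, 1)
  expect_equal(pair_energy(1, 2, c(0, 1), states, ts, p_udi), -4)
  expect_equal(pair_energy(1, 2, c(1, 0), states, ts, p_udi), -4)
  expect_equal(pair_energy(1, 2, c(0, 1), states, ts, p_di), -4)
  expect_equal(pair_energy(1, 2, c(1, 0), states, ts, p_di), -1)  # rotated: weak
  expect_equal(pair_energy(1, 2, c(0, -1), states, ts, p_di), -1) # mirrored: weak
})

test_that("pair energy is symmetric under label swap with displacement negation", {
  ts <- random_target_set(9, 2, seed = 9)
  disps <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  for (mode in c("UDI", "DI")) {
    p <- interaction_params(-4, -1, mode)
    set.seed(31)
    for (rep in 1:40) {
      ij <- sample(9, 2)
      states <- sample(2, 9, replace = TRUE)
      d <- disps[sample(4, 1), ]
      expect_equal(
        pair_energy(ij[1], ij[2], d, states, ts, p),
        pair_energy(ij[2], ij[1], -d, states, ts, p)
      )
    }
  }
})

test_that("total energy matches the brute-force oracle on random small states", {
  ts <- random_target_set(4, 2, seed = 2)
  set.seed(17)
  for (mode in c("UDI", "DI")) {
    p <- interaction_params(-4, -1, mode)
    for (rep in 1:60) {
      sites <- sample(0:15, 4)
      pos <- cbind(sites %/% 4L, sites %% 4L)
      states <- sample(2, 4, replace = TRUE)
      st <- lattice_state(pos, states, 4, ts, p)
      expect_equal(
        st$energy,
        oracle_total_energy(pos, states, 4, ts$placements, mode, -4, -1)
      )
    }
  }
})

test_that("assembled threshold equals the bond-count of the square target", {
  expect_equal(assembly_threshold(25, -4), -160)
  expect_equal(assembly_threshold(4, -4), -16)
  expect_equal(assembly_threshold(1, -4), 0)
  expect_error(assembly_threshold(8, -4), "perfect square")
  # consistency with the energy of a correctly assembled placement
  for (mode in c("UDI", "DI")) {
    p <- interaction_params(-4, -1, mode)
    ts <- random_target_set(25, 2, seed = 13)
    st <- assembled_state(ts, p, 15, m = 1)
    expect_equal(st$energy, assembly_threshold(25, -4))
    expect_true(is_assembled(st$energy, assembly_threshold(25, -4)))
  }
})

test_that("rotated and mirrored assemblies reach the minimum only under UDI", {
  ts <- random_target_set(25, 2, seed = 19)
  thr <- assembly_threshold(25, -4)
  p_udi <- interaction_params(-4, -1, "UDI")
  p_di <- interaction_params(-4, -1, "DI")
  for (tf in list(c(rotate = 1, mirror = FALSE), c(rotate = 2, mirror = FALSE),
                  c(rotate = 0, mirror = TRUE))) {
    st_u <- assembled_state(ts, p_udi, 15, m = 1, rotate = tf[["rotate"]],
                            mirror = as.logical(tf[["mirror"]]))
    st_d <- assembled_state(ts, p_di, 15, m = 1, rotate = tf[["rotate"]],
                            mirror = as.logical(tf[["mirror"]]))
    expect_true(is_assembled(st_u$energy, thr))
    expect_false(is_assembled(st_d$energy, thr))
  }
})

test_that("UDI total energy is invariant under lattice rotation of the state", {
  ts <- random_target_set(9, 2, seed = 23)
  p <- interaction_params(-4, -1, "UDI")
  L <- 7
  set.seed(41)
  for (rep in 1:20) {
    sites <- sample(0:(L^2 - 1), 9)
    pos <- cbind(sites %/% L, sites %% L)
    states <- sample(2, 9, replace = TRUE)
    st <- lattice_state(pos, states, L, ts, p)
    rot <- cbind(pos[, 2], (L - 1) - pos[, 1])       # 90 degree rotation
    mir <- cbind(pos[, 1], (L - 1) - pos[, 2])       # mirror
    expect_equal(lattice_state(rot, states, L, ts, p)$energy, st$energy)
    expect_equal(lattice_state(mir, states, L, ts, p)$energy, st$energy)
  }
})

test_that("isolated particles and single bonds give the expected totals", {
  ts <- domino_targets()
  p <- interaction_params(-4, -1, "UDI")
  st0 <- lattice_state(rbind(c(0, 0), c(5, 5)), c(1, 1), 11, ts, p)
  expect_equal(st0$energy, 0)
  st1 <- lattice_state(rbind(c(0, 0), c(0, 1)), c(1, 1), 11, ts, p)
  expect_equal(st1$energy, -4)
})
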