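# A tiny hand-built ensemble: 3 assembled trajectories, binning factor 1.
toy_ensemble <- function(energies, t_fas = vapply(energies, length, 1)) {
  traj <- purrr::map2_dfr(energies, seq_along(energies), function(e, k) {
    tibble::tibble(realization = k, sweep = seq_along(e),
                   mc_step = seq_along(e), energy = e)
  })
  runs <- tibble::tibble(
    realization = seq_along(energies), seed = seq_along(energies),
    t_fas = t_fas, assembled = TRUE
  )
  slmassembly:::new_assembly_ensemble(traj, runs, list(bin = 1))
}

test_that("the survivor average drops trajectories past their assembly time", {
  # identical trajectories: average equals any one of them
  e <- list(c(0, -1, -2), c(0, -1, -2), c(0, -1, -2))
  sa <- survivor_average(toy_ensemble(e))
  expect_equal(sa$e_avg, c(0, -1, -2))
  # one run assembling early leaves the other alone afterwards
  e2 <- list(c(0, -2, -4, -6, -8), c(0, -4, -4, -4, -4))
  sa2 <- survivor_average(toy_ensemble(e2, t_fas = c(5, 2)))
  expect_equal(sa2$e_avg, c(0, -3, -4, -6, -8))
  expect_equal(sa2$n_survivors, c(2, 2, 1, 1, 1))
  # hand-computed 3-trajectory case matches the per-sweep mean
  e3 <- list(c(0, -3, -6), c(-1, -2, -3), c(-2, -4, -6))
  sa3 <- survivor_average(toy_ensemble(e3, t_fas = c(3, 3, 2)))
  expect_equal(sa3$e_avg,
               c(mean(c(0, -1, -2)), mean(c(-3, -2, -4)), mean(c(-6, -3))))
})

test_that("the trajectory RMSD matches its closed forms", {
  # identical trajectories deviate by zero
  e <- list(c(0, -1, -2), c(0, -1, -2))
  r <- trajectory_rmsd(toy_ensemble(e))
  expect_equal(r$rmsd, c(0, 0))
  # constant offset d gives RMSD d (against a flat partner)
  e2 <- list(rep(-4, 6), rep(-6, 6))
  r2 <- trajectory_rmsd(toy_ensemble(e2))
  expect_equal(r2$rmsd, c(1, 1))  # average is -5, both sit 1 away
  # toy series {0, 2} against average {1, 1}
  e3 <- list(c(0, 2), c(2, 0))
  r3 <- trajectory_rmsd(toy_ensemble(e3))
  expect_equal(r3$rmsd, c(1, 1))
  # adding a common constant to every trajectory leaves RMSD unchanged
  shift <- trajectory_rmsd(toy_ensemble(lapply(e3, function(x) x + 11)))
  expect_equal(shift$rmsd, r3$rmsd)
})

test_that("the first-assembly spread follows the sample convention", {
  expect_equal(tfas_spread(c(100, 300)), sd(c(100, 300)))
  expect_equal(tfas_spread(c(100, 300)), 200 / sqrt(2))
  expect_equal(tfas_spread(c(5, 5, 5)), 0)
  expect_equal(tfas_spread(3 * c(100, 200, 400)), 3 * tfas_spread(c(100, 200, 400)))
  expect_error(tfas_spread(100), "at least 2")
})

test_that("log-normal fits recover known parameters and truncate the KDE", {
  set.seed(4)
  x <- rlnorm(1e4, meanlog = 13, sdlog = 0.6)
  fit <- fit_tfas(x)
  expect_lt(abs(fit$meanlog - 13) / 13, 0.05)
  expect_lt(abs(fit$sdlog - 0.6) / 0.6, 0.05)
  expect_lte(max(fit$kde$t), max(x))
  expect_gte(min(fit$kde$t), min(x))
  # the KDE mass over the truncated support is close to its coverage
  dx <- diff(fit$kde$t[1:2])
  mass <- sum(fit$kde$density) * dx
  expect_lt(abs(mass - mean(x >= min(x) & x <= max(x))), 0.15)
  # degenerate samples are flagged rather than fitted
  expect_true(fit_tfas(rep(1000, 6))$degenerate)
  expect_error(fit_tfas(c(-1, 2, 3, 4, 5)), "positive")
  expect_error(fit_tfas(c(10, 20)), "at least 5")
})

test_that("predictability correlates exactly for affine relations", {
  v <- c(10, 20, 40, 80, 25)
  r_affine <- 0.2 + 3 / v          # R exactly affine in 1/variability
  out <- predictability_correlation(r_affine, v)
  expect_equal(out$pearson_r, 1)
  expect_equal(out$slope, 3)
  expect_equal(out$intercept, 0.2)
  out2 <- predictability_correlation(-r_affine, v)
  expect_equal(out2$pearson_r, -1)
  # 5-point hand case matches the covariance formula
  r5 <- c(0.4, 0.55, 0.6, 0.3, 0.52)
  v5 <- c(50, 20, 15, 80, 22)
  out5 <- predictability_correlation(r5, v5)
  iv <- 1 / v5
  expect_equal(out5$pearson_r,
               sum((r5 - mean(r5)) * (iv - mean(iv))) /
                 sqrt(sum((r5 - mean(r5))^2) * sum((iv - mean(iv))^2)))
  expect_error(predictability_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_true(is.na(predictability_correlation(c(1, 1, 1), v[1:3])$pearson_r))
})
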