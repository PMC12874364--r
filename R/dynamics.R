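#' Cluster-size cutoff draws
#'
#' Samples the cluster-size cutoff `n_c` as the smallest integer strictly
#' greater than `1/xi` with `xi ~ Uniform(0, 1]`, so `P(n_c >= k) = 1/(k - 1)`
#' for `k >= 2` and a cluster of `n` particles passes the cutoff with
#' probability `1/(n - 1)`.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed (drawn from R's RNG when `NULL`).
#' @return A numeric vector of cutoffs (all >= 2).
#' @export
draw_cluster_cutoff <- function(n = 1, seed = NULL) {
  .cpp_draw_cutoffs(as.integer(n), draw_stream_seed(seed))
}

#' Virtual-link probability
#'
#' The probability used during cluster construction to form a virtual link
#' between an in-cluster particle and an interacting neighbour:
#' `max(0, 1 - exp(-(eps_after - eps_before)))`, zeroed for non-interacting
#' pairs or when the size cutoff is exhausted. Only moves that would weaken or
#' break a bond can recruit.
#'
#' @param eps_before Pair energy in the current geometry.
#' @param eps_after Pair energy after the virtual displacement.
#' @param interacting Logical; `FALSE` forces 0.
#' @param capacity_ok Logical; `FALSE` (cutoff exhausted) forces 0.
#' @return Link probability in `[0, 1]`.
#' @export
link_probability <- function(eps_before, eps_after, interacting = TRUE,
                             capacity_ok = TRUE) {
  p <- pmax(0, 1 - exp(-(eps_after - eps_before)))
  p * as.numeric(interacting) * as.numeric(capacity_ok)
}

#' Single-particle move acceptance probe
#'
#' Deterministic acceptance probability for moving one particle one site:
#' blocked destinations reject outright, otherwise Metropolis
#' `min(1, exp(-dE))`.
#'
#' @param state A [lattice_state()].
#' @param targets A [target_set()].
#' @param params An [interaction_params()].
#' @param particle Particle label.
#' @param direction 1..4 or `"up"/"down"/"left"/"right"`.
#' @return A list with `blocked`, `delta_e`, `prob`.
#' @export
spmc_acceptance <- function(state, targets, params, particle, direction) {
  ma <- model_args(targets, params, state$lattice)
  do.call(.cpp_spmc_prob, c(ma, state_args(state), list(
    particle = as.integer(particle - 1L),
    direction = direction_index(direction)
  )))
}

#' One single-particle Monte Carlo move
#'
#' Uniformly selects a particle and direction, rejects occupied destinations,
#' and otherwise accepts with the Metropolis probability, updating the cached
#' energy incrementally.
#'
#' @inheritParams spmc_acceptance
#' @param seed Optional integer seed.
#' @return A list with `accepted`, `particle`, `direction` and the updated
#'   `state`.
#' @export
spmc_move <- function(state, targets, params, seed = NULL) {
  with_seed(seed, {
    p <- sample.int(state$n_particles, 1L)
    d <- sample.int(4L, 1L)
    probe <- spmc_acceptance(state, targets, params, p, d)
    accepted <- !probe$blocked && stats::runif(1) < probe$prob
    if (accepted) {
      state$positions[p, ] <- (state$positions[p, ] + direction_vector(d)) %%
        state$lattice
      state$energy <- state$energy + probe$delta_e
    }
    list(accepted = accepted, particle = p, direction = d, state = state)
  })
}

#' Tentative cluster-move construction
#'
#' Builds one virtual-move cluster by breadth-first recruitment from the seed
#' particle: every interacting (cluster, non-cluster) pair is Bernoulli-tested
#' at most once at [link_probability()], particles blocking a member's
#' destination are recruited with probability 1 (hard core), and the matching
#' reverse-move link factors are recorded from the post-move geometry with the
#' opposite displacement. Recruitment beyond the cutoff `n_c` marks the move
#' frustrated (acceptance 0).
#'
#' @inheritParams spmc_acceptance
#' @param seed_particle Seed particle label.
#' @param direction Move direction.
#' @param n_c Cluster-size cutoff; drawn via [draw_cluster_cutoff()] when
#'   `NULL`.
#' @param seed Optional integer seed for the Bernoulli trials.
#' @return A list of class `cluster_move` with the members, the accumulated
#'   log link factors (formed and failed, forward and reverse), the boundary
#'   energy change `delta_e`, `frustrated`, and the final `acceptance`.
#' @export
cluster_probe <- function(state, targets, params, seed_particle, direction,
                          n_c = NULL, seed = NULL) {
  rng_seed <- draw_stream_seed(seed)
  if (is.null(n_c)) n_c <- draw_cluster_cutoff(1, seed = rng_seed + 1)
  ma <- model_args(targets, params, state$lattice)
  out <- do.call(.cpp_cluster_probe, c(ma, state_args(state), list(
    seed_particle = as.integer(seed_particle - 1L),
    direction = direction_index(direction),
    n_c = as.double(n_c),
    rng_seed = rng_seed
  )))
  out$seed <- out$seed + 1L
  out$direction <- out$direction + 1L
  out$members <- out$members + 1L
  class(out) <- "cluster_move"
  out
}

#' Cluster-move acceptance probability
#'
#' Recomputes the final acceptance of a tentative cluster move from its
#' recorded pieces: 0 when frustrated (cutoff exceeded) or when any required
#' reverse factor vanishes, otherwise
#' `n_C^(-1/2) * min(1, exp(-dE) * (reverse factors) / (forward factors))`.
#' The `n_C^(-1/2)` diffusivity factor mimics the Stokes-drag scaling of
#' physical cluster diffusion.
#'
#' @param move A `cluster_move` from [cluster_probe()].
#' @return Acceptance probability in `[0, 1]`.
#' @export
vmmc_acceptance <- function(move) {
  stopifnot(inherits(move, "cluster_move"))
  if (move$frustrated || move$reverse_zero) return(0)
  log_ratio <- (move$log_rev_formed - move$log_fwd_formed) +
    (move$log_rev_failed - move$log_fwd_failed)
  min(1, exp(-move$delta_e + log_ratio)) / sqrt(move$n_members)
}

#' One virtual-move Monte Carlo move
#'
#' Composes [draw_cluster_cutoff()], [cluster_probe()] and
#' [vmmc_acceptance()]; on acceptance all members translate one site and the
#' cached energy is updated by the boundary energy change.
#'
#' @inheritParams spmc_acceptance
#' @param seed Optional integer seed.
#' @return A list with `accepted`, `move` (the `cluster_move`) and the updated
#'   `state`.
#' @export
vmmc_move <- function(state, targets, params, seed = NULL) {
  with_seed(seed, {
    p <- sample.int(state$n_particles, 1L)
    d <- sample.int(4L, 1L)
    nc <- draw_cluster_cutoff(1)
    move <- cluster_probe(state, targets, params, p, d, n_c = nc)
    acc <- vmmc_acceptance(move)
    accepted <- acc > 0 && stats::runif(1) < acc
    if (accepted) {
      shift <- direction_vector(d)
      state$positions[move$members, 1L] <-
        (state$positions[move$members, 1L] + shift[1L]) %% state$lattice
      state$positions[move$members, 2L] <-
        (state$positions[move$members, 2L] + shift[2L]) %% state$lattice
      state$energy <- state$energy + move$delta_e
    }
    list(accepted = accepted, move = move, state = state)
  })
}

#' Self-healing drive bias
#'
#' Exponent bias for switching `particle` to `proposed_state`: `+dmu` when at
#' least two current nearest neighbours already hold the proposed state,
#' `-dmu` when at least two hold the particle's current state; the two
#' contributions are evaluated independently and summed, so e.g. four
#' neighbours split two-and-two between the current and proposed states give a
#' net bias of zero.
#'
#' @inheritParams spmc_acceptance
#' @param proposed_state Proposed internal state (1..M, different from the
#'   current one).
#' @param dmu Drive magnitude.
#' @return The bias added to the Metropolis exponent.
#' @export
drive_bias <- function(state, targets, params, particle, proposed_state, dmu) {
  if (proposed_state == state$states[particle])
    stop("proposed state must differ from the current state")
  ma <- model_args(targets, params, state$lattice)
  do.call(.cpp_drive_bias, c(ma, state_args(state), list(
    particle = as.integer(particle - 1L),
    new_state = as.integer(proposed_state - 1L),
    dmu = dmu
  )))
}

#' State-switch acceptance probe
#'
#' Acceptance probability `min(1, exp(-dE + bias))` for switching one
#' particle's internal state under the drive.
#'
#' @inheritParams drive_bias
#' @return A list with `delta_e`, `bias`, `prob`.
#' @export
state_switch_acceptance <- function(state, targets, params, particle,
                                    proposed_state, dmu = 0) {
  ma <- model_args(targets, params, state$lattice)
  do.call(.cpp_switch_prob, c(ma, state_args(state), list(
    particle = as.integer(particle - 1L),
    new_state = as.integer(proposed_state - 1L),
    dmu = dmu
  )))
}

#' One state-switch attempt
#'
#' Uniformly selects a particle other than `exclude` (the particle moved in
#' this iteration's physical sub-step) and a new internal state distinct from
#' its current one, then accepts with `min(1, exp(-dE + bias))`. Only a single
#' particle can change its state per iteration; with one stored target this is
#' a no-op.
#'
#' @inheritParams spmc_acceptance
#' @param dmu Drive magnitude.
#' @param exclude Particle label excluded from selection (or `NULL`).
#' @param seed Optional integer seed.
#' @return A list with `accepted`, `particle`, `new_state` and the updated
#'   `state`.
#' @export
state_switch <- function(state, targets, params, dmu = 0, exclude = NULL,
                         seed = NULL) {
  if (targets$n_targets < 2L)
    return(list(accepted = FALSE, particle = NA_integer_,
                new_state = NA_integer_, state = state))
  with_seed(seed, {
    cand <- setdiff(seq_len(state$n_particles), exclude)
    if (!length(cand))
      return(list(accepted = FALSE, particle = NA_integer_,
                  new_state = NA_integer_, state = state))
    p <- cand[sample.int(length(cand), 1L)]
    others <- setdiff(seq_len(targets$n_targets), state$states[p])
    snew <- others[sample.int(length(others), 1L)]
    probe <- state_switch_acceptance(state, targets, params, p, snew, dmu)
    accepted <- stats::runif(1) < probe$prob
    if (accepted) {
      state$states[p] <- snew
      state$energy <- state$energy + probe$delta_e
    }
    list(accepted = accepted, particle = p, new_state = snew, state = state)
  })
}
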