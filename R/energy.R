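#' Interaction parameters
#'
#' Strong and weak pair energies (in units of \eqn{k_B T}; the inverse
#' temperature is absorbed, so Boltzmann factors are `exp(-E)`) and the
#' interaction mode. Under undirected interactions (`"UDI"`) a pair interacts
#' strongly whenever it is a nearest-neighbour pair in a stored target,
#' irrespective of orientation; under directed interactions (`"DI"`) the strong
#' bond additionally requires the pair's current displacement to equal the
#' displacement stored in the target, so rotated or mirrored arrangements only
#' reach the weak energy.
#'
#' @param js Strong interaction energy (<= jw <= 0). Default -4.
#' @param jw Weak interaction energy. Default -1.
#' @param mode `"UDI"` or `"DI"`.
#' @return An object of class `interaction_params`.
#' @export
interaction_params <- function(js = -4, jw = -1, mode = c("UDI", "DI")) {
  mode <- match.arg(mode)
  if (!(js <= jw && jw <= 0))
    stop("invalid configuration: need js <= jw <= 0")
  structure(list(js = js, jw = jw, mode = mode), class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf("<interaction_params> Js = %g, Jw = %g, mode = %s\n",
              x$js, x$jw, x$mode))
  invisible(x)
}

#' Pair interaction energy
#'
#' Energy of the bond between adjacent particles `i` and `j` given every
#' particle's internal state. With `A_m` meaning "(i, j) are a neighbouring
#' pair in target m" (under DI, also sharing the stored displacement), the
#' branches are: `Js` when both states match one such target (or each matches a
#' different one), `(Js + Jw) / 2` when exactly one state matches, and `Jw`
#' otherwise.
#'
#' @param i,j Particle labels (1-based).
#' @param displacement Integer vector `c(row, col)`: the periodic-minimal
#'   lattice vector from `i` to `j`; must have Manhattan length 1.
#' @param states Integer vector of internal states for all particles (1..M).
#' @param targets A [target_set()].
#' @param params An [interaction_params()].
#' @return The bond energy in \eqn{k_B T}.
#' @export
pair_energy <- function(i, j, displacement, states, targets, params) {
  if (i == j) stop("contract violation: i and j must differ")
  if (sum(abs(displacement)) != 1L)
    stop("contract violation: particles are not nearest neighbours")
  ma <- model_args(targets, params, lattice = 1000000L)
  do.call(.cpp_pair_energy, c(ma, list(
    i = i - 1L, j = j - 1L,
    dr = as.integer(displacement[1L]), dc = as.integer(displacement[2L]),
    si = as.integer(states[i] - 1L), sj = as.integer(states[j] - 1L)
  )))
}

#' Total system energy
#'
#' Sum of [pair_energy()] over all currently adjacent unordered particle
#' pairs, each counted once.
#'
#' @param state A [lattice_state()].
#' @param targets A [target_set()].
#' @param params An [interaction_params()].
#' @return Total energy in \eqn{k_B T}.
#' @export
total_energy <- function(state, targets, params) {
  ma <- model_args(targets, params, lattice = state$lattice)
  do.call(.cpp_total_energy, c(ma, state_args(state)))
}

#' Assembled-target energy
#'
#' The global energy minimum: all `2 * sqrt(N) * (sqrt(N) - 1)` bonds of the
#' square target at the strong energy, i.e. `2 * js * sqrt(N) * (sqrt(N) - 1)`.
#'
#' @param n_particles Number of particles; must be a perfect square.
#' @param js Strong interaction energy.
#' @return The assembly detection threshold in \eqn{k_B T}.
#' @export
assembly_threshold <- function(n_particles, js) {
  if (!is_perfect_square(n_particles))
    stop("invalid configuration: n_particles must be a perfect square")
  k <- round(sqrt(n_particles))
  2 * js * k * (k - 1)
}

#' Assembly detection
#'
#' A sampled energy counts as assembled when it reaches the global minimum
#' (within a 1e-9 numerical slack).
#'
#' @param energy Sampled energy value(s).
#' @param threshold Output of [assembly_threshold()].
#' @return Logical vector.
#' @export
is_assembled <- function(energy, threshold) {
  energy <= threshold + 1e-9
}
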