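#' Lattice system state
#'
#' Positions (0-based `(row, col)` coordinates on the `L x L` periodic
#' lattice), internal states and the cached total energy of the `N`
#' distinguishable particles. Positions and site occupancy are mutually
#' inverse; at most one particle per site.
#'
#' @param positions An `N x 2` integer matrix of 0-based `(row, col)`
#'   coordinates (row `i` is particle `i`), or a data frame with columns
#'   `label`, `row`, `col`.
#' @param states Integer vector of internal states (1..M).
#' @param lattice Lattice side length `L` (>= 2).
#' @param targets A [target_set()] used to compute the cached energy.
#' @param params An [interaction_params()].
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(positions, states, lattice, targets, params) {
  if (is.data.frame(positions)) {
    positions <- positions[order(positions$label), ]
    positions <- cbind(positions$row, positions$col)
  }
  positions <- as.matrix(positions)
  storage.mode(positions) <- "integer"
  n <- nrow(positions)
  lattice <- as.integer(lattice)
  if (lattice < 2L) stop("invalid configuration: lattice side must be >= 2")
  if (lattice^2 < n) stop("invalid configuration: more particles than sites")
  if (any(positions < 0L) || any(positions >= lattice))
    stop("positions out of lattice bounds")
  site <- positions[, 1L] * lattice + positions[, 2L]
  if (anyDuplicated(site)) stop("two particles on one site")
  states <- as.integer(states)
  if (length(states) != n) stop("states must have one entry per particle")
  if (any(states < 1L) || any(states > targets$n_targets))
    stop("states must lie in 1..M")
  x <- structure(
    list(lattice = lattice, n_particles = n, positions = positions,
         states = states, energy = NA_real_),
    class = "lattice_state"
  )
  x$energy <- total_energy(x, targets, params)
  x
}

#' Random initial state
#'
#' `N` distinct uniformly chosen sites and uniform internal states, the random
#' initial condition of every simulation.
#'
#' @param targets A [target_set()].
#' @param params An [interaction_params()].
#' @param lattice Lattice side length.
#' @param seed Optional integer seed.
#' @return A [lattice_state()].
#' @export
random_state <- function(targets, params, lattice = 15, seed = NULL) {
  n <- targets$n_particles
  lattice <- as.integer(lattice)
  if (lattice^2 < n) stop("invalid configuration: more particles than sites")
  with_seed(seed, {
    sites <- sample.int(lattice^2, n) - 1L
    states <- sample.int(targets$n_targets, n, replace = TRUE)
    lattice_state(
      cbind(sites %/% lattice, sites %% lattice),
      states, lattice, targets, params
    )
  })
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d particles on a %d x %d lattice, E = %g kT\n",
              x$n_particles, x$lattice, x$lattice, x$energy))
  invisible(x)
}

#' @export
as_tibble.lattice_state <- function(x, ...) {
  tibble::tibble(
    label = seq_len(x$n_particles),
    row = as.integer(x$positions[, 1L]),
    col = as.integer(x$positions[, 2L]),
    state = x$states
  )
}

#' Largest connected cluster
#'
#' Size of the largest connected component of occupied sites under
#' nearest-neighbour (periodic) adjacency.
#'
#' @param state A [lattice_state()].
#' @return An integer cluster size.
#' @export
max_cluster_size <- function(state) {
  .cpp_max_cluster(state$lattice,
                   as.integer(state$positions[, 1L]),
                   as.integer(state$positions[, 2L]))
}
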