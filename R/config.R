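#' Simulation configuration
#'
#' All knobs of one simulation realization. The defaults reproduce the study's
#' default parameter table: 25 particles with 2 encoded targets on a 15 x 15
#' lattice, `Js = -4`, `Jw = -1` (\eqn{k_B T}), and a binning factor / step
#' budget of 500 / 5e6 for directed interactions and 5000 / 5e7 otherwise
#' (directed systems assemble an order of magnitude faster and are sampled more
#' finely). The drive `dmu` is stored as a magnitude with the
#' favourable-positive convention: switches towards a local state majority gain
#' `+dmu` in the Metropolis exponent.
#'
#' @param n_particles Number of particles `N` (perfect square).
#' @param lattice Lattice side `L` (>= 3, `L^2 >= N`).
#' @param n_targets Number of stored targets `M`.
#' @param js,jw Strong/weak interaction energies (`js <= jw <= 0`).
#' @param dmu Drive magnitude `|dmu| >= 0`.
#' @param dynamics `"VMMC"` (collective cluster moves) or `"SPMC"`
#'   (single-particle Metropolis).
#' @param mode `"UDI"` or `"DI"`.
#' @param n_steps Total MC iterations `T`; default depends on `mode`.
#' @param bin Binning factor `n_MC`: the energy is sampled every `bin`
#'   iterations (one sweep); default depends on `mode`.
#' @param seed Integer seed of the realization.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(dynamics = "SPMC", dmu = 1)
#' @export
sim_config <- function(n_particles = 25, lattice = 15, n_targets = 2,
                       js = -4, jw = -1, dmu = 0,
                       dynamics = c("VMMC", "SPMC"), mode = c("UDI", "DI"),
                       n_steps = NULL, bin = NULL, seed = 1L) {
  dynamics <- match.arg(dynamics)
  mode <- match.arg(mode)
  if (!is_perfect_square(n_particles))
    stop("invalid configuration: n_particles must be a perfect square")
  lattice <- as.integer(lattice)
  if (lattice < 3L)
    stop("invalid configuration: dynamics require lattice side >= 3")
  if (lattice^2 < n_particles)
    stop("invalid configuration: more particles than sites")
  if (!(js <= jw && jw <= 0))
    stop("invalid configuration: need js <= jw <= 0")
  dmu <- abs(dmu)
  if (is.null(bin)) bin <- if (mode == "DI") 500 else 5000
  if (is.null(n_steps)) n_steps <- if (mode == "DI") 5e6 else 5e7
  if (bin < 1) stop("invalid configuration: bin must be >= 1")
  if (n_steps < 0) stop("invalid configuration: n_steps must be >= 0")
  structure(
    list(n_particles = as.integer(n_particles), lattice = lattice,
         n_targets = as.integer(n_targets), js = js, jw = jw, dmu = dmu,
         dynamics = dynamics, mode = mode, n_steps = n_steps, bin = bin,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %s/%s: N = %d, L = %d, M = %d, Js = %g, Jw = %g, ",
           "dmu = %g, T = %g, bin = %g, seed = %d\n"),
    x$dynamics, x$mode, x$n_particles, x$lattice, x$n_targets,
    x$js, x$jw, x$dmu, x$n_steps, x$bin, x$seed
  ))
  invisible(x)
}
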