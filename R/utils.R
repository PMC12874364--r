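# Internal helpers

# Evaluate `code` with a temporarily seeded R RNG, restoring .Random.seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# A fresh integer seed for C++ RNG streams, drawn from R's RNG.
draw_stream_seed <- function(seed = NULL) {
  if (!is.null(seed)) return(as.double(seed))
  as.double(sample.int(.Machine$integer.max, 1L))
}

direction_index <- function(direction) {
  if (is.character(direction)) {
    idx <- match(direction, c("up", "down", "left", "right"))
    if (anyNA(idx)) stop("direction must be one of 'up', 'down', 'left', 'right'")
    return(idx - 1L)
  }
  d <- as.integer(direction)
  if (any(d < 1L | d > 4L)) stop("direction index must be in 1..4")
  d - 1L
}

direction_vector <- function(direction) {
  d <- direction_index(direction) + 1L
  rbind(
    c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)
  )[d, , drop = FALSE]
}

# Flatten a target_set + interaction_params into the argument list shared by
# all C++ entry points.
model_args <- function(targets, params, lattice) {
  stopifnot(inherits(targets, "target_set"), inherits(params, "interaction_params"))
  list(
    L = as.integer(lattice),
    N = targets$n_particles,
    M = targets$n_targets,
    js = params$js,
    jw = params$jw,
    directed = identical(params$mode, "DI"),
    adj = targets$adj,
    tdr = targets$tdr,
    tdc = targets$tdc
  )
}

state_args <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  list(
    pr = as.integer(state$positions[, 1L]),
    pc = as.integer(state$positions[, 2L]),
    ps = as.integer(state$states - 1L)
  )
}

is_perfect_square <- function(n) {
  k <- round(sqrt(n))
  k * k == n
}
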