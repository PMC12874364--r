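#' Stored target structures
#'
#' A target set holds the `M` memorised arrangements of the `N` distinguishable
#' particles. Each target is a bijection of the particle labels onto a
#' rectangular block of lattice offsets (the canonical shape is the
#' `sqrt(N) x sqrt(N)` square). From the placements the pair lookup is derived:
#' for every unordered label pair, the targets in which the two particles are
#' nearest neighbours, and (for directed interactions) the stored displacement
#' of one relative to the other.
#'
#' @param placements Either a list of integer matrices (one per target, each a
#'   permutation of `1:N` arranged in the target block) or a data frame with
#'   columns `target`, `label`, `row`, `col` (offsets are 0-based integers).
#' @return An object of class `target_set`.
#' @examples
#' ts <- random_target_set(25, 2, seed = 1)
#' dplyr::count(target_table(ts), target)
#' @export
target_set <- function(placements) {
  if (is.data.frame(placements)) {
    placements <- unname(split(placements, placements$target))
    placements <- lapply(placements, function(df) {
      nr <- max(df$row) + 1L
      nc <- max(df$col) + 1L
      if (min(df$row) != 0L || min(df$col) != 0L)
        stop("target offsets must start at (0, 0)")
      m <- matrix(NA_integer_, nr, nc)
      m[cbind(df$row + 1L, df$col + 1L)] <- as.integer(df$label)
      if (anyNA(m)) stop("target offsets must fill the block contiguously")
      m
    })
  }
  if (!is.list(placements) || !length(placements))
    stop("placements must be a non-empty list of matrices or a data frame")
  placements <- lapply(placements, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  })
  n <- length(placements[[1L]])
  for (m in placements) {
    if (length(m) != n || !setequal(as.vector(m), seq_len(n)))
      stop("each target must place every label 1..N exactly once")
    if (!all(dim(m) == dim(placements[[1L]])))
      stop("all targets must share the same block shape")
  }
  M <- length(placements)
  adj <- array(0L, dim = c(n, n, M))  # indexed [j, i, m], matching the C++ layout
  tdr <- array(0L, dim = c(n, n, M))
  tdc <- array(0L, dim = c(n, n, M))
  for (m in seq_len(M)) {
    mat <- placements[[m]]
    nr <- nrow(mat); nc <- ncol(mat)
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        i <- mat[r, c]
        if (c < nc) {
          j <- mat[r, c + 1L]
          adj[j, i, m] <- adj[i, j, m] <- 1L
          tdr[j, i, m] <- 0L; tdc[j, i, m] <- 1L
          tdr[i, j, m] <- 0L; tdc[i, j, m] <- -1L
        }
        if (r < nr) {
          j <- mat[r + 1L, c]
          adj[j, i, m] <- adj[i, j, m] <- 1L
          tdr[j, i, m] <- 1L; tdc[j, i, m] <- 0L
          tdr[i, j, m] <- -1L; tdc[i, j, m] <- 0L
        }
      }
    }
  }
  structure(
    list(
      n_particles = n,
      n_targets = M,
      block = dim(placements[[1L]]),
      placements = placements,
      adj = as.integer(adj),
      tdr = as.integer(tdr),
      tdc = as.integer(tdc)
    ),
    class = "target_set"
  )
}

#' Randomise a target set
#'
#' Draws `n_targets` independent uniform-random bijections of the labels onto
#' the `sqrt(N) x sqrt(N)` square, the randomisation performed at the start of
#' every simulation.
#'
#' @param n_particles Number of particles `N`; must be a perfect square.
#' @param n_targets Number of stored targets `M` (one per internal state).
#' @param seed Optional integer seed; the draw is deterministic given the seed.
#' @return A [target_set()].
#' @export
random_target_set <- function(n_particles, n_targets, seed = NULL) {
  if (!is_perfect_square(n_particles))
    stop("invalid configuration: n_particles must be a perfect square")
  if (n_targets < 1L) stop("invalid configuration: n_targets must be >= 1")
  k <- as.integer(round(sqrt(n_particles)))
  placements <- with_seed(seed, {
    lapply(seq_len(n_targets), function(m) {
      matrix(sample.int(n_particles), k, k)
    })
  })
  target_set(placements)
}

#' Tabular view of a target set
#'
#' One row per (target, label) with the 0-based block offsets, the portable
#' serialisation format of a target set.
#'
#' @param x A `target_set`.
#' @return A tibble with columns `target`, `label`, `row`, `col`.
#' @export
target_table <- function(x) {
  stopifnot(inherits(x, "target_set"))
  purrr::map_dfr(seq_len(x$n_targets), function(m) {
    mat <- x$placements[[m]]
    idx <- which(!is.na(mat), arr.ind = TRUE)
    tibble::tibble(
      target = m,
      label = as.integer(mat[idx]),
      row = as.integer(idx[, 1L] - 1L),
      col = as.integer(idx[, 2L] - 1L)
    ) |> dplyr::arrange(.data$label)
  })
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf(
    "<target_set> %d particles, %d target(s), block %d x %d\n",
    x$n_particles, x$n_targets, x$block[1L], x$block[2L]
  ))
  invisible(x)
}

#' @export
as_tibble.target_set <- function(x, ...) target_table(x)
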