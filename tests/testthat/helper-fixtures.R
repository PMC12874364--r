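# Shared fixtures built in code.

# A 1x2 domino target pair for two particles (the smallest system with a
# nearest-neighbour pair in its target).
domino_targets <- function() target_set(list(matrix(1:2, 1, 2)))

# Two domino targets with opposite stored orientation; distinguishable under
# DI, degenerate under UDI.
mirrored_domino_targets <- function() {
  target_set(list(matrix(1:2, 1, 2), matrix(c(2L, 1L), 1, 2)))
}

# Place target `m` of a target set in the lattice corner (identity layout).
assembled_state <- function(targets, params, lattice, m = 1,
                            state = m, rotate = 0, mirror = FALSE) {
  mat <- targets$placements[[m]]
  for (r in seq_len(rotate %% 4)) mat <- t(mat)[, rev(seq_len(nrow(mat))), drop = FALSE]
  if (mirror) mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  pos <- matrix(0L, targets$n_particles, 2)
  for (r in seq_len(nrow(mat))) {
    for (c in seq_len(ncol(mat))) {
      pos[mat[r, c], ] <- c(r - 1L, c - 1L)
    }
  }
  lattice_state(pos, rep(state, targets$n_particles), lattice, targets, params)
}

# All ordered placements of `n` particles on distinct sites of an L x L
# lattice, as a matrix of site indices (0-based).
all_placements <- function(L, n) {
  sites <- 0:(L * L - 1)
  grids <- do.call(expand.grid, rep(list(sites), n))
  keep <- apply(grids, 1, function(x) !anyDuplicated(x))
  out <- as.matrix(grids[keep, , drop = FALSE])
  dimnames(out) <- NULL
  out
}
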