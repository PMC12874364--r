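# Independent brute-force re-implementation of the pair-energy branches and
# the total energy, working directly on target placement matrices. Used as the
# oracle the package's C++ energy path is checked against.

oracle_wrap <- function(d, L) {
  d <- d %% L
  ifelse(d > L / 2, d - L, d)
}

# Is (i, j) a neighbouring pair in target matrix `mat`, given the current
# displacement (dr, dc) from i to j? Under UDI adjacency in the target block
# suffices; under DI the stored displacement must match exactly.
oracle_in_target <- function(mat, i, j, dr, dc, mode) {
  pi_ <- which(mat == i, arr.ind = TRUE)
  pj_ <- which(mat == j, arr.ind = TRUE)
  tdr <- pj_[1] - pi_[1]
  tdc <- pj_[2] - pi_[2]
  if (abs(tdr) + abs(tdc) != 1) return(FALSE)
  if (mode == "UDI") return(TRUE)
  tdr == dr && tdc == dc
}

# Eq. 1 branch by branch.
oracle_pair_energy <- function(i, j, dr, dc, states, placements, mode, js, jw) {
  members <- vapply(placements, oracle_in_target, TRUE,
                    i = i, j = j, dr = dr, dc = dc, mode = mode)
  si <- states[i]; sj <- states[j]
  if (si == sj) {
    if (members[si]) return(js)
    return(jw)
  }
  if (members[si] && members[sj]) return(js)     # (i,j) in S_m and S_n
  if (members[si] || members[sj]) return((js + jw) / 2)
  jw
}

# Eq. 2: sum over adjacent unordered pairs.
oracle_total_energy <- function(positions, states, L, placements, mode, js, jw) {
  n <- nrow(positions)
  E <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dr <- oracle_wrap(positions[j, 1] - positions[i, 1], L)
      dc <- oracle_wrap(positions[j, 2] - positions[i, 2], L)
      if (abs(dr) + abs(dc) != 1) next
      E <- E + oracle_pair_energy(i, j, dr, dc, states, placements, mode, js, jw)
    }
  }
  E
}
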