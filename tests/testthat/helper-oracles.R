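# Shared oracles, independent of the implementation paths they check.

# Closed-form transient pgf of the linear birth-death process
# (birth rate b per individual, death rate g): F(s, t) from the Riccati
# solution of the backward equation.
bd_transient_pgf <- function(s, t, b, g) {
  lam <- b - g
  e <- exp(-lam * t)
  (g * (s - 1) - e * (b * s - g)) / (b * (s - 1) - e * (b * s - g))
}

# Matrix exponential via eigen-decomposition (fixtures are diagonalisable).
expm_eigen <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(A)) %*% solve(e$vectors))
}

# Brute-force moments of a sum of N independent variables from their
# per-variable moment sequences (rows k = 0..k_max), by direct enumeration
# of multi-indices with the multinomial theorem.
sum_moment_enum <- function(mom_list, k) {
  N <- length(mom_list)
  grid <- do.call(expand.grid, rep(list(0:k), N))
  grid <- grid[rowSums(grid) == k, , drop = FALSE]
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    l <- as.numeric(grid[r, ])
    coef <- exp(lgamma(k + 1) - sum(lgamma(l + 1)))
    tot <- tot + coef * prod(vapply(seq_len(N),
                                    function(i) mom_list[[i]][l[i] + 1],
                                    numeric(1)))
  }
  tot
}

ks_dist <- function(x, Fx) {
  x <- sort(x)
  n <- length(x)
  F <- Fx(x)
  max(abs(seq_len(n) / n - F), abs((seq_len(n) - 1) / n - F))
}

sir_fix <- fixture_sir()
seir_fix <- fixture_seir()
innate_fix <- fixture_innate()
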