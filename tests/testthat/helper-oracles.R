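# Independent oracles used to cross-check the implementation. These
# deliberately avoid the package's own code paths: cycle structure is found
# by exhaustive walking, the spectral abscissa by characteristic-polynomial
# root finding (Faddeev-LeVerrier + polyroot), components via igraph.

# Brute-force cycle enumeration on a successor map: a node is on a cycle iff
# walking from it returns to it within S steps. Distinct cycles are counted
# by partitioning cycle nodes into orbits.
oracle_cycles <- function(successor) {
  S <- length(successor)
  on_cycle <- vapply(seq_len(S), function(v) {
    u <- v
    for (k in seq_len(S)) {
      u <- successor[u]
      if (u == v) return(TRUE)
    }
    FALSE
  }, logical(1))
  nodes <- which(on_cycle)
  lengths <- integer(0)
  remaining <- nodes
  while (length(remaining)) {
    v <- remaining[1]
    orbit <- v
    u <- successor[v]
    while (u != v) {
      orbit <- c(orbit, u)
      u <- successor[u]
    }
    lengths <- c(lengths, length(orbit))
    remaining <- setdiff(remaining, orbit)
  }
  list(cycle_nodes = nodes, n_cycles = length(lengths), lengths = lengths)
}

oracle_n_components <- function(successor) {
  S <- length(successor)
  g <- igraph::graph_from_edgelist(cbind(seq_len(S), successor), directed = FALSE)
  igraph::components(g)$no
}

# Characteristic polynomial by Faddeev-LeVerrier; abscissa from polyroot.
oracle_abscissa_charpoly <- function(J) {
  n <- nrow(J)
  coefs <- numeric(n + 1)
  coefs[1] <- 1                       # lambda^n
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- J %*% M
    c_k <- -sum(diag(M)) / k
    coefs[k + 1] <- c_k
    M <- M + c_k * diag(n)
  }
  roots <- polyroot(rev(coefs))
  max(Re(roots))
}

# Marginal abundance of a bare loop network by direct root finding on an
# explicitly constructed cycle matrix (no package builders involved).
oracle_xc_loop_numeric <- function(L, S = L) {
  stopifnot(S >= L)
  succ <- c(seq_len(L)[-1], 1L)
  if (S > L) succ <- c(succ, sample.int(L, S - L, replace = TRUE))
  absc <- function(x) {
    w <- diag(-1, S)
    w[cbind(seq_len(S), succ)] <- (x - 1) / x
    max(Re(eigen(w, only.values = TRUE)$values))
  }
  stats::uniroot(absc, c(0.05, 0.99), tol = 1e-10)$root
}

# Small standard fixtures
fixture_cycle_topology <- function(L) {
  tree_topology(L, c(seq_len(L)[-1], 1L), L)
}
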