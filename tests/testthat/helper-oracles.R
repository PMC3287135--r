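# Independent oracles and small network builders shared across tests.

# brute-force O(N^2) DFT, straight from the definition (two-sided)
dft_brute <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(0:(N - 1), function(w)
    sum(x * exp(-2i * pi * w * n / N)), 0i)
}

# one-sided bin selection matching the package convention
one_sided <- function(z) z[seq_len(length(z) %/% 2 + 1)]

# angular distance, treating +pi and -pi as the same angle
phase_diff <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# hand K-S: normalize to unit sum, cumulate, max abs difference
ks_brute <- function(a, b) {
  max(abs(cumsum(a / sum(a)) - cumsum(b / sum(b))))
}

birth_death <- function(kb = 100, kd = 1, a0 = 0) {
  reaction_network(c(A = a0), list(
    reaction(character(), "A", mass_action(kb)),
    reaction("A", character(), mass_action(kd))), "count")
}

# two-state isomerization A <-> B with n molecules total (finite CME)
isomerization <- function(k1 = 1, k2 = 0.5, n = 3) {
  reaction_network(c(A = n, B = 0), list(
    reaction("A", "B", mass_action(k1)),
    reaction("B", "A", mass_action(k2))), "count")
}

# CME distribution of A at time t for the isomerization network, via the
# matrix exponential of the generator on the (n+1)-state space
cme_isomerization <- function(k1, k2, n, t) {
  states <- 0:n  # number of A molecules
  Q <- matrix(0, n + 1, n + 1)
  for (a in states) {
    i <- a + 1
    if (a > 0) Q[i, i - 1] <- k1 * a            # A -> B
    if (a < n) Q[i, i + 1] <- k2 * (n - a)      # B -> A
    Q[i, i] <- -(k1 * a + k2 * (n - a))
  }
  p0 <- numeric(n + 1)
  p0[n + 1] <- 1  # start with all molecules as A
  as.numeric(Matrix::expm(Matrix::Matrix(t(Q) * t)) %*% p0)
}

# random pure mass-action network over n species (for round-trip tests)
random_network <- function(n_species, n_reactions, seed) {
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  amounts <- stats::setNames(sample(0:500, n_species, replace = TRUE), sp)
  rx <- lapply(seq_len(n_reactions), function(j) {
    nr <- sample(0:2, 1)
    np <- sample(0:2, 1)
    if (nr == 0 && np == 0) np <- 1
    reactants <- sample(sp, nr)
    products <- sample(sp, np, replace = TRUE)
    mods <- setdiff(sample(sp, sample(0:1, 1)), reactants)
    reaction(reactants, products, mass_action(stats::runif(1, 1e-4, 2)),
             modifiers = mods)
  })
  reaction_network(amounts, rx, "count")
}

# random signed DAG as an influence_graph (edges respect node order, so
# every walk is a simple path and matrix powers enumerate them exactly)
random_dag <- function(n, p, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  from <- character(); to <- character(); sgn <- integer()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
      sgn <- c(sgn, sample(c(-1L, 1L), 1))
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, sign = sgn,
                                    stringsAsFactors = FALSE)),
            class = "influence_graph")
}

# path-sum oracle on a DAG via adjacency-matrix powers (walks = simple
# paths in a DAG); `signed` uses the signed adjacency matrix
dag_proximity_oracle <- function(g, source, max_len, signed = FALSE) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (e in seq_len(nrow(g$edges)))
    A[g$edges$from[e], g$edges$to[e]] <-
      A[g$edges$from[e], g$edges$to[e]] +
      (if (signed) g$edges$sign[e] else 1)
  out <- stats::setNames(numeric(n), g$nodes)
  P <- diag(n)
  for (L in seq_len(max_len)) {
    P <- P %*% A
    out <- out + P[match(source, g$nodes), ] / L
  }
  out
}
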