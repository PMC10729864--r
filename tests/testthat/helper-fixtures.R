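# Independent oracles and small fixtures shared across tests. Everything here
# is deliberately naive (enumeration, direct formulas, quadratic loops) so it
# checks the package's optimised paths without sharing code with them.

mat_key <- function(m) paste(m, collapse = "")

# All 0/1 matrices with the row and column sums of m0, by brute force over
# every 0/1 matrix of that shape (feasible up to ~16 cells).
enum_fixed_margin <- function(m0) {
  r <- rowSums(m0); cs <- colSums(m0); n <- length(m0)
  stopifnot(n <= 16L)
  out <- list()
  for (x in 0:(2^n - 1)) {
    m <- matrix(as.integer(intToBits(x)[1:n]), nrow(m0))
    if (all(rowSums(m) == r) && all(colSums(m) == cs))
      out[[length(out) + 1L]] <- m
  }
  out
}

# Naive checkerboard-swap sampler: repeatedly picks two rows and two columns
# and swaps a 2x2 checkerboard if present. Slow but transparently
# margin-preserving; used as an independent null-sampler oracle.
checkerboard_sample <- function(m, n_swaps) {
  nr <- nrow(m); nc <- ncol(m)
  for (t in seq_len(n_swaps)) {
    ij <- sample.int(nr, 2L); kl <- sample.int(nc, 2L)
    a <- m[ij[1L], kl[1L]]; b <- m[ij[1L], kl[2L]]
    c_ <- m[ij[2L], kl[1L]]; d <- m[ij[2L], kl[2L]]
    if (a == d && b == c_ && a != b) {
      m[ij[1L], kl[1L]] <- b; m[ij[1L], kl[2L]] <- a
      m[ij[2L], kl[1L]] <- d; m[ij[2L], kl[2L]] <- c_
    }
  }
  m
}

# Direct evaluation of the beta-binomial mass via the Beta function.
bb_pmf_direct <- function(n, K, a, b) {
  choose(K, n) * beta(n + a, K - n + b) / beta(a, b)
}

# Two-stage draw: latent Beta success probability, then binomial count.
rbetabinom <- function(nn, K, a, b) rbinom(nn, K, rbeta(nn, a, b))

# Expression fixture with two clearly separated groups for a subset of genes.
# Effects are large enough (6 log2 units against sd 0.1-0.5) that DEG calls
# are deterministic; `up` genes rise in group 1, `down` genes fall.
make_two_group_fixture <- function(genes = paste0("g", 1:6),
                                   up = "g1", down = "g2",
                                   n_per_group = 5L, sd = 0.1,
                                   effect = 5, seed = 99L) {
  set.seed(seed)
  ns <- 2L * n_per_group
  x <- matrix(rnorm(length(genes) * ns, mean = 5, sd = sd),
              length(genes), ns, dimnames = list(genes, paste0("s", 1:ns)))
  labels <- c(rep(0L, n_per_group), rep(1L, n_per_group))
  x[up, labels == 1L] <- x[up, labels == 1L] + effect
  x[down, labels == 1L] <- x[down, labels == 1L] - effect
  contrast_set("CX", x, labels)
}

# Small deterministic binary/signed matrix pair used across counting tests.
make_hand_matrices <- function() {
  binary <- matrix(c(1, 1, 0, 1,
                     1, 0, 0, 1,
                     0, 1, 1, 0), 3, 4, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), paste0("k", 1:4)))
  signed <- matrix(c(1, 1, 0, 1,
                     -1, 0, 0, 1,
                     0, -1, 1, 0), 3, 4, byrow = TRUE,
                   dimnames = dimnames(binary))
  storage.mode(binary) <- "integer"
  storage.mode(signed) <- "integer"
  list(binary = binary, signed = signed)
}

# igraph of n_cliques disjoint cliques of the given size, optionally joined
# in a chain by single bridge edges.
make_clique_graph <- function(clique_size = 10L, n_cliques = 2L,
                              bridged = FALSE) {
  edges <- NULL
  for (q in seq_len(n_cliques)) {
    nodes <- paste0("q", q, "_", seq_len(clique_size))
    cmb <- t(combn(nodes, 2L))
    edges <- rbind(edges, cmb)
    if (bridged && q > 1L)
      edges <- rbind(edges, c(paste0("q", q - 1L, "_1"), nodes[1L]))
  }
  igraph::graph_from_edgelist(edges, directed = FALSE)
}
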