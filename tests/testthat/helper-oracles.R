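# Shared oracles and small fixtures, all built in code.

# CODATA constants, written out independently of the package internals
ORACLE_H <- 6.62607015e-34
ORACLE_MUB <- 9.2740100783e-24
oracle_resonance_mT <- function(g, freq_GHz) {
  1e3 * ORACLE_H * freq_GHz * 1e9 / (g * ORACLE_MUB)
}

# analytic first-derivative Gaussian spectrum with peak amplitude `amp`
# and absorption sigma `sigma`, centred at b0
deriv_gaussian_spectrum <- function(b0, sigma, amp, field) {
  shape <- -(field - b0) / sigma^2 * exp(-(field - b0)^2 / (2 * sigma^2))
  epr_spectrum(field, amp * shape / max(abs(shape)), frequency_GHz = 9.67)
}

# least-squares branch lengths of a fixed topology against a distance
# matrix; returns the residual sum of squares (0 for the generating
# topology of additive data) and fitted patristic matrix
ls_fit_topology <- function(topo, d) {
  labs <- rownames(d)
  n <- length(labs)
  pairs <- utils::combn(n, 2)
  nedge <- nrow(topo$edge)
  A <- matrix(0, ncol(pairs), nedge)
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- match(labs[pairs[1, p]], topo$tip.label)
    j <- match(labs[pairs[2, p]], topo$tip.label)
    path_nodes <- ape::nodepath(topo, i, j)
    for (s in seq_len(length(path_nodes) - 1L)) {
      e <- which((topo$edge[, 1] == path_nodes[s] & topo$edge[, 2] == path_nodes[s + 1]) |
                 (topo$edge[, 2] == path_nodes[s] & topo$edge[, 1] == path_nodes[s + 1]))
      A[p, e] <- 1
    }
    y[p] <- d[pairs[1, p], pairs[2, p]]
  }
  fit <- stats::lm.fit(A, y)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# random additive distance matrix from a random tree with positive branches
random_additive_matrix <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.05, 1))
  dm <- ape::cophenetic.phylo(tr)
  ord <- order(rownames(dm))
  list(tree = tr, d = dm[ord, ord])
}

two_clade_newick <- paste0(
  "((A:0.1,B:0.1,(C:0.1,D:0.1):0.1):0.3,",
  "(E:0.1,F:0.1,(G:0.1,H:0.1):0.1):0.3);")
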