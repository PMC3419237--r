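## Distance-based protein phylogenetics: p/Poisson/Kimura distances,
## neighbor joining, column-bootstrap supports.

.GAP_CHARS <- c("-", ".", "?")

## coerce an alignment (character matrix, AAStringSet, or list/vector of
## equal-length strings) to a character matrix, taxa x sites
.as_aln_matrix <- function(aln) {
  if (is.matrix(aln) && is.character(aln)) {
    m <- aln
  } else if (inherits(aln, "AAStringSet") || inherits(aln, "XStringSet")) {
    seqs <- as.character(aln)
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(aln)
  } else if (is.character(aln) || is.list(aln)) {
    seqs <- unlist(aln)
    if (length(unique(nchar(seqs))) != 1L)
      stop("alignment rows must all have the same length")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  } else stop("unsupported alignment representation")
  if (nrow(m) < 2L) stop("alignment needs at least 2 sequences")
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

#' Pairwise protein distances from an alignment
#'
#' Uncorrected `p` distance (mismatches over compared columns, pairwise gap
#' deletion), Poisson correction `-ln(1 - p)`, or Kimura's protein
#' correction `-ln(1 - p - 0.2 p^2)`. Saturated pairs (correction argument
#' non-positive) are capped at `max_distance` with a warning.
#'
#' @param aln alignment: character matrix (taxa x sites), `AAStringSet`, or
#'   named character vector of equal-length gapped sequences.
#' @param model `"kimura"` (default), `"poisson"` or `"p"`.
#' @param max_distance cap for saturated pairs (default 10 substitutions
#'   per site).
#' @return Symmetric distance matrix with taxon labels (substitutions per
#'   site), zero diagonal.
#' @export
protein_distance <- function(aln, model = c("kimura", "poisson", "p"),
                             max_distance = 10) {
  model <- match.arg(model)
  m <- .as_aln_matrix(aln)
  n <- nrow(m)
  ok <- !matrix(m %in% .GAP_CHARS, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("taxa '", rownames(m)[i], "' and '", rownames(m)[j],
           "' share no gap-free columns")
    p <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    dij <- switch(model,
      p = p,
      poisson = { a <- 1 - p; if (a <= 0) NA_real_ else -log(a) },
      kimura = { a <- 1 - p - 0.2 * p^2; if (a <= 0) NA_real_ else -log(a) })
    if (is.na(dij) || dij > max_distance) { dij <- max_distance; saturated <- TRUE }
    d[i, j] <- d[j, i] <- dij
  }
  if (saturated)
    warning("saturated pair(s) capped at ", max_distance, " substitutions/site")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion. Negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' branch (preserving the path length through the new node); ties in Q are
#' broken deterministically by the current taxon/cluster order, which
#' follows the input label order.
#'
#' @param d symmetric distance matrix with taxon labels (or a `dist`).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(d)
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("'d' must be a square matrix")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) stop("'d' must be symmetric")
  if (any(diag(d) != 0)) stop("'d' must have a zero diagonal")

  fmt <- function(x) sprintf("%.12g", max(x, 0))
  ## node representation: growing newick fragments
  labs <- rownames(d)
  frag <- as.list(labs)
  D <- d
  while (length(frag) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    ## first minimum in column-major order = deterministic label-order tie-break
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- min(ij); j <- max(ij)
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    ## clamp negatives, moving the deficit to the sibling
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newfrag <- paste0("(", frag[[i]], ":", fmt(bi), ",",
                      frag[[j]], ":", fmt(bj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
  }
  ## final star join of the remaining three clusters
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[[1]], ":", fmt(b1), ",", frag[[2]], ":", fmt(b2),
                ",", frag[[3]], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for the neighbor-joining tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds distances
#' and NJ per replicate, and counts how often each internal bipartition of
#' the reference tree is recovered. Supports are attached to the reference
#' tree's node labels as counts out of `n_reps`; nodes with support above
#' `threshold * n_reps` are flagged (the conventional display rule, e.g.
#' over 150 of 300 replicates).
#'
#' @inheritParams protein_distance
#' @param n_reps bootstrap replicates (default 300).
#' @param seed RNG seed for column resampling.
#' @param threshold display-flag fraction of `n_reps` (default 0.5).
#' @return Object of class `boot_tree`: list with `tree` (an `ape::phylo`
#'   whose `node.label` holds support counts), `supports`, `flagged`
#'   (logical per internal node), `n_reps`.
#' @export
bootstrap_support <- function(aln, model = "kimura", n_reps = 300, seed = 1,
                              threshold = 0.5) {
  m <- .as_aln_matrix(aln)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (ncol(m) < 10L)
    warning("alignment has fewer than 10 columns; supports will be unstable")
  ref <- neighbor_joining(protein_distance(m, model))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    reps[[b]] <- neighbor_joining(
      suppressWarnings(protein_distance(m[, cols, drop = FALSE], model)))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(counts)
  structure(list(tree = ref, supports = counts,
                 flagged = counts > threshold * n_reps,
                 n_reps = n_reps, threshold = threshold),
            class = "boot_tree")
}

#' @export
print.boot_tree <- function(x, ...) {
  cat(sprintf("NJ tree with bootstrap supports (%d replicates)\n", x$n_reps))
  cat(sprintf("  %d tips, %d internal nodes, %d flagged above %.0f%%\n",
              length(x$tree$tip.label), x$tree$Nnode, sum(x$flagged),
              100 * x$threshold))
  invisible(x)
}

#' @export
plot.boot_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, type = "unrooted", ...)
  ape::nodelabels(x$tree$node.label, frame = "none", cex = 0.8)
  invisible(x)
}
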