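test_that("CDS translation follows the standard code and stop-codon contract", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(nchar(translate_cds(paste0(strrep("ATG", 793), "TAA"))), 793)
  expect_equal(translate_cds("atggugcat"), "MVH")   # case and U tolerated
  expect_error(translate_cds("ATGA"), "divisible")
  expect_error(translate_cds("ATGXAATAA"), "invalid")
  expect_error(translate_cds("ATGTAAAAATAA"), "internal stop")
  expect_equal(translate_cds("ATGTAAAAATAA", strict = FALSE), "M")
})

test_that("pairwise identity behaves on exact and near-exact pairs", {
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQR"), 100)
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQW"), 90)
  # one terminal gap: identity over alignment columns
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQ"), 90)
  expect_error(pairwise_identity("", "MK"), "empty")
})

test_that("protein distances match their closed forms", {
  a <- strrep("A", 10)
  b <- paste0("C", strrep("A", 9))          # p = 0.1
  aln <- c(x = a, y = b)
  expect_equal(protein_distance(aln, "p")["x", "y"], 0.1)
  expect_equal(protein_distance(aln, "poisson")["x", "y"], -log(0.9))
  expect_equal(round(protein_distance(aln, "poisson")["x", "y"], 5), 0.10536)
  expect_equal(protein_distance(aln, "kimura")["x", "y"],
               -log(1 - 0.1 - 0.2 * 0.01))
  same <- c(x = a, y = a, z = a)
  for (m in c("p", "poisson", "kimura"))
    expect_true(all(protein_distance(same, m) == 0))
})

test_that("distances use pairwise gap deletion and cap saturated pairs", {
  aln <- c(x = "AAAA--", y = "AA--CC", z = "AACCCC")
  d <- protein_distance(aln, "p")
  expect_equal(d["x", "y"], 0)        # only first two columns comparable
  expect_equal(d["x", "z"], 0.5)      # 4 comparable, 2 mismatches
  expect_error(protein_distance(c(x = "AA--", y = "--CC")), "gap-free")
  sat <- c(x = strrep("A", 10), y = strrep("C", 10))  # p = 1: saturated
  expect_warning(ds <- protein_distance(sat, "poisson"), "capped")
  expect_equal(ds["x", "y"], 10)
})

test_that("corrected distances converge to p as divergence vanishes", {
  n <- 1e4
  aln <- c(x = strrep("A", n), y = paste0("C", strrep("A", n - 1)))  # p = 1e-4
  p <- protein_distance(aln, "p")["x", "y"]
  expect_lt(abs(protein_distance(aln, "poisson")["x", "y"] - p), 1e-6)
  expect_lt(abs(protein_distance(aln, "kimura")["x", "y"] - p), 1e-6)
})

test_that("three-taxon neighbor joining solves the closed-form star", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("neighbor joining is exact on additive matrices (direct-construction oracle)", {
  withr::with_seed(42, {
    for (i in 1:8) {
      gen <- random_additive_matrix(sample(4:8, 1))
      tr <- neighbor_joining(gen$d)
      expect_equal(ape::dist.topo(ape::unroot(gen$tree), tr), 0,
                   ignore_attr = TRUE)
      back <- ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)]
      expect_lt(max(abs(back - gen$d)), 1e-9)
      # independent cross-check against ape's NJ topology
      expect_equal(ape::dist.topo(ape::nj(gen$d), tr), 0, ignore_attr = TRUE)
    }
  })
})

test_that("four- and five-taxon NJ beats brute force over all topologies", {
  withr::with_seed(7, {
    for (n in c(4, 5)) {
      gen <- random_additive_matrix(n)
      tr <- neighbor_joining(gen$d)
      topos <- phangorn::allTrees(n, rooted = FALSE,
                                  tip.label = rownames(gen$d))
      rss <- vapply(topos, function(tp) ls_fit_topology(tp, gen$d)$rss,
                    numeric(1))
      best <- topos[[which.min(rss)]]
      expect_lt(min(rss), 1e-12)
      expect_equal(ape::dist.topo(best, tr), 0, ignore_attr = TRUE)
    }
  })
})

test_that("NJ output is invariant to taxon input order", {
  withr::with_seed(9, {
    gen <- random_additive_matrix(6)
    perm <- sample(6)
    tr1 <- neighbor_joining(gen$d)
    tr2 <- neighbor_joining(gen$d[perm, perm])
    expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(tr2)[rownames(gen$d), rownames(gen$d)] -
                        ape::cophenetic.phylo(tr1)[rownames(gen$d), rownames(gen$d)])),
              1e-9)
  })
})

test_that("degenerate equal-distance matrices still give a valid tree", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), letters[1:4])
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and bounded", {
  fam <- simulate_protein_family(two_clade_newick, 120, 1, seed = 5)
  b1 <- bootstrap_support(fam$alignment, n_reps = 25, seed = 7)
  b2 <- bootstrap_support(fam$alignment, n_reps = 25, seed = 7)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 25))
  single <- bootstrap_support(fam$alignment, n_reps = 1, seed = 1)
  expect_true(all(single$supports %in% c(0, 1)))
  short <- fam$alignment[, 1:5]
  w <- capture_warnings(bootstrap_support(short, n_reps = 2, seed = 1))
  expect_true(any(grepl("10 columns", w)))
})

test_that("a star (zero-signal) family draws no confident internal branches", {
  star_newick <- paste0("(", paste0("t", 1:8, ":0.15", collapse = ","), ");")
  fam <- simulate_protein_family(star_newick, 200, rate = 1, seed = 3)
  bs <- bootstrap_support(fam$alignment, n_reps = 100, seed = 2)
  internal <- bs$supports[-1]   # drop the trivial root bipartition
  expect_lt(max(internal), 85)
  expect_lt(mean(internal), 60)
})

test_that("KEN-box scanning reports 1-based spans", {
  expect_equal(scan_ken_box("AAKENAA"),
               data.frame(start = 3L, end = 5L))
  expect_equal(nrow(scan_ken_box("AAAA")), 0)
  hits <- scan_ken_box("KENXXKEN")
  expect_equal(hits$start, c(1L, 6L))
  # an extended consensus can be supplied as a pattern
  expect_equal(nrow(scan_ken_box("AKENDAAKENP", pattern = "KEN[^P]")), 1)
})
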