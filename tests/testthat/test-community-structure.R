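test_that("Bray-Curtis similarity matches the direct formula and vegan", {
  m <- rbind(a = c(1, 3), b = c(3, 1), c = c(1, 3))
  bc <- bray_curtis_matrix(m)
  expect_equal(bc$values["a", "b"], 50)
  expect_equal(bc$values["a", "c"], 100)
  expect_equal(unname(diag(bc$values)), rep(100, 3))

  disj <- rbind(x = c(1, 0), y = c(0, 2))
  expect_equal(bray_curtis_matrix(disj)$values["x", "y"], 0)

  expect_error(bray_curtis_matrix(m[1, , drop = FALSE]), "2 samples")
  expect_warning(bray_curtis_matrix(rbind(a = c(0, 0), b = c(0, 0),
                                          c = c(1, 1))),
                 "all-zero")

  set.seed(31)
  r <- matrix(rexp(8 * 20), 8)
  rownames(r) <- paste0("s", 1:8)
  got <- bray_curtis_matrix(r)$values
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(got[i, j], oracle_bray(r[i, ], r[j, ]))

  skip_if_not_installed("vegan")
  vd <- as.matrix(vegan::vegdist(r, "bray"))
  expect_equal(unname(got), unname(100 * (1 - vd)), tolerance = 1e-12)
})

test_that("Bray-Curtis is bounded, symmetric and scale-invariant per pair", {
  set.seed(32)
  m <- matrix(runif(5 * 12), 5)
  bc <- bray_curtis_matrix(m)$values
  expect_true(all(bc >= 0 & bc <= 100))
  expect_equal(bc, t(bc))
  # jointly rescaling a pair leaves their similarity unchanged
  bc2 <- bray_curtis_matrix(m * 7.3)$values
  expect_equal(bc, bc2)
})

test_that("environmental distances use n-1 normalization", {
  md <- data.frame(sample_id = c("p", "q"), v = c(0, 2))
  d <- env_distance_matrix(md, "v")
  expect_equal(d$values["p", "q"], sqrt(2))  # values +-1/sqrt(2)*2

  md3 <- data.frame(sample_id = c("p", "q", "r"),
                    a = c(1, 2, 3), b = c(10, 20, 30))
  d0 <- env_distance_matrix(md3, c("a", "b"))
  # translation invariance
  md3b <- md3
  md3b$a <- md3$a + 100
  expect_equal(env_distance_matrix(md3b, c("a", "b"))$values, d0$values)
  # identical samples at distance zero
  md2 <- data.frame(sample_id = c("u", "v", "w"),
                    a = c(1, 1, 5), b = c(2, 2, 9))
  expect_equal(env_distance_matrix(md2, c("a", "b"))$values["u", "v"], 0)

  mdz <- data.frame(sample_id = c("p", "q"), a = c(1, 1), b = c(0, 2))
  expect_warning(dz <- env_distance_matrix(mdz, c("a", "b")),
                 "zero-variance")
  expect_equal(dz$values["p", "q"], sqrt(2))

  expect_error(env_distance_matrix(md3, "missing_var"), "not in metadata")
})

test_that("UPGMA reproduces the hand-worked group-average merge", {
  d <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma(new_resemblance(d, "distance", "test"))
  expect_equal(h$height, c(2, 7))  # A,B at 2; {A,B} vs C at (8+6)/2

  # two samples at distance d: single merge at d
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(new_resemblance(d2, "distance", "t"))$height, 3)

  # equidistant points merge at the common distance regardless of order
  d3 <- matrix(4, 4, 4); diag(d3) <- 0
  expect_equal(upgma(new_resemblance(d3, "distance", "t"))$height,
               rep(4, 3))
})

test_that("UPGMA matches the exhaustive oracle and hclust", {
  set.seed(33)
  for (k in 1:40) {
    n <- sample(3:5, 1)
    d <- random_dist(n, max = 10)
    h <- upgma(new_resemblance(d, "distance", "t"))
    coph <- as.matrix(stats::cophenetic(h))
    want <- oracle_agglomerate(d, "average")$cophenetic
    expect_equal(unname(coph[h$labels, h$labels]), unname(want),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # against stats::hclust on a larger tie-free matrix
  set.seed(34)
  d <- random_dist(9, max = 5)
  rownames(d) <- colnames(d) <- paste0("s", 1:9)
  h1 <- upgma(new_resemblance(d, "distance", "t"))
  h2 <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  expect_equal(as.matrix(stats::cophenetic(h1))[h2$labels, h2$labels],
               as.matrix(stats::cophenetic(h2)), tolerance = 1e-12)
})

test_that("similarity matrices cluster via their 100 - S distances", {
  m <- rbind(a = c(1, 0, 0), b = c(0.9, 0.1, 0), c = c(0, 0, 1))
  bc <- bray_curtis_matrix(m)
  h <- upgma(bc)
  # a and b are the most similar pair and must merge first
  first <- sort(h$merge[1, ])
  expect_equal(first, sort(-match(c("a", "b"), h$labels)))
})

test_that("RELATE rank correlation behaves as a Mantel-type test", {
  set.seed(35)
  r <- matrix(runif(6 * 10), 6)
  rownames(r) <- paste0("s", 1:6)
  bc <- bray_curtis_matrix(r)
  self <- relate(bc, bc, n_perm = 99, seed = 1)
  expect_equal(self$rho, 1)
  expect_gte(self$p, 1 / 100)

  # rank reversal of the triangle entries gives rho = -1
  rev <- bc
  rev$values <- 100 - bc$values
  diag(rev$values) <- 100
  expect_equal(relate(bc, rev, n_perm = 19, seed = 1)$rho, -1)

  # invariance under monotone transforms (rank-based statistic)
  tr <- bc
  tr$values <- bc$values^3 / 1e4
  expect_equal(relate(bc, tr, n_perm = 19, seed = 1)$rho, 1)

  b2 <- bc
  rownames(b2$values) <- colnames(b2$values) <- paste0("t", 1:6)
  expect_error(relate(bc, b2), "same samples")
  expect_error(relate(bc, bc, n_perm = 0), "n_perm")
})

test_that("RELATE agrees with vegan::mantel on the statistic", {
  skip_if_not_installed("vegan")
  set.seed(36)
  r <- matrix(rexp(10 * 15), 10)
  rownames(r) <- paste0("s", 1:10)
  md <- data.frame(sample_id = rownames(r), a = rnorm(10), b = rnorm(10))
  bc <- bray_curtis_matrix(r)
  ed <- env_distance_matrix(md, c("a", "b"))
  bc_dist <- new_resemblance(100 - bc$values, "distance", "bray")
  ours <- relate(bc_dist, ed, n_perm = 99, seed = 2)
  vg <- vegan::mantel(stats::as.dist(bc_dist$values),
                      stats::as.dist(ed$values),
                      method = "spearman", permutations = 99)
  expect_equal(ours$rho, vg$statistic, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("newick export round-trips through ape", {
  d <- random_dist(5, 3)
  rownames(d) <- colnames(d) <- paste0("s", 1:5)
  h <- upgma(new_resemblance(d, "distance", "t"))
  f <- tempfile(fileext = ".nwk")
  write_newick(h, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, paste0("s", 1:5))
})
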