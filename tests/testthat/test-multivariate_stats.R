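test_that("Bray-Curtis matches hand arithmetic and flags undefined pairs", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 1, 3), c = c(1, 2, 3))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 2 / 12, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disj <- rbind(c(1, 0), c(0, 1))
  expect_equal(bray_curtis(disj)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("Euclidean distance with z-scoring is unit-invariant", {
  m <- rbind(c(0, 0), c(3, 4), c(1, 1))
  expect_equal(euclidean_dist(m, standardize = FALSE)[1, 2], 5)
  m2 <- m
  m2[, 2] <- m2[, 2] * 1000
  expect_equal(euclidean_dist(m, standardize = TRUE),
               euclidean_dist(m2, standardize = TRUE), tolerance = 1e-9)
})

test_that("exact-enumeration p equals the brute-force oracle on n <= 8", {
  set.seed(61)
  designs <- list(c(3, 3), c(2, 3), c(2, 2, 2), c(2, 3, 3), c(4, 4))
  for (sizes in designs) {
    n <- sum(sizes)
    groups <- rep(letters[seq_along(sizes)], sizes)
    x <- matrix(rnorm(n * 3), nrow = n)
    d <- euclidean_dist(x, standardize = FALSE)
    r <- permanova(d, groups)
    o <- oracle_permanova_p(d, groups)
    expect_identical(r$method, "exact")
    expect_identical(r$n_permutations_used, o$n_distinct)
    expect_equal(r$p_perm, o$p, tolerance = 1e-12)
  }
})

test_that("the documented 3-vs-3 separation has exact p = 1/10", {
  x <- matrix(c(1, 2, 3, 11, 12, 13), ncol = 1)
  d <- euclidean_dist(x, standardize = FALSE)
  r <- permanova(d, c("a", "a", "a", "b", "b", "b"))
  expect_identical(r$method, "exact")
  expect_identical(r$n_permutations_used, 10L)
  expect_equal(r$p_perm, 0.1, tolerance = 1e-12)
})

test_that("pseudo-F agrees with an independent implementation", {
  set.seed(62)
  m <- matrix(abs(rnorm(21 * 8)) + 0.1, nrow = 21)
  g <- rep(letters[1:7], each = 3)
  d <- bray_curtis(m)
  r <- permanova(d, g, n_perm = 99, seed = 1)
  va <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(r$pseudo_F, va$F[1], tolerance = 1e-9)
})

test_that("degenerate inputs are flagged, not mis-tested", {
  d <- as_dist_matrix(matrix(0, 4, 4))
  r <- permanova(d, c("a", "a", "b", "b"))
  expect_true(r$degenerate)
  expect_true(is.na(r$pseudo_F))
  expect_error(permanova(d, c("a", "a", "a", "a")), "2 groups")
})

test_that("pairwise comparisons match one-way runs and add Monte-Carlo p", {
  set.seed(63)
  m <- matrix(abs(rnorm(9 * 5)) + 0.1, nrow = 9)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- bray_curtis(m)
  pw <- pairwise_permanova(d, g, seed = 2)
  expect_identical(nrow(pw), 3L)
  # a 3-vs-3 pair has 10 distinct relabelings, forcing the MC branch
  expect_true(all(pw$n_distinct == 10))
  expect_true(all(!is.na(pw$p_montecarlo)))
  # internal consistency with one-way permanova on the sub-matrix
  ix <- which(g %in% c("a", "b"))
  r_ab <- permanova(d[ix, ix], g[ix])
  expect_equal(pw$pseudo_t[pw$group1 == "a" & pw$group2 == "b"],
               sqrt(r_ab$pseudo_F), tolerance = 1e-12)
  expect_equal(pw$p_perm[1], r_ab$p_perm, tolerance = 1e-12)
  # identical groups give pseudo-t ~ 0 and p ~ 1
  m2 <- rbind(m[1:3, ], m[1:3, ]) + 0
  d2 <- euclidean_dist(rbind(m[1:3, ], m[1:3, ]), standardize = FALSE)
  pw2 <- pairwise_permanova(d2, rep(c("a", "b"), each = 3), seed = 3)
  expect_lt(pw2$pseudo_t, 1e-6)
  expect_gt(pw2$p_perm, 0.9)
})

test_that("PCoA recovers known configurations and variance fractions", {
  set.seed(64)
  pts <- matrix(rnorm(24), ncol = 2)
  d <- euclidean_dist(pts, standardize = FALSE)
  pc <- pcoa(d)
  pr <- vegan::procrustes(pts, pc$points[, 1:2])
  expect_lt(sqrt(mean(residuals(pr)^2)), 1e-8)
  # variance fractions equal classical PCA's
  pca <- prcomp(pts)
  expect_equal(pc$percent_variance / 100,
               pca$sdev^2 / sum(pca$sdev^2), tolerance = 1e-9)
  # collinear points: one axis explains everything
  line <- cbind(1:6, 2 * (1:6))
  pl <- pcoa(euclidean_dist(line, standardize = FALSE))
  expect_equal(pl$percent_variance[1], 100, tolerance = 1e-9)
  # three equidistant points split 50/50
  tri <- as_dist_matrix(matrix(1, 3, 3) - diag(3))
  pt <- pcoa(tri)
  expect_equal(pt$percent_variance[1:2], c(50, 50), tolerance = 1e-9)
  # sign convention is deterministic
  expect_equal(pcoa(d)$points, pc$points, tolerance = 0)
})

test_that("NMDS reaches near-zero stress on embeddable data", {
  set.seed(65)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- euclidean_dist(pts, standardize = FALSE)
  nm <- nmds(d, k = 2, n_restarts = 4, seed = 9)
  expect_lt(nm$stress, 0.01)
  # stress sequence is monotone non-increasing
  expect_true(all(diff(nm$stress_sequence) <= 1e-12))
  # configuration distances preserve the input rank order
  dc <- as.matrix(dist(nm$points))[upper.tri(d)]
  expect_gt(cor(dc, d[upper.tri(d)], method = "spearman"), 0.99)
})

test_that("correlation screen reproduces Pearson r and handles NA columns", {
  md <- sample_metadata(paste0("s", 1:5), rep("T", 5), 1:5)
  sp <- soil_properties(md$sample_id, y = c(2, 1, 4, 3, 6),
                        z = c(1, 1, 1, 1, 1),
                        w = c(2, 1, 4, NA, 6))
  gt <- matrix(1:5, nrow = 1, dimnames = list("g1", md$sample_id))
  scr <- correlation_screen(sp, gt)
  ry <- scr[scr$property == "y", ]
  expect_equal(ry$r, 0.8219949, tolerance = 1e-6)
  expect_equal(ry$p, cor.test(1:5, c(2, 1, 4, 3, 6))$p.value,
               tolerance = 1e-12)
  # zero variance flagged undefined; NA excluded pairwise
  expect_identical(scr$status[scr$property == "z"], "undefined")
  expect_identical(scr$n[scr$property == "w"], 4L)
  # x vs x and x vs -x
  sp2 <- soil_properties(md$sample_id, same = 1:5, neg = -(1:5))
  scr2 <- correlation_screen(sp2, gt)
  expect_equal(scr2$r[scr2$property == "same"], 1, tolerance = 1e-12)
  expect_equal(scr2$r[scr2$property == "neg"], -1, tolerance = 1e-12)
})
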