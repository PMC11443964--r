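test_that("pairwise correlations flag zero-variance channels as undefined", {
  ray <- toy_plane_population(cbind(A = c(1, 2, 3, 4), leak = c(2, 4, 6, 8)))
  r <- pairwise_correlations(ray)
  expect_equal(r["A", "leak"], 1)

  const <- toy_plane_population(cbind(A = c(1, 2, 3), leak = c(5, 5, 5)))
  r <- pairwise_correlations(const)
  expect_true(is.na(r["A", "leak"]))
  expect_true(is.na(r["leak", "leak"]))
  expect_equal(r["A", "A"], 1)
})

test_that("correlation graphs apply the 1/N threshold and drop undefined edges", {
  pop <- get_dic_pop("STG")
  gr <- correlation_graph(pop)
  expect_equal(igraph::graph_attr(gr, "threshold"), 1 / 8)
  expect_equal(igraph::vcount(gr), 8)
  r <- pairwise_correlations(pop)
  manual <- sum(abs(r[upper.tri(r)]) >= 1 / 8, na.rm = TRUE)
  expect_equal(igraph::ecount(gr), manual)
  # DIC-generated sets share the random-sampling trait: mostly positive edges
  er <- igraph::E(gr)$r
  expect_gt(mean(er > 0), 0.5)

  expect_equal(igraph::ecount(correlation_graph(pop, threshold = 1.1)), 0)

  ident <- toy_plane_population(cbind(A = rep(2, 5), leak = rep(3, 5)))
  expect_equal(igraph::ecount(correlation_graph(ident)), 0)
})

test_that("PCA matches a brute-force eigendecomposition and its invariants", {
  set.seed(8)
  x <- cbind(A = runif(5, 1, 4), leak = runif(5, 0.1, 0.5))
  pop <- toy_plane_population(x)
  p <- pca_population(pop)
  ev <- eigen(stats::cov(x))
  expect_equal(p$variance_fraction, ev$values / sum(ev$values),
               tolerance = 1e-12)
  for (k in 1:2)
    expect_equal(abs(p$loadings[, k]), abs(ev$vectors[, k]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: dominant entry positive
  expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))

  # exactly collinear points concentrate all variance on PC1
  line <- toy_plane_population(cbind(A = 1:5, leak = 2 * (1:5)))
  expect_equal(pca_population(line)$variance_fraction, c(1, 0),
               tolerance = 1e-12)

  # more conductances than members is an error
  small <- get_dic_pop("STG")[1:4, ]
  small_pop <- condegen:::new_population(get_model("STG"), small, list())
  expect_error(pca_population(small_pop), "more members")
})

test_that("the homogeneous-scaling direction is the origin-to-mean unit vector", {
  pop <- toy_plane_population(cbind(A = c(1, 3), leak = c(1, 3)))
  expect_equal(unname(unclass(homogeneous_scaling_direction(pop))),
               c(1, 1) / sqrt(2), tolerance = 1e-12, ignore_attr = TRUE)

  # equals the dominant right-singular direction of the uncentered data
  set.seed(2)
  base <- c(2, 0.5)
  x <- outer(runif(12, 0.5, 2), base)          # ray with multiplicative noise
  colnames(x) <- c("A", "leak")
  pop <- toy_plane_population(x)
  hs <- homogeneous_scaling_direction(pop)
  v <- svd(x)$v[, 1]
  expect_gt(alignment(hs, v), 1 - 1e-10)

  zero <- toy_plane_population(cbind(A = 0, leak = 0)[c(1, 1), ])
  expect_error(homogeneous_scaling_direction(zero), "origin")
})

test_that("alignment is a sign-invariant cosine", {
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  expect_equal(alignment(u, u), 1)
  expect_equal(alignment(u, v), 0)
  w <- c(1, 1, 0)
  expect_equal(alignment(u, w), cos(pi / 4), tolerance = 1e-12)
  expect_equal(alignment(u, w), alignment(w, u))
  expect_equal(alignment(-u, w), alignment(u, w))
  expect_error(alignment(u, c(1, 2)), "dimension mismatch")
})

test_that("Rin normalization divides a passive population by its leak exactly", {
  x <- cbind(A = c(0, 0, 0), leak = c(0.005, 0.01, 0.02))
  pop <- toy_plane_population(x)
  np <- normalize_by_rin(pop, V_ref = -70, model = toy_plane_model())
  expect_equal(unclass(np), x / x[, "leak"], ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("Rin normalization collapses STG scaling-only subsets", {
  np <- normalize_by_rin(get_scaling_pop("STG"))
  x <- unclass(np)
  spread <- apply(x, 2, function(cc) diff(range(cc)) / (abs(mean(cc)) + 1e-300))
  expect_lt(max(spread), 1e-3)
})

test_that("total-least-squares directions minimize orthogonal distances", {
  pop <- toy_plane_population(cbind(A = c(1, 2, 3), leak = c(2, 4, 6)))
  d <- tls_regression(pop, c("A", "leak"), through_origin = TRUE)
  expect_equal(unname(unclass(d)), c(1, 2) / sqrt(5), tolerance = 1e-12,
               ignore_attr = TRUE)

  # grid-search oracle over the direction angle on a noisy 6-point cloud
  set.seed(5)
  x <- cbind(A = 1:6 + rnorm(6, 0, 0.3), leak = 0.7 * (1:6) + rnorm(6, 0, 0.3))
  pop <- toy_plane_population(x)
  d <- tls_regression(pop, c("A", "leak"))
  xc <- scale(x, center = TRUE, scale = FALSE)
  loss <- function(th) {
    v <- c(cos(th), sin(th))
    sum((xc %*% c(-v[2], v[1]))^2)      # squared orthogonal residuals
  }
  ths <- seq(0, pi, length.out = 20001)
  best <- ths[which.min(vapply(ths, loss, numeric(1)))]
  expect_gt(alignment(d, c(cos(best), sin(best))), 1 - 1e-6)

  expect_error(tls_regression(toy_plane_population(
    cbind(A = rep(0, 4), leak = rep(0, 4))), c("A", "leak")), "degenerate")
})

test_that("ratio-only regressions do not pass through the origin", {
  pop <- get_ratio_pop("STG")
  x <- unclass(pop)
  fit <- stats::lm(x[, "CaS"] ~ x[, "A"])
  ct <- summary(fit)$coefficients
  expect_lt(ct["(Intercept)", "Pr(>|t|)"], 0.01)
  expect_gt(abs(ct["(Intercept)", "Estimate"]), 0)
})
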