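crab <- crab_example()

test_that("symmetrized-KL dissimilarities are metric-like and match hand arithmetic", {
  tb <- entropy_table(matrix(c(-1, -3, -5, -1), 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  # KL(1,2) = -1 - (-3) = 2, KL(2,1) = -1 - (-5) = 4 -> D = sqrt(3)
  dv <- symmetrized_kl_matrix(tb)
  expect_equal(dv$D["a", "b"], sqrt(3), tolerance = 1e-12)
  expect_equal(symmetrized_kl_matrix(tb, kl_factor = 2)$D["a", "b"], sqrt(6),
               tolerance = 1e-12)
  # identical models embed at zero distance
  tb2 <- entropy_table(matrix(c(-1, -1, -1, -1), 2))
  expect_equal(symmetrized_kl_matrix(tb2)$D[1, 2], 0)
  # the published crab matrix produces a clean dissimilarity matrix
  D <- symmetrized_kl_matrix(crab$sfifj)$D
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 9))
  expect_true(all(is.finite(D)) && all(D >= 0))
})

test_that("exactly embeddable configurations are recovered with near-zero stress", {
  set.seed(3)
  P <- matrix(stats::rnorm(10), 5, 2)
  D <- as.matrix(stats::dist(P))
  for (mode in c("ordinal", "interval")) {
    e <- nmds(D, 2, mode)
    expect_lt(e$stress, 1e-6)
    expect_equal(as.vector(stats::dist(e$coords)), as.vector(stats::dist(P)),
                 tolerance = 1e-4)
  }
})

test_that("stress decreases monotonically and ordinal fits are at least as good as interval", {
  D <- symmetrized_kl_matrix(crab$sfifj)
  eo <- nmds(D, 2, "ordinal")
  ei <- nmds(D, 2, "interval")
  expect_lte(eo$stress, ei$stress + 1e-9)
  expect_true(all(diff(eo$stress_trace[-1]) <= 1e-8))
  # interval disparities are re-normalized against a moving distance total,
  # so per-iteration monotonicity holds only approximately
  expect_true(all(diff(ei$stress_trace[-1]) <= 1e-3))
  # independent cross-check of the near-perfect ordinal embedding
  skip_if_not_installed("vegan")
  mono <- vegan::monoMDS(stats::as.dist(D$D), k = 2)
  expect_lt(abs(eo$stress - mono$stress), 0.01)
})

test_that("AIC differences and Akaike weights match worked examples", {
  expect_equal(delta_aic(c(10, 12, 15)), c(0, 2, 5))
  expect_equal(delta_aic(c(10, 12, 15) + 7), c(0, 2, 5))
  expect_equal(akaike_weights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(akaike_weights(c(0, 2)), c(1 / (1 + exp(-1)), 1 - 1 / (1 + exp(-1))),
               tolerance = 1e-6)
  # published nine-model AICs: hurdle negative binomial takes all the weight
  w <- akaike_weights(crab$aics)
  expect_gt(w[["HurdNBi"]], 0.9999)
  d <- delta_aic(crab$aics)
  expect_equal(d[["Poisson"]], 5421.11814, tolerance = 1e-3)
  expect_equal(d[["ZINegBi"]], 43.15146, tolerance = 1e-3)
})

test_that("implicit Akaike priors favor rich models only above n = e^2", {
  expect_equal(akaike_prior(0, 10), 1)
  expect_equal(akaike_prior(2, 8) / akaike_prior(1, 8),
               exp(0.5 * log(8) - 1), tolerance = 1e-12)
  expect_gt(akaike_prior(2, 8), akaike_prior(1, 8))
  expect_lt(akaike_prior(2, 7), akaike_prior(1, 7))
})

test_that("the model average is a convex combination inside the hull", {
  set.seed(5)
  co <- matrix(stats::rnorm(12), 6, 2)
  expect_equal(model_average_location(co, rep(1 / 6, 6)), colMeans(co))
  w1 <- c(1, rep(0, 5))
  expect_equal(model_average_location(co, w1), co[1, ])
  for (i in 1:20) {
    w <- rand_pi(6)
    expect_true(in_convex_hull(model_average_location(co, w), co))
  }
  expect_error(model_average_location(co, rep(1, 6)), "sum to 1")
})
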