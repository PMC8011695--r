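test_that("reduced-parameter multinomial probabilities match direct pmf evaluation", {
  p <- reduce_to_multinomial("Poisson", 1, k = 3)
  expect_equal(p, c(exp(-1), exp(-1), 1 - 2 * exp(-1)), tolerance = 1e-12)
  # near-degenerate rate puts all mass in the zero category
  p0 <- reduce_to_multinomial("Poisson", 1e-10, k = 3)
  expect_equal(p0, c(1, 0, 0), tolerance = 1e-9)
  # full one-inflation concentrates on category "1"
  p1 <- reduce_to_multinomial("OIPoiss", c(1, 5), k = 3)
  expect_equal(p1, c(0, 1, 0), tolerance = 1e-12)
  expect_error(reduce_to_multinomial("Poisson", -1, 3), "invalid")
  expect_error(reduce_to_multinomial("ZIPoiss", c(1.5, 1), 3), "invalid")
  expect_error(reduce_to_multinomial("NoSuch", 1, 3), "unknown model family")
})

test_that("every family's pmf is a probability distribution and reduces cleanly", {
  thetas <- list(
    Poisson = 2.3, NegBin = c(1.7, 3.2), ZIPoiss = c(0.3, 2.5),
    ZINegBi = c(0.2, 1.5, 3), HurdNBi = c(0.4, 2, 2.5),
    PoisNB = c(0.4, 1, 2, 5), NBPois = c(0.6, 2, 5, 1),
    OIPoiss = c(0.25, 3), OINegBi = c(0.15, 1.2, 2.8)
  )
  for (fam in model_families()) {
    th <- thetas[[fam]]
    f <- get_family(fam)
    expect_equal(f$n_params, length(th), info = fam)
    # truncated mass reaches 1 to 1e-8
    expect_equal(sum(f$pmf(0:500, th)), 1, tolerance = 1e-8, info = fam)
    for (k in c(2, 4, 6)) {
      pi <- reduce_to_multinomial(fam, th, k)
      expect_true(all(pi >= 0), info = fam)
      expect_equal(sum(pi), 1, tolerance = 1e-10, info = fam)
    }
  }
})

test_that("multinomial log-likelihood matches closed-form small cases", {
  expect_identical(multinomial_loglik(c(1, 0), c(1, 0)), 0)
  expect_equal(multinomial_loglik(c(1, 1), c(0.5, 0.5)), log(2 * 0.25),
               tolerance = 1e-12)
  expect_equal(multinomial_loglik(c(2, 0), c(0.5, 0.5)), log(0.25),
               tolerance = 1e-12)
  expect_identical(multinomial_loglik(c(1, 1), c(1, 0)), -Inf)
})

test_that("Poisson fit to a single tide matches a dense grid search", {
  d <- count_dataset(rbind(c(112, 96, 101, 48, 22, 16)))
  fit <- fit_model(d, "Poisson")
  grid <- seq(1e-3, 10, by = 1e-4)
  ll <- vapply(grid, function(l)
    multinomial_loglik(d$counts[1, ], reduce_to_multinomial("Poisson", l, 6)),
    numeric(1))
  expect_equal(unname(fit$theta_hat), grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(fit$aic, -2 * fit$loglik + 2, tolerance = 1e-12)
  expect_equal(aic(fit), fit$aic)
})

test_that("an all-zero-category tide drives the Poisson rate to the boundary", {
  d <- count_dataset(rbind(c(10, 0)))
  fit <- fit_model(d, "Poisson")
  expect_equal(unname(fit$pi_hat), c(1, 0), tolerance = 1e-4)
})

test_that("pooled fits are local optima of the multinomial likelihood", {
  sim <- simulate_tides(n_tides = 15, pairs_per_tide = 150, seed = 21)
  for (fam in c("Poisson", "NegBin", "ZIPoiss")) {
    fit <- fit_model(sim$data, fam)
    k <- ncol(sim$data$counts)
    base <- fit$loglik
    set.seed(99)
    for (i in 1:25) {
      th <- fit$theta_hat * exp(stats::rnorm(length(fit$theta_hat), sd = 0.2))
      if (fam == "ZIPoiss") th[1] <- min(max(th[1], 0), 1)
      ll <- tryCatch({
        pi <- reduce_to_multinomial(fam, th, k)
        sum(apply(sim$data$counts, 1, multinomial_loglik, pi = pi))
      }, error = function(e) -Inf)
      expect_lte(ll, base + 1e-6)
    }
  }
})

test_that("overdispersed data rank the negative binomial above the Poisson", {
  # generating distribution: NegBin(size 1.5, mu 2.5) reduced to 6 categories
  pi_nb <- reduce_to_multinomial("NegBin", c(1.5, 2.5), 6)
  sim <- simulate_tides(true_pi = pi_nb, n_tides = 200, pairs_per_tide = 100,
                        seed = 8)
  f_nb <- fit_model(sim$data, "NegBin")
  f_po <- fit_model(sim$data, "Poisson")
  expect_lt(f_nb$aic, f_po$aic)
})

test_that("inflated and hurdle families nest their base distributions", {
  k <- 6
  pois <- reduce_to_multinomial("Poisson", 2.2, k)
  expect_equal(reduce_to_multinomial("ZIPoiss", c(0, 2.2), k), pois,
               tolerance = 1e-12)
  expect_equal(reduce_to_multinomial("OIPoiss", c(0, 2.2), k), pois,
               tolerance = 1e-12)
  nb <- reduce_to_multinomial("NegBin", c(1.3, 2.8), k)
  p0 <- stats::dnbinom(0, size = 1.3, mu = 2.8)
  expect_equal(reduce_to_multinomial("HurdNBi", c(p0, 1.3, 2.8), k), nb,
               tolerance = 1e-8)
  expect_equal(reduce_to_multinomial("ZINegBi", c(0, 1.3, 2.8), k), nb,
               tolerance = 1e-12)
})

test_that("pooled fitting recovers the Poisson rate from large simulated data", {
  lambda <- 2
  pi_true <- reduce_to_multinomial("Poisson", lambda, 8)
  sim <- simulate_tides(true_pi = pi_true, n_tides = 500,
                        pairs_per_tide = 400, seed = 31)
  fit <- fit_model(sim$data, "Poisson")
  lam_hat <- unname(fit$theta_hat)
  # curvature-based standard error at the optimum
  eps <- 1e-4
  ll <- function(l) sum(apply(sim$data$counts, 1, multinomial_loglik,
                              pi = reduce_to_multinomial("Poisson", l, 8)))
  d2 <- (ll(lam_hat + eps) - 2 * ll(lam_hat) + ll(lam_hat - eps)) / eps^2
  se <- 1 / sqrt(-d2)
  expect_lt(abs(lam_hat - lambda), 3 * se)
})

test_that("per-replicate mode fits each tide separately and sums the pieces", {
  sim <- simulate_tides(n_tides = 4, pairs_per_tide = 80, seed = 5)
  fit <- fit_model(sim$data, "Poisson", mode = "per_replicate")
  expect_true(is.matrix(fit$theta_hat))
  expect_equal(nrow(fit$theta_hat), 4)
  expect_equal(fit$n_params, 4)
  single <- fit_model(count_dataset(sim$data$counts[2, , drop = FALSE]),
                      "Poisson")
  expect_equal(unname(fit$theta_hat[2, ]), unname(single$theta_hat),
               tolerance = 1e-6)
})
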