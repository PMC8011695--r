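test_that("exact neg-crossentropy matches full enumeration of small multinomials", {
  expect_equal(neg_crossentropy_multinomial(c(0.5, 0.5), c(0.5, 0.5), 1),
               log(0.5), tolerance = 1e-12)
  expect_equal(neg_crossentropy_multinomial(c(0.5, 0.5), c(0.5, 0.5), 2),
               enum_neg_crossentropy(c(0.5, 0.5), c(0.5, 0.5), 2),
               tolerance = 1e-12)
  expect_equal(neg_crossentropy_multinomial(c(0.6, 0.4), c(0.5, 0.5), 2),
               enum_neg_crossentropy(c(0.6, 0.4), c(0.5, 0.5), 2),
               tolerance = 1e-10)
  # a k = 3 case with asymmetric cells
  pr <- c(0.2, 0.5, 0.3); ps <- c(0.4, 0.4, 0.2)
  for (n in c(1, 3, 5))
    expect_equal(neg_crossentropy_multinomial(pr, ps, n),
                 enum_neg_crossentropy(pr, ps, n), tolerance = 1e-10)
  expect_identical(neg_crossentropy_multinomial(c(0.5, 0.5), c(1, 0), 3), -Inf)
})

test_that("neg-selfentropy handles degenerate and uniform cases in closed form", {
  expect_equal(neg_selfentropy_multinomial(c(1, 0), 7), 0, tolerance = 1e-12)
  expect_equal(neg_selfentropy_multinomial(c(0.5, 0.5), 2),
               enum_neg_crossentropy(c(0.5, 0.5), c(0.5, 0.5), 2),
               tolerance = 1e-12)
  expect_equal(neg_selfentropy_multinomial(rep(0.25, 4), 1), log(0.25),
               tolerance = 1e-12)
})

test_that("KL equals the categorical closed form and obeys Gibbs' inequality", {
  expect_equal(kl_multinomial(c(0.6, 0.4), c(0.5, 0.5), 10),
               10 * (0.6 * log(1.2) + 0.4 * log(0.8)), tolerance = 1e-10)
  expect_equal(kl_multinomial(c(0.3, 0.7), c(0.3, 0.7), 5), 0,
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:300) {
    k <- sample(2:6, 1); n <- sample(1:50, 1)
    pr <- rand_pi(k); ps <- rand_pi(k)
    kl <- kl_multinomial(pr, ps, n)
    expect_equal(kl, n * sum(pr * log(pr / ps)), tolerance = 1e-8)
    expect_gte(kl, 0)  # Gibbs: H(r, r) >= H(r, s)
  }
})

test_that("empirical proportions reproduce the printed single-tide example", {
  d <- count_dataset(rbind(c(112, 96, 101, 48, 22, 16)))
  expect_equal(unname(empirical_pis(d)[1, ]),
               c(112, 96, 101, 48, 22, 16) / 395, tolerance = 1e-12)
  expect_equal(unname(empirical_pis(count_dataset(rbind(c(5, 5))))[1, ]),
               c(0.5, 0.5))
  pooled <- empirical_pis(count_dataset(rbind(c(1, 0), c(0, 1))), "pooled")
  expect_equal(unname(pooled), c(0.5, 0.5))
})

test_that("the AIC-based neg-crossentropy estimate is -AIC/(2n) exactly", {
  expect_identical(sgf_from_aic(0, 0, 5), 0)
  expect_equal(sgf_from_aic(-100, 2, 50), -2.04, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    ll <- -stats::rexp(1, 1 / 500); k <- sample(1:4, 1); n <- sample(10:5000, 1)
    a <- -2 * ll + 2 * k
    expect_identical(sgf_from_aic(ll, k, n), -a / (2 * n))
  }
})

test_that("the entropy table sums exact per-replicate terms and is additive", {
  sim <- simulate_tides(n_tides = 3, pairs_per_tide = 40, seed = 13)
  fits <- fit_model_set(sim$data, c("Poisson", "NegBin"))
  tab <- entropies_matcalc(sim$data, fits)
  # cell = sum over replicates of the exact pairwise neg-crossentropy
  pi_p <- fits$Poisson$pi_hat; pi_n <- fits$NegBin$pi_hat
  manual <- sum(vapply(sim$data$n_j, function(n)
    neg_crossentropy_multinomial(pi_p, pi_n, n), numeric(1)))
  expect_equal(tab$sfifj["Poisson", "NegBin"], manual, tolerance = 1e-10)
  # additivity: per-replicate tables sum to the ensemble table
  parts <- lapply(1:3, function(j) {
    dj <- count_dataset(sim$data$counts[j, , drop = FALSE])
    entropies_matcalc(dj, fits)
  })
  expect_equal(tab$sfifj, Reduce(`+`, lapply(parts, `[[`, "sfifj")),
               tolerance = 1e-10)
  expect_equal(tab$sgg, sum(vapply(parts, `[[`, numeric(1), "sgg")),
               tolerance = 1e-10)
})

test_that("identical fitted models produce identical rows and zero implied KL", {
  d <- count_dataset(rbind(c(3, 2), c(1, 4)))
  fits <- suppressWarnings(fit_model_set(d, c("Poisson", "ZIPoiss")))
  # force identical probability vectors
  fits$ZIPoiss$pi_hat <- fits$Poisson$pi_hat
  tab <- entropies_matcalc(d, fits)
  expect_equal(tab$sfifj[1, 2], tab$sfifj[1, 1], tolerance = 1e-10)
  # one replicate, two models, tiny counts: match the enumeration oracle
  d1 <- count_dataset(rbind(c(1, 1)))
  f2 <- suppressWarnings(fit_model_set(d1, c("Poisson", "NegBin")))
  t1 <- entropies_matcalc(d1, f2)
  for (i in 1:2) for (j in 1:2)
    expect_equal(t1$sfifj[i, j],
                 enum_neg_crossentropy(f2[[i]]$pi_hat, f2[[j]]$pi_hat, 2),
                 tolerance = 1e-10)
})

test_that("implied KL matrices are nonnegative with zero diagonal", {
  sim <- simulate_tides(n_tides = 10, pairs_per_tide = 120, seed = 77)
  fits <- fit_model_set(sim$data)
  tab <- entropies_matcalc(sim$data, fits)
  kl <- diag(tab$sfifj) - tab$sfifj
  expect_true(all(kl >= -1e-8))
  expect_equal(unname(diag(kl)), rep(0, 9))
})

test_that("per-observation rescaling divides all entropic quantities by the total", {
  sim <- simulate_tides(n_tides = 4, pairs_per_tide = 50, seed = 2)
  fits <- fit_model_set(sim$data, c("Poisson", "NegBin"))
  tab <- entropies_matcalc(sim$data, fits)
  po <- per_observation(tab)
  expect_equal(po$sfifj, tab$sfifj / 200, tolerance = 1e-12)
  expect_equal(po$sgg, tab$sgg / 200, tolerance = 1e-12)
  expect_identical(per_observation(po), po)
})
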