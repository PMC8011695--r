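# Synthetic-data generators with closed-form truth: i.i.d. multinomial tide
# counts from a known generating category distribution (a distribution-level
# stand-in for the individual-based behavioural simulator that motivated the
# crab example), multivariate-normal samples for validating the
# nearest-neighbour Sgg estimator, and planar Gaussian model ensembles whose
# whole KL geometry is known exactly.

#' Default generating category distribution
#'
#' A 50:50 mixture of Poisson(1) and Poisson(6) reduced to k categories: a
#' dispersed, bimodal-ish distribution that lies inside none of the nine
#' fitted families, mimicking the output of a behavioural simulator.
#'
#' @param k Number of categories (last = right tail).
#' @return Probability vector of length k.
#' @export
default_generating_pi <- function(k = 6) {
  pmf <- function(x) 0.5 * stats::dpois(x, 1) + 0.5 * stats::dpois(x, 6)
  head_p <- pmf(0:(k - 2))
  c(head_p, 1 - sum(head_p))
}

#' Simulate multinomial tide counts from a known generating distribution
#'
#' Each replicate ("tide") is an independent multinomial draw of size
#' `pairs_per_tide` from `true_pi`. The exact generating-process
#' neg-selfentropy (summed over replicates) and an oracle for the exact
#' neg-crossentropy from the generating process to any candidate probability
#' vector are returned alongside the data. Defaults follow the crab study
#' design: 300 tides of about 400 pairs each.
#'
#' @param true_pi Generating category distribution (sums to 1).
#' @param n_tides Number of replicates.
#' @param pairs_per_tide Total count per replicate (scalar or length
#'   `n_tides`).
#' @param seed Integer seed.
#' @return List with `data` (a [count_dataset()]), `true_pi`, `true_sgg`
#'   (exact, total scale), and `sgf_oracle(pi_s)` returning the exact total
#'   neg-crossentropy from the generating process to `pi_s`.
#' @export
simulate_tides <- function(true_pi = default_generating_pi(),
                           n_tides = 300, pairs_per_tide = 400,
                           seed = 1L) {
  if (abs(sum(true_pi) - 1) > 1e-8) stop("true_pi must sum to 1")
  if (any(true_pi < 0)) stop("true_pi must be nonnegative")
  if (n_tides < 1 || any(pairs_per_tide < 1)) stop("sizes must be positive")
  n_j <- rep_len(pairs_per_tide, n_tides)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  counts <- t(vapply(n_j, function(n) drop(stats::rmultinom(1, n, true_pi)),
                     numeric(length(true_pi))))
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  true_sgg <- sum(vapply(n_j, function(n)
    neg_selfentropy_multinomial(true_pi, n), numeric(1)))
  sgf_oracle <- function(pi_s) sum(vapply(n_j, function(n)
    neg_crossentropy_multinomial(true_pi, pi_s, n), numeric(1)))
  list(data = count_dataset(counts), true_pi = true_pi, true_sgg = true_sgg,
       sgf_oracle = sgf_oracle, seed = seed)
}

#' Simulate a multivariate normal sample
#'
#' @param n Sample size.
#' @param mu Mean vector.
#' @param Sigma Covariance matrix (positive definite).
#' @param seed Integer seed.
#' @return n x q numeric matrix.
#' @export
simulate_mvn <- function(n, mu = rep(0, 7), Sigma = diag(length(mu)),
                         seed = 1L) {
  Sigma <- as.matrix(Sigma)
  tryCatch(chol(Sigma), error = function(e) stop("Sigma must be positive definite"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  if (n == 1) X <- matrix(X, nrow = 1)
  X
}

#' Planar Gaussian model ensemble with exact KL geometry
#'
#' Places r unit-covariance Gaussian model means on a two-dimensional plane
#' inside a three-dimensional ambient space and the generating mean off the
#' plane. Because `KL(N(a, I), N(b, I)) = ||a - b||^2 / 2` is exact and
#' symmetric, every divergence, the neg-selfentropy (closed form), the true
#' orthogonal projection M and the true height h are known exactly; on the
#' embedding scale (square roots of symmetrized KL), model coordinates are
#' the planar means divided by sqrt(2).
#'
#' @param r Number of models (>= 3).
#' @param h_true True perpendicular distance of the generating process from
#'   the model plane, on the embedding (sqrt-KL) scale.
#' @param seed Integer seed.
#' @param spread Standard deviation of the scatter of model means.
#' @param n_eff Effective sample size used to turn the exact per-observation
#'   neg-crossentropies into pseudo-AICs for Akaike weighting.
#' @param m_loc Optional length-2 in-plane location of the generating mean;
#'   by default it is drawn near the model cloud's centroid. Placing it well
#'   outside the cloud builds a one-sided ensemble whose projection falls
#'   outside the convex hull of the models.
#' @return List with `means` (r x 3), `mu_g`, `kl` (exact r x r KL matrix),
#'   `sgg`, `sgf`, `aics`, `true_m` (in-plane generating mean), `h_true`,
#'   `true_dist_to_m` (embedding scale), `diameter` (embedding scale), and
#'   `labels`.
#' @export
planar_ensemble <- function(r = 10, h_true = 0.5, seed = 1L, spread = 2,
                            n_eff = 50, m_loc = NULL) {
  if (r < 3) stop("need at least 3 models")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  P <- matrix(stats::rnorm(2 * r, sd = spread), r, 2)
  # generating mean's in-plane part: near the cloud but not at the centroid
  m <- colMeans(P) + stats::rnorm(2, sd = spread / 2)
  if (!is.null(m_loc)) m <- as.numeric(m_loc)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  z <- h_true * sqrt(2)
  means <- cbind(P, 0)
  mu_g <- c(m, z)
  labels <- paste0("f", seq_len(r))
  rownames(means) <- labels
  kl <- as.matrix(stats::dist(means))^2 / 2
  dimnames(kl) <- list(labels, labels)
  sgg <- mvn_sgg(diag(3))
  kl_g <- colSums((t(P) - m)^2) / 2 + z^2 / 2
  sgf <- stats::setNames(sgg - kl_g, labels)
  aics <- -2 * n_eff * sgf
  true_dist <- sqrt(colSums((t(P) - m)^2) / 2)
  diameter <- max(stats::dist(P / sqrt(2)))
  list(means = means, mu_g = mu_g, kl = kl, sgg = sgg, sgf = sgf,
       aics = aics, true_m = m, h_true = h_true,
       true_dist_to_m = stats::setNames(true_dist, labels),
       diameter = diameter, labels = labels)
}

#' Entropy table of a planar Gaussian ensemble
#'
#' Wraps the exact Gaussian divergences of [planar_ensemble()] in the
#' `entropy_table` layout consumed by the geometry pipeline (selfentropies on
#' the diagonal equal to `sgg` of a 3-D standard normal shifted so that
#' `diag - offdiag` reproduces the exact KL matrix).
#'
#' @param ens A [planar_ensemble()] result.
#' @return An `entropy_table` with `n_list = 1` and
#'   `scale = "per_observation"`.
#' @export
ensemble_entropy_table <- function(ens) {
  r <- length(ens$labels)
  self <- mvn_sgg(diag(3))
  sfifj <- self - ens$kl               # diag = self, diag - offdiag = KL
  entropy_table(sfifj, sgfi = ens$sgf, sfig = ens$sgf, sgg = ens$sgg,
                n_list = 1, scale = "per_observation")
}

#' Bias study of the nearest-neighbour Sgg estimator
#'
#' Repeatedly simulates multivariate-normal samples, estimates Sgg with
#' [weighted_knn_neg_selfentropy()], and summarizes the ratio of the estimate
#' to the closed-form truth per sample size. Defaults run a reduced version
#' of the validation design: dimension 7, identity covariance, means at 10.
#'
#' @param n_values Sample sizes to test.
#' @param n_reps Replicates per sample size.
#' @param q Dimension.
#' @param mu,Sigma Mean and covariance of the generating normal.
#' @param seed Integer seed.
#' @return Data frame with one row per sample size: `n`, `median_ratio`,
#'   `mean_ratio`, `sd_ratio`, `true_sgg`.
#' @export
validate_sgg <- function(n_values = c(10, 25, 50, 150), n_reps = 200, q = 7,
                         mu = rep(10, q), Sigma = diag(q), seed = 1L) {
  truth <- mvn_sgg(Sigma)
  rows <- lapply(seq_along(n_values), function(i) {
    n <- n_values[i]
    est <- vapply(seq_len(n_reps), function(rep) {
      X <- simulate_mvn(n, mu, Sigma, seed = seed + 1000L * i + rep)
      weighted_knn_neg_selfentropy(X)
    }, numeric(1))
    ratio <- est / truth
    data.frame(n = n, median_ratio = stats::median(ratio),
               mean_ratio = mean(ratio), sd_ratio = stats::sd(ratio),
               true_sgg = truth)
  })
  do.call(rbind, rows)
}
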