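# Weighted k-nearest-neighbour estimation of the generating process'
# neg-selfentropy Sgg from an i.i.d. multivariate sample, plus the
# multivariate-normal closed form used to validate it.

#' Closed-form neg-selfentropy of a multivariate normal
#'
#' `Sgg = -0.5 * log((2 pi e)^q * det(Sigma))` for dimension q.
#'
#' @param Sigma Symmetric positive-definite covariance matrix.
#' @return Scalar neg-selfentropy (negative of the differential entropy).
#' @export
#' @examples
#' mvn_sgg(diag(7))  # -9.93257
mvn_sgg <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(unname(Sigma), tol = 1e-8)) stop("Sigma must be symmetric")
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("Sigma must be positive definite"))
  q <- nrow(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  -0.5 * (q * log(2 * pi * exp(1)) + logdet)
}

#' Nearest-neighbour weights for the entropy estimator
#'
#' Solves for the minimum-Euclidean-norm weight vector satisfying
#' `sum(w) = 1` and, for dimensions `q >= 4`, the bias-cancellation
#' constraints `sum_j w_j * Gamma(j + 2l/q) / Gamma(j) = 0` for
#' `l = 1, ..., floor(q/4)`. Below `q = 4` no Gamma constraint binds and the
#' weights are uniform, recovering the unweighted estimator.
#'
#' @param k_nn Number of neighbours.
#' @param q Dimension of the observations.
#' @return Weight vector of length `k_nn`.
#' @export
solve_weights <- function(k_nn, q) {
  n_gamma <- floor(q / 4)
  if (k_nn < 1 + n_gamma)
    stop("k_nn = ", k_nn, " too small for q = ", q,
         " (need at least ", 1 + n_gamma, " neighbours)")
  if (n_gamma == 0) return(rep(1 / k_nn, k_nn))
  j <- seq_len(k_nn)
  A <- rbind(rep(1, k_nn),
             t(vapply(seq_len(n_gamma), function(l)
               exp(lgamma(j + 2 * l / q) - lgamma(j)), numeric(k_nn))))
  b <- c(1, rep(0, n_gamma))
  # minimum-norm solution of the underdetermined system A w = b, with two
  # iterative-refinement sweeps to push constraint residuals to ~1e-13
  w <- drop(t(A) %*% solve(A %*% t(A), b))
  for (i in 1:2) {
    res <- b - drop(A %*% w)
    w <- w + drop(t(A) %*% solve(A %*% t(A), res))
  }
  w
}

#' Weighted k-nearest-neighbour estimate of Sgg
#'
#' Kozachenko-Leonenko-type estimator: with `xi_(j),i = (n-1) exp(-digamma(j))
#' V_q ||X_(j),i - X_i||^q` (j-th nearest neighbour of observation i, V_q the
#' unit-ball volume), the entropy estimate is the weighted average of
#' `log xi` over neighbours and observations, and the returned value is its
#' negative. Weights come from [solve_weights()] for samples of at least 30
#' observations; smaller samples use the unweighted (uniform) estimator.
#'
#' @param X Numeric matrix, n observations x q dimensions.
#' @param k_nn Number of neighbours, or `"auto"` for `round(n^(1/3))`.
#' @param weighted `NULL` (choose by sample size), `TRUE`, or `FALSE`.
#' @return Estimated neg-selfentropy (scalar).
#' @export
weighted_knn_neg_selfentropy <- function(X, k_nn = "auto", weighted = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); q <- ncol(X)
  if (n < 2) stop("need at least 2 observations")
  if (any(!is.finite(X))) stop("X must be finite")
  if (identical(k_nn, "auto")) k_nn <- max(1L, round(n^(1 / 3)))
  if (k_nn >= n) stop("k_nn must be smaller than the number of observations")
  if (is.null(weighted)) weighted <- n >= 30
  w <- if (weighted) solve_weights(k_nn, q) else rep(1 / k_nn, k_nn)

  dm <- as.matrix(stats::dist(X))
  diag(dm) <- Inf
  nn <- t(apply(dm, 1, function(row) sort(row)[seq_len(k_nn)]))
  if (any(nn == 0)) {
    # duplicate observations break the log; deterministic jitter, then redo
    warning("zero nearest-neighbour distances; applying deterministic jitter")
    scale <- max(apply(X, 2, function(col) diff(range(col))), 1)
    seed <- as.integer(abs(sum(X * 1e4)) %% .Machine$integer.max)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-12 * scale), n, q)
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    dm <- as.matrix(stats::dist(X))
    diag(dm) <- Inf
    nn <- t(apply(dm, 1, function(row) sort(row)[seq_len(k_nn)]))
  }
  log_vq <- (q / 2) * log(pi) - lgamma(1 + q / 2)
  j <- seq_len(k_nn)
  # log xi_(j),i for each observation (rows) and neighbour rank (cols)
  log_xi <- sweep(q * log(nn), 2, log(n - 1) - digamma(j) + log_vq, "+")
  h_hat <- mean(log_xi %*% w)
  -h_hat
}
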