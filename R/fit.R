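# Fitting count-distribution families to ordered category counts through the
# reduced-parameter multinomial likelihood: the first k - 1 multinomial cell
# probabilities are the family pmf at 0, ..., k - 2 and the last cell absorbs
# the right tail mass P(X >= k - 1).

#' Reduce a count distribution to k multinomial cell probabilities
#'
#' @param family Family name or object (see [get_family()]).
#' @param theta Parameter vector on the natural scale.
#' @param k Number of ordered categories (last one is the right tail).
#' @return Probability vector of length `k`, nonnegative, summing to 1.
#' @export
#' @examples
#' reduce_to_multinomial("Poisson", 1, k = 3)  # e^-1, e^-1, 1 - 2 e^-1
reduce_to_multinomial <- function(family, theta, k) {
  fam <- get_family(family)
  .check_theta(fam, theta)
  if (k < 2) stop("need k >= 2 categories")
  head_p <- fam$pmf(0:(k - 2), theta)
  tail_p <- 1 - sum(head_p)
  if (tail_p < -1e-12)
    stop("pmf head mass exceeds 1 by more than 1e-12 for ", fam$name,
         " (tail = ", tail_p, ")")
  pi <- c(head_p, max(tail_p, 0))
  pi / sum(pi)
}

#' Multinomial log-likelihood of one replicate
#'
#' Returns `log(n!/(y_1! ... y_k!)) + sum_i y_i log(pi_i)`; `-Inf` when a
#' positive count falls in a zero-probability cell (data/model
#' incompatibility).
#'
#' @param counts_row Integer vector of category counts.
#' @param pi Probability vector of the same length.
#' @return Log-likelihood (scalar).
#' @export
#' @examples
#' multinomial_loglik(c(1, 1), c(0.5, 0.5))  # log(2 * 0.25)
multinomial_loglik <- function(counts_row, pi) {
  if (length(counts_row) != length(pi)) stop("counts_row and pi lengths differ")
  n <- sum(counts_row)
  if (n < 1) stop("replicate total must be >= 1")
  if (any(counts_row > 0 & pi <= 0)) return(-Inf)
  pos <- counts_row > 0
  lgamma(n + 1) - sum(lgamma(counts_row + 1)) +
    sum(counts_row[pos] * log(pi[pos]))
}

.dataset_loglik <- function(counts, fam, theta) {
  k <- ncol(counts)
  pi <- tryCatch(reduce_to_multinomial(fam, theta, k), error = function(e) NULL)
  if (is.null(pi)) return(-Inf)
  sum(apply(counts, 1, multinomial_loglik, pi = pi))
}

# moment summaries of the pooled counts, treating the top category at its
# lower bound k - 1 (it is a right tail)
.moment_summaries <- function(counts) {
  k <- ncol(counts)
  tot <- colSums(counts)
  n <- sum(tot)
  vals <- 0:(k - 1)
  m <- sum(vals * tot) / n
  v <- sum((vals - m)^2 * tot) / n
  list(m = m, v = max(v, 1e-6), p0 = tot[1] / n, p1 = if (k >= 2) tot[2] / n else 0)
}

.fit_one <- function(counts, fam, n_restarts = 4) {
  ms <- .moment_summaries(counts)
  th0 <- fam$start(ms$m, ms$v, ms$p0, ms$p1)
  u0 <- fam$to_unc(th0)
  negll <- function(u) {
    th <- fam$to_nat(u)
    ll <- .dataset_loglik(counts, fam, th)
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- list(u0)
  if (n_restarts > 0) {
    # deterministic jittered restarts around the moment start
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(20191108L)
    for (i in seq_len(n_restarts))
      starts[[i + 1]] <- u0 + stats::rnorm(length(u0), sd = 0.5)
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
  best <- NULL
  for (s in starts) {
    fit <- if (length(s) == 1) {
      o <- stats::optimize(function(u) negll(u), interval = c(-12, 12))
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      f1 <- stats::optim(s, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      # polish with BFGS from the Nelder-Mead solution
      tryCatch(stats::optim(f1$par, negll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               error = function(e) f1)
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- fam$to_nat(best$par)
  names(theta) <- fam$par_names
  list(theta = theta, loglik = -best$value,
       converged = is.finite(best$value) && best$value < 1e11)
}

#' Fit one count-model family to a count dataset
#'
#' Maximizes the reduced-parameter multinomial likelihood by derivative-free
#' search from a method-of-moments start plus jittered restarts (deterministic
#' seed). In `"pooled"` mode a single parameter vector is shared by all
#' replicates; in `"per_replicate"` mode every replicate gets its own vector
#' and log-likelihoods and parameter counts are summed.
#'
#' @param data A [count_dataset()] (or a count matrix).
#' @param family Family name or object.
#' @param mode `"pooled"` (default) or `"per_replicate"`.
#' @return An object of class `fitted_count_model` with fields `family`,
#'   `theta_hat`, `pi_hat` (vector, or N x k matrix in per-replicate mode),
#'   `loglik`, `n_params`, `aic`, `expected_freqs`, `converged`.
#' @export
#' @examples
#' d <- count_dataset(rbind(c(112, 96, 101, 48, 22, 16)))
#' fit_model(d, "Poisson")
fit_model <- function(data, family, mode = c("pooled", "per_replicate")) {
  mode <- match.arg(mode)
  data <- as_count_dataset(data)
  fam <- get_family(family)
  k <- ncol(data$counts)
  if (k - 1 < fam$n_params)
    warning(fam$name, ": ", fam$n_params, " free parameters with only ", k,
            " categories; fit may be non-identifiable")
  if (mode == "pooled") {
    res <- .fit_one(data$counts, fam)
    pi_hat <- reduce_to_multinomial(fam, res$theta, k)
    loglik <- res$loglik
    n_params <- fam$n_params
    theta_hat <- res$theta
    expected <- outer(data$n_j, pi_hat)
    converged <- res$converged
  } else {
    per <- lapply(seq_len(nrow(data$counts)), function(j)
      .fit_one(data$counts[j, , drop = FALSE], fam))
    theta_hat <- do.call(rbind, lapply(per, `[[`, "theta"))
    pi_hat <- t(vapply(seq_len(nrow(theta_hat)), function(j)
      reduce_to_multinomial(fam, theta_hat[j, ], k), numeric(k)))
    loglik <- sum(vapply(per, `[[`, numeric(1), "loglik"))
    n_params <- fam$n_params * nrow(data$counts)
    expected <- pi_hat * data$n_j
    converged <- all(vapply(per, `[[`, logical(1), "converged"))
  }
  colnames(expected) <- data$category_labels
  structure(list(
    family = fam$name, mode = mode, theta_hat = theta_hat, pi_hat = pi_hat,
    loglik = loglik, n_params = n_params, aic = -2 * loglik + 2 * n_params,
    expected_freqs = expected, n_j = data$n_j, converged = converged
  ), class = "fitted_count_model")
}

#' Akaike's information criterion of a fitted count model
#'
#' @param fit A `fitted_count_model`.
#' @return `-2 * loglik + 2 * n_params`.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "fitted_count_model"))
  -2 * fit$loglik + 2 * fit$n_params
}

#' Fit a whole model set
#'
#' @param data A [count_dataset()].
#' @param families Character vector of family names (default: all nine).
#' @param mode Passed to [fit_model()].
#' @return Named list of `fitted_count_model` objects.
#' @export
fit_model_set <- function(data, families = model_families(),
                          mode = c("pooled", "per_replicate")) {
  mode <- match.arg(mode)
  fits <- lapply(families, function(f) fit_model(data, f, mode))
  names(fits) <- families
  fits
}

#' @export
print.fitted_count_model <- function(x, ...) {
  cat("Fitted", x$family, "model (", x$mode, ")\n")
  if (is.matrix(x$theta_hat)) {
    cat("  per-replicate parameter estimates (first rows):\n")
    print(utils::head(signif(x$theta_hat, 5), 3))
  } else {
    cat("  theta_hat:", paste(names(x$theta_hat), "=",
                              signif(x$theta_hat, 5), collapse = ", "), "\n")
  }
  cat("  loglik:", format(x$loglik), "  AIC:", format(x$aic), "\n")
  invisible(x)
}
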