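# Exact neg-crossentropies between reduced-parameter multinomial models.
# For cell probabilities pi_r (true) and pi_s (approximating) and a total
# count n, the expected log-probability of the multinomial outcome is
#   H(f_r, f_s) = log n! + n sum_i pi_{i,r} log pi_{i,s}
#                 - sum_i E[log Y_i!],  Y_i ~ Binomial(n, pi_{i,r}),
# which is computed exactly with log-gamma terms. All Kullback-Leibler
# divergences between multinomial models follow as differences of these.

.validate_pi <- function(pi, nm) {
  if (any(pi < -1e-12)) stop(nm, " has negative entries")
  if (abs(sum(pi) - 1) > 1e-8) stop(nm, " does not sum to 1 (", sum(pi), ")")
  pmax(pi, 0)
}

# E[ log(Y!) ] for Y ~ Binomial(n, p), exactly, for each p
.e_lfact_binom <- function(p, n) {
  lf <- lgamma(0:n + 1)
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(lf[n + 1])
    sum(stats::dbinom(0:n, n, pp) * lf)
  }, numeric(1))
}

#' Exact neg-crossentropy between two multinomial models
#'
#' The expected value, under the multinomial with cell probabilities `pi_r`,
#' of the log multinomial probability with cell probabilities `pi_s`, for a
#' total count `n`. With `pi_s = pi_r` this is the neg-selfentropy. Returns
#' `-Inf` when `pi_s` puts zero mass where `pi_r` does not.
#'
#' @param pi_r,pi_s Probability vectors of equal length.
#' @param n Total count of the multinomial (>= 1).
#' @return Scalar neg-crossentropy (a negative number except in degenerate
#'   cases).
#' @export
#' @examples
#' neg_crossentropy_multinomial(c(0.5, 0.5), c(0.5, 0.5), n = 2)
neg_crossentropy_multinomial <- function(pi_r, pi_s, n) {
  if (length(pi_r) != length(pi_s)) stop("pi_r and pi_s lengths differ")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  pi_r <- .validate_pi(pi_r, "pi_r"); pi_s <- .validate_pi(pi_s, "pi_s")
  if (any(pi_r > 0 & pi_s == 0)) return(-Inf)
  pos <- pi_r > 0
  lgamma(n + 1) + n * sum(pi_r[pos] * log(pi_s[pos])) -
    sum(.e_lfact_binom(pi_r, n))
}

#' @rdname neg_crossentropy_multinomial
#' @param pi Probability vector.
#' @export
neg_selfentropy_multinomial <- function(pi, n) {
  neg_crossentropy_multinomial(pi, pi, n)
}

#' Kullback-Leibler divergence between two multinomial models
#'
#' Computed as the difference of neg-self and neg-crossentropy,
#' `H(r, r) - H(r, s)`; the log-factorial terms cancel, so the result equals
#' the categorical identity `n * sum(pi_r * log(pi_r / pi_s))`.
#'
#' @inheritParams neg_crossentropy_multinomial
#' @return Nonnegative divergence; zero iff the two probability vectors agree.
#' @export
kl_multinomial <- function(pi_r, pi_s, n) {
  neg_selfentropy_multinomial(pi_r, n) -
    neg_crossentropy_multinomial(pi_r, pi_s, n)
}

#' Empirical (fully parameterized) category probabilities
#'
#' The sample proportions that play the role of the generating-process cell
#' probabilities when estimating divergences to the unknown truth.
#'
#' @param data A [count_dataset()].
#' @param mode `"per_replicate"` (one probability vector per row, the default)
#'   or `"pooled"` (column totals over the grand total).
#' @return A matrix (per replicate) or vector (pooled) of proportions.
#' @export
empirical_pis <- function(data, mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  data <- as_count_dataset(data)
  if (mode == "pooled") colSums(data$counts) / sum(data$counts)
  else sweep(data$counts, 1, data$n_j, "/")
}

#' Neg-crossentropy of a fitted model from its AIC
#'
#' The per-observation estimate `loglik/n - k/n`, identical to
#' `-AIC / (2 n)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k_params Number of free parameters.
#' @param n Sample size.
#' @return Estimated per-observation neg-crossentropy.
#' @export
sgf_from_aic <- function(loglik, k_params, n) {
  if (n < 1) stop("n must be >= 1")
  # evaluated through the AIC so the -AIC/(2n) identity holds bit-exactly
  -(-2 * loglik + 2 * k_params) / (2 * n)
}

.fit_pi_matrix <- function(fit, N, k) {
  if (is.matrix(fit$pi_hat)) fit$pi_hat
  else matrix(fit$pi_hat, nrow = N, ncol = k, byrow = TRUE)
}

#' Entropy table for a fitted model set
#'
#' Computes, summed over replicates, the exact neg-crossentropies between all
#' pairs of fitted models (`sfifj`), between the empirical model (sample
#' proportions, standing in for the generating process) and each fitted model
#' in both directions (`sgfi`, `sfig`), and the empirical plug-in
#' neg-selfentropy (`sgg`).
#'
#' @param data A [count_dataset()].
#' @param fits Named list of `fitted_count_model` objects on the same data.
#' @param empirical_mode How the empirical proportions are formed; see
#'   [empirical_pis()].
#' @return An object of class `entropy_table` with fields `sfifj` (r x r
#'   matrix), `sgfi`, `sfig` (length-r vectors), `sgg`, `n_list`, `labels`,
#'   and `scale = "total"`.
#' @export
entropies_matcalc <- function(data, fits,
                              empirical_mode = c("per_replicate", "pooled")) {
  empirical_mode <- match.arg(empirical_mode)
  data <- as_count_dataset(data)
  N <- nrow(data$counts); k <- ncol(data$counts)
  r <- length(fits)
  labels <- names(fits)
  if (is.null(labels)) labels <- vapply(fits, `[[`, character(1), "family")
  pis <- lapply(fits, .fit_pi_matrix, N = N, k = k)
  emp <- empirical_pis(data, empirical_mode)
  if (!is.matrix(emp)) emp <- matrix(emp, nrow = N, ncol = k, byrow = TRUE)
  n_list <- data$n_j

  cross_sum <- function(A, B) {
    sum(vapply(seq_len(N), function(j)
      neg_crossentropy_multinomial(A[j, ], B[j, ], n_list[j]), numeric(1)))
  }
  sfifj <- matrix(NA_real_, r, r, dimnames = list(labels, labels))
  for (i in seq_len(r)) for (j in seq_len(r))
    sfifj[i, j] <- cross_sum(pis[[i]], pis[[j]])
  sgfi <- vapply(pis, function(P) cross_sum(emp, P), numeric(1))
  sfig <- vapply(pis, function(P) cross_sum(P, emp), numeric(1))
  sgg <- cross_sum(emp, emp)
  structure(list(sfifj = sfifj, sgfi = stats::setNames(sgfi, labels),
                 sfig = stats::setNames(sfig, labels), sgg = sgg,
                 n_list = n_list, labels = labels, scale = "total"),
            class = "entropy_table")
}

#' Assemble an entropy table from precomputed matrices
#'
#' For workflows where the neg-crossentropy matrix and the g-row vectors come
#' from elsewhere (e.g., printed output of another fitting run).
#'
#' @param sfifj r x r neg-crossentropy matrix with model labels.
#' @param sgfi,sfig Optional length-r vectors of neg-crossentropies to and
#'   from the generating process.
#' @param sgg Optional neg-selfentropy of the generating process.
#' @param n_list Per-replicate totals (defaults to 1, i.e., quantities already
#'   on the working scale).
#' @param scale `"total"` or `"per_observation"`.
#' @return An `entropy_table`.
#' @export
entropy_table <- function(sfifj, sgfi = NULL, sfig = NULL, sgg = NA_real_,
                          n_list = 1, scale = "total") {
  sfifj <- as.matrix(sfifj)
  if (nrow(sfifj) != ncol(sfifj)) stop("sfifj must be square")
  labels <- rownames(sfifj)
  if (is.null(labels)) labels <- paste0("f", seq_len(nrow(sfifj)))
  dimnames(sfifj) <- list(labels, labels)
  structure(list(sfifj = sfifj, sgfi = sgfi, sfig = sfig, sgg = sgg,
                 n_list = n_list, labels = labels, scale = scale),
            class = "entropy_table")
}

#' Convert an entropy table between total and per-observation scales
#'
#' Dividing all entropic quantities by the total number of observations puts
#' them on a common per-observation scale, which is the working scale of the
#' projection solver.
#'
#' @param table An `entropy_table`.
#' @return An `entropy_table` with `scale = "per_observation"`.
#' @export
per_observation <- function(table) {
  stopifnot(inherits(table, "entropy_table"))
  if (table$scale == "per_observation") return(table)
  tot <- sum(table$n_list)
  table$sfifj <- table$sfifj / tot
  if (!is.null(table$sgfi)) table$sgfi <- table$sgfi / tot
  if (!is.null(table$sfig)) table$sfig <- table$sfig / tot
  if (!is.na(table$sgg)) table$sgg <- table$sgg / tot
  table$scale <- "per_observation"
  table
}

#' @export
print.entropy_table <- function(x, ...) {
  cat("Entropy table (", x$scale, " scale ), ", length(x$labels),
      " models\n", sep = "")
  print(signif(x$sfifj, 7))
  if (!is.null(x$sgfi)) { cat("sgfi:\n"); print(signif(x$sgfi, 7)) }
  if (!is.na(x$sgg)) cat("sgg:", format(x$sgg), "\n")
  invisible(x)
}
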