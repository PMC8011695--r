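# Distance geometry of the model set: the symmetrized-KL dissimilarity
# matrix, its non-metric MDS embedding (SMACOF majorization with isotonic
# disparities), and the Akaike-weight machinery used for model averaging.

#' Square-root symmetrized-KL dissimilarity matrix
#'
#' From an entropy table, forms `KL(i, j) = sfifj[i, i] - sfifj[i, j]`,
#' symmetrizes by the arithmetic average of the two directions, and takes
#' element-wise square roots (divergences are treated as squared statistical
#' distances). Optionally appends a row/column for the generating process g
#' using `KL(g, f_i) = sgg - sgfi[i]` and `KL(f_i, g) = sfifj[i, i] -
#' sfig[i]`.
#'
#' @param table An `entropy_table`.
#' @param include_g Append the generating-process row/column (requires
#'   `sgg`, `sgfi`, `sfig`).
#' @param kl_factor 1 (default) or 2 (Akaike's 2*KL convention).
#' @return An object of class `divergence_matrix`: list with `D` (symmetric,
#'   zero-diagonal dissimilarities), `kl` (the symmetrized squared
#'   divergences), and `labels`.
#' @export
symmetrized_kl_matrix <- function(table, include_g = FALSE, kl_factor = 1) {
  stopifnot(inherits(table, "entropy_table"))
  S <- table$sfifj
  kl <- diag(S) - S                     # KL(i, j), rows = first argument
  labels <- table$labels
  if (include_g) {
    if (is.null(table$sgfi) || is.null(table$sfig) || is.na(table$sgg))
      stop("include_g requires sgg, sgfi and sfig")
    kl_g_f <- table$sgg - table$sgfi
    kl_f_g <- diag(S) - table$sfig
    kl <- rbind(cbind(kl, g = kl_f_g), g = c(kl_g_f, 0))
    labels <- c(labels, "g")
  }
  sym <- (kl + t(kl)) / 2 * kl_factor
  tol <- 1e-8 * max(1, max(abs(sym)))
  if (any(sym < -tol))
    stop("negative symmetrized KL beyond numerical tolerance (min ",
         min(sym), ")")
  if (any(sym < 0)) {
    warning("small negative symmetrized KL values clamped to 0")
    sym[sym < 0] <- 0
  }
  diag(sym) <- 0
  D <- sqrt(sym)
  dimnames(D) <- dimnames(sym) <- list(labels, labels)
  structure(list(D = D, kl = sym, labels = labels),
            class = "divergence_matrix")
}

.as_dissim_matrix <- function(D) {
  if (inherits(D, "divergence_matrix")) D$D
  else if (inherits(D, "dist")) as.matrix(D)
  else as.matrix(D)
}

# pool-adjacent-violators: isotonic (nondecreasing) least-squares fit
.pava <- function(y) {
  n <- length(y)
  vals <- y; ws <- rep(1, n); sizes <- rep(1L, n); nb <- n
  repeat {
    viol <- which(vals[-nb] > vals[-1] + 0)
    if (!length(viol)) break
    j <- viol[1]
    newv <- (vals[j] * ws[j] + vals[j + 1] * ws[j + 1]) / (ws[j] + ws[j + 1])
    vals <- c(vals[seq_len(j - 1)], newv, if (j + 2 <= nb) vals[(j + 2):nb])
    ws <- c(ws[seq_len(j - 1)], ws[j] + ws[j + 1], if (j + 2 <= nb) ws[(j + 2):nb])
    sizes <- c(sizes[seq_len(j - 1)], sizes[j] + sizes[j + 1],
               if (j + 2 <= nb) sizes[(j + 2):nb])
    nb <- nb - 1L
  }
  rep(vals, sizes)
}

#' Non-metric multidimensional scaling by SMACOF majorization
#'
#' Embeds a dissimilarity matrix in `d` dimensions by iterative majorization
#' (Guttman transform), with disparities obtained by monotone (isotonic)
#' regression of configuration distances on dissimilarities in `"ordinal"`
#' mode (ties handled by the primary approach: tied dissimilarities may
#' untie) or by an affine fit in `"interval"` mode. Initialization is
#' classical (Torgerson) metric scaling. The reported stress is normalized
#' stress-1, `sqrt(sum((dhat - d)^2) / sum(d^2))`.
#'
#' @param D A `divergence_matrix`, `dist` object, or symmetric matrix.
#' @param d Target dimension (default 2).
#' @param mode `"ordinal"` (default) or `"interval"`.
#' @param maxit,tol Iteration cap and stress-change convergence tolerance.
#' @return An object of class `mds_embedding`: `coords` (r x d), `stress`,
#'   `disparities`, `dissim` (input matrix), `stress_trace`, `converged`.
#' @export
nmds <- function(D, d = 2, mode = c("ordinal", "interval"),
                 maxit = 10000, tol = 1e-9) {
  mode <- match.arg(mode)
  Dm <- .as_dissim_matrix(D)
  r <- nrow(Dm)
  if (r < d + 1) stop("need at least d + 1 = ", d + 1, " objects")
  labels <- rownames(Dm)
  if (is.null(labels)) labels <- paste0("f", seq_len(r))
  lt <- lower.tri(Dm)
  delta <- Dm[lt]
  m <- length(delta)

  # Torgerson start; pad with tiny deterministic coordinates if the double-
  # centred matrix has fewer than d positive eigenvalues
  X <- suppressWarnings(stats::cmdscale(Dm, k = d))
  if (ncol(X) < d)
    X <- cbind(X, matrix(1e-8 * sin(seq_len(r * (d - ncol(X)))), nrow = r))
  if (any(stats::dist(X) == 0))
    X <- X + 1e-9 * matrix(sin(seq_len(r * d)), r, d)

  ord <- order(delta)
  dvec <- as.vector(stats::dist(X))
  normalize <- function(dh) dh * sqrt(m / sum(dh^2))
  disparities <- function(dvec) {
    if (mode == "ordinal") {
      # primary tie approach: within blocks of equal delta, sort by distance
      o2 <- order(delta, dvec)
      dh <- numeric(m)
      dh[o2] <- .pava(dvec[o2])
    } else {
      cf <- stats::coef(stats::lm.fit(cbind(1, delta), dvec))
      dh <- pmax(cf[1] + cf[2] * delta, 0)
    }
    normalize(dh)
  }
  dhat <- disparities(dvec)
  stress1 <- function(dvec, dhat) sqrt(sum((dhat - dvec)^2) / sum(dvec^2))
  s_old <- stress1(dvec, dhat)
  trace <- s_old
  converged <- FALSE
  for (it in seq_len(maxit)) {
    # Guttman transform
    Bm <- matrix(0, r, r)
    ratio <- ifelse(dvec > 0, dhat / dvec, 0)
    Bm[lower.tri(Bm)] <- -ratio
    Bm <- Bm + t(Bm)
    diag(Bm) <- -colSums(Bm)
    X <- Bm %*% X / r
    dvec <- as.vector(stats::dist(X))
    dhat <- disparities(dvec)
    s_new <- stress1(dvec, dhat)
    trace <- c(trace, s_new)
    if (abs(s_old - s_new) < tol) { converged <- TRUE; break }
    s_old <- s_new
  }
  # put the configuration back on the dissimilarity scale (least-squares
  # ratio fit of configuration distances to the input dissimilarities) so
  # that coordinates are interpretable in sqrt-divergence units; stress-1 is
  # invariant under this common rescaling of distances and disparities
  sc <- sum(delta * dvec) / sum(dvec^2)
  X <- X * sc
  dhat <- dhat * sc
  rownames(X) <- labels
  Dh <- matrix(0, r, r, dimnames = list(labels, labels))
  Dh[lt] <- dhat; Dh <- Dh + t(Dh)
  structure(list(coords = X, stress = s_new, disparities = Dh,
                 dissim = Dm, mode = mode, stress_trace = trace,
                 converged = converged),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("NMDS embedding (", x$mode, " ), ", nrow(x$coords), " objects in ",
      ncol(x$coords), "-D, stress-1 = ", signif(x$stress, 4),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' AIC differences
#'
#' @param aics Vector of AIC values.
#' @return `aics - min(aics)`; the best model maps to exactly 0.
#' @export
delta_aic <- function(aics) {
  if (any(!is.finite(aics))) stop("AICs must be finite")
  aics - min(aics)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum(exp(-delta_r / 2))`, computed with the
#' max-subtraction trick.
#'
#' @param aics Vector of AIC values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  e <- exp(-delta_aic(aics) / 2)
  e / sum(e)
}

#' Implicit Akaike prior of a model
#'
#' The subjective model prior under which Akaike weights are posterior model
#' probabilities: `q = C * exp(0.5 * k * log(n) - k)` (unnormalized; for
#' sample sizes above e^2 ~ 7.4 it increases with the parameter count k).
#'
#' @param k_params Number of free parameters.
#' @param n Sample size.
#' @return Unnormalized prior weight.
#' @export
akaike_prior <- function(k_params, n) {
  if (n < 1) stop("n must be >= 1")
  exp(0.5 * k_params * log(n) - k_params)
}

#' Model-averaged location in the embedding
#'
#' @param emb An `mds_embedding` (or coordinate matrix).
#' @param weights Nonnegative weights summing to 1 (e.g., Akaike weights).
#' @return Length-d coordinate vector; always inside the convex hull of the
#'   model coordinates.
#' @export
model_average_location <- function(emb, weights) {
  coords <- if (inherits(emb, "mds_embedding")) emb$coords else as.matrix(emb)
  if (length(weights) != nrow(coords)) stop("one weight per model required")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  drop(crossprod(coords, weights))
}
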