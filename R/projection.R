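# Solving the Pythagorean system for the orthogonal projection of the
# generating process onto the embedded model plane: for each model i,
#   KL(g, f_i) = d(f_i, M)^2 + h_i^2,  with h_1 = h_2 = ... = h,
# so M = (y1*, y2*) is found by minimizing the spread of the implied h_i^2.

.affine_scale_map <- function(emb) {
  # least-squares affine map from squared input dissimilarities (entropy
  # scale) to the embedding's squared configuration distances
  lt <- lower.tri(emb$dissim)
  x <- emb$dissim[lt]^2
  y <- as.vector(stats::dist(emb$coords))^2
  if (stats::var(x) < .Machine$double.eps) {
    cf <- c(0, 1)
  } else {
    cf <- stats::coef(stats::lm.fit(cbind(1, x), y))
    if (!is.finite(cf[2]) || cf[2] <= 0) cf <- c(0, sum(y) / sum(x))
  }
  f <- function(z) cf[1] + cf[2] * z
  attr(f, "coefficients") <- c(intercept = unname(cf[1]), slope = unname(cf[2]))
  f
}

#' Project the generating process onto the model plane
#'
#' Given the embedded model coordinates, an estimate of the generating
#' process' neg-selfentropy `sgg`, and the per-model neg-crossentropies
#' `sgf` (same entropy scale), the squared divergences `sgg - sgf[i]` are
#' mapped onto the embedding's squared-distance scale and the location `M`
#' minimizing the dispersion of the implied per-model squared heights
#' `h_i^2 = map(sgg - sgf_i) - d(f_i, M)^2` is found by multi-start
#' quasi-Newton search (objective: `sum_{i<j} (h_i^2 - h_j^2)^2`).
#'
#' @param emb An `mds_embedding` of the r models.
#' @param sgg Neg-selfentropy of the generating process.
#' @param sgf Length-r vector of neg-crossentropies `Sgf_i`.
#' @param scale_map `"affine"` (default; least-squares affine map from
#'   squared dissimilarities to squared configuration distances),
#'   `"identity"`, or a monotone function.
#' @param n_starts Number of perturbed starts around the model centroid.
#' @return An object of class `model_projection`: `m_coords`, `h`,
#'   `h_sq_residuals`, `dist_to_models`, `sgg_used`, `objective`,
#'   `inconsistent` (TRUE when all implied squared heights are negative).
#' @export
project_generating_process <- function(emb, sgg, sgf,
                                       scale_map = c("affine", "identity"),
                                       n_starts = 8) {
  stopifnot(inherits(emb, "mds_embedding"))
  coords <- emb$coords
  r <- nrow(coords); d <- ncol(coords)
  if (length(sgf) != r) stop("sgf must have one entry per embedded model")
  map <- if (is.function(scale_map)) scale_map
         else switch(match.arg(scale_map),
                     affine = .affine_scale_map(emb),
                     identity = function(z) z)
  target2 <- map(sgg - sgf)            # squared g-to-model distances
  if (any(target2 < 0))
    warning("negative mapped squared divergences; check entropy scales")

  h_sq <- function(M) target2 - colSums((t(coords) - M)^2)
  objective <- function(M) {
    v <- h_sq(M)
    r * sum(v^2) - sum(v)^2            # = sum_{i<j} (v_i - v_j)^2
  }
  centroid <- colMeans(coords)
  spread <- mean(sqrt(colSums((t(coords) - centroid)^2)))
  starts <- list(centroid)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(773L)
  for (i in seq_len(n_starts))
    starts[[i + 1]] <- centroid + stats::rnorm(d, sd = spread)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  M <- best$par
  names(M) <- colnames(coords)
  v <- h_sq(M)
  h2 <- mean(v)
  structure(list(m_coords = M, h = sqrt(max(h2, 0)), h_sq_residuals = v,
                 dist_to_models = sqrt(colSums((t(coords) - M)^2)),
                 sgg_used = sgg, objective = best$value,
                 scale_map = attr(map, "coefficients"),
                 inconsistent = h2 < 0),
            class = "model_projection")
}

#' @export
print.model_projection <- function(x, ...) {
  cat("Model projection: M = (", paste(signif(x$m_coords, 5), collapse = ", "),
      "), h = ", signif(x$h, 5), "\n", sep = "")
  if (x$inconsistent)
    cat("  note: mean implied h^2 was negative (truth below the manifold?)\n")
  invisible(x)
}

.subset_entropy_table <- function(table, keep) {
  entropy_table(table$sfifj[keep, keep, drop = FALSE],
                sgfi = table$sgfi[keep], sfig = table$sfig[keep],
                sgg = table$sgg, n_list = table$n_list, scale = table$scale)
}

#' Stability of projection vs model average under model elimination
#'
#' Repeatedly removes models (in the order given), re-runs the NMDS
#' embedding, the projection of the generating process, and the
#' model-averaged location, and reports the displacement of each from the
#' full-set run. Configurations are compared through distances to the models
#' common to both runs (coordinate systems of separate NMDS runs are
#' arbitrary up to rotation, so displacement is measured on inter-point
#' distances, not coordinates).
#'
#' @param table An `entropy_table` carrying `sgg`, `sgfi`, `sfig`.
#' @param order Character vector of model labels to eliminate, in order.
#' @param aics AIC values for the Akaike weights; if `NULL`, derived from
#'   `sgfi` via `AIC = -2 * sum(n_list) * sgfi` (valid on the
#'   per-observation scale).
#' @param d Embedding dimension.
#' @param ... Passed to [nmds()].
#' @return A data frame with one row per elimination step (step 0 = full
#'   set): models remaining, stress, h, projection and model-average
#'   displacement from the full-set run.
#' @export
elimination_trajectory <- function(table, order, aics = NULL, d = 2, ...) {
  stopifnot(inherits(table, "entropy_table"))
  labels <- table$labels
  if (is.null(aics)) aics <- -2 * sum(table$n_list) * table$sgfi
  names(aics) <- labels
  run <- function(keep) {
    tb <- .subset_entropy_table(table, keep)
    emb <- nmds(symmetrized_kl_matrix(tb), d = d, ...)
    proj <- project_generating_process(emb, tb$sgg, tb$sgfi)
    w <- akaike_weights(aics[keep])
    avg <- model_average_location(emb, w)
    dist_avg <- sqrt(colSums((t(emb$coords) - avg)^2))
    list(keep = keep, emb = emb, proj = proj,
         dist_proj = stats::setNames(proj$dist_to_models, keep),
         dist_avg = stats::setNames(dist_avg, keep))
  }
  full <- run(labels)
  steps <- list(full)
  remaining <- labels
  boundary <- FALSE
  for (i in seq_along(order)) {
    cand <- setdiff(remaining, order[i])
    if (length(cand) < d + 1) { boundary <- TRUE; break }
    remaining <- cand
    steps[[length(steps) + 1]] <- run(remaining)
  }
  disp <- function(st) {
    common <- intersect(st$keep, full$keep)
    c(proj = sqrt(mean((st$dist_proj[common] - full$dist_proj[common])^2)),
      avg = sqrt(mean((st$dist_avg[common] - full$dist_avg[common])^2)))
  }
  out <- data.frame(
    step = seq_along(steps) - 1L,
    n_models = vapply(steps, function(s) length(s$keep), integer(1)),
    stress = vapply(steps, function(s) s$emb$stress, numeric(1)),
    h = vapply(steps, function(s) s$proj$h, numeric(1)),
    proj_displacement = vapply(steps, function(s) disp(s)[["proj"]], numeric(1)),
    avg_displacement = vapply(steps, function(s) disp(s)[["avg"]], numeric(1))
  )
  attr(out, "steps") <- steps
  attr(out, "stopped_at_boundary") <- boundary
  out
}
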