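#' Full model-space analysis of a count dataset
#'
#' Runs the whole pipeline: fits the model set through the reduced-parameter
#' multinomial likelihood, computes the exact entropy table, builds the
#' square-root symmetrized-KL dissimilarity matrix, embeds the models with
#' non-metric MDS, solves for the orthogonal projection of the generating
#' process (using the empirical plug-in neg-selfentropy by default, or the
#' nearest-neighbour estimate), and computes Akaike weights and the
#' model-averaged location. All entropic quantities entering the projection
#' are put on the per-observation scale so that the system of squared
#' distances is dimensionally coherent.
#'
#' @param data A [count_dataset()] (or count matrix, or file path).
#' @param families Model set (default: all nine registered families).
#' @param fit_mode `"pooled"` or `"per_replicate"`.
#' @param d Embedding dimension.
#' @param nmds_mode `"ordinal"` or `"interval"`.
#' @param sgg_method `"plugin"` (empirical multinomial neg-selfentropy) or
#'   `"knn"` (nearest-neighbour estimator on dithered count rows; count
#'   vectors are integer-valued, so a fixed-seed uniform(-0.5, 0.5) dither
#'   per cell restores the continuity the estimator assumes).
#' @param knn Neighbour count for the `"knn"` method, or `"auto"`.
#' @param kl_factor 1 or 2 (Akaike's 2*KL convention).
#' @param seed Seed for the dither when `sgg_method = "knn"`.
#' @return An object of class `model_space` with fields `fits`, `table`
#'   (total scale), `table_po` (per-observation), `divergences`, `embedding`,
#'   `projection`, `aics`, `delta_aic`, `weights`, `average`.
#' @export
#' @examples
#' sim <- simulate_tides(n_tides = 20, pairs_per_tide = 100, seed = 7)
#' ms <- model_space(sim$data, families = c("Poisson", "NegBin", "ZIPoiss"))
#' ms$projection$h
model_space <- function(data, families = model_families(),
                        fit_mode = c("pooled", "per_replicate"), d = 2,
                        nmds_mode = c("ordinal", "interval"),
                        sgg_method = c("plugin", "knn"), knn = "auto",
                        kl_factor = 1, seed = 1L) {
  fit_mode <- match.arg(fit_mode); nmds_mode <- match.arg(nmds_mode)
  sgg_method <- match.arg(sgg_method)
  if (is.character(data) && length(data) == 1) data <- read_counts(data)
  data <- as_count_dataset(data)
  fits <- fit_model_set(data, families, fit_mode)
  table <- entropies_matcalc(data, fits)
  table_po <- per_observation(table)
  if (sgg_method == "knn") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    X <- data$counts + matrix(stats::runif(length(data$counts), -0.5, 0.5),
                              nrow(data$counts))
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    table_po$sgg <- weighted_knn_neg_selfentropy(X, k_nn = knn) / mean(data$n_j)
  }
  dv <- symmetrized_kl_matrix(table_po, kl_factor = kl_factor)
  emb <- nmds(dv, d = d, mode = nmds_mode)
  proj <- project_generating_process(emb, table_po$sgg, table_po$sgfi)
  aics <- vapply(fits, aic, numeric(1))
  w <- akaike_weights(aics)
  avg <- model_average_location(emb, w)
  structure(list(fits = fits, table = table, table_po = table_po,
                 divergences = dv, embedding = emb, projection = proj,
                 aics = aics, delta_aic = delta_aic(aics), weights = w,
                 average = avg),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat("Model-space analysis of", length(x$fits), "count models\n\n")
  ord <- order(x$aics)
  df <- data.frame(AIC = round(x$aics, 3), dAIC = round(x$delta_aic, 3),
                   weight = signif(x$weights, 4))[ord, ]
  print(df)
  cat("\nNMDS stress-1:", signif(x$embedding$stress, 4), "\n")
  cat("Projection M: (", paste(signif(x$projection$m_coords, 4),
                               collapse = ", "), "),  h =",
      signif(x$projection$h, 4), "\n")
  cat("Model average: (", paste(signif(x$average, 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Plot a model-space analysis
#'
#' Two-dimensional map of the embedded models with the projected generating
#' process M and the Akaike-weight model average.
#'
#' @param x A `model_space` object.
#' @param ... Passed to [plot()].
#' @export
plot.model_space <- function(x, ...) {
  co <- x$embedding$coords
  M <- x$projection$m_coords
  all_x <- c(co[, 1], M[1], x$average[1]); all_y <- c(co[, 2], M[2], x$average[2])
  plot(co, pch = 19, xlab = "y1", ylab = "y2", asp = 1,
       xlim = range(all_x) + c(-0.5, 0.5), ylim = range(all_y) + c(-0.5, 0.5),
       ...)
  graphics::text(co, labels = rownames(co), pos = 3, cex = 0.8)
  graphics::points(M[1], M[2], pch = 17, col = "blue", cex = 1.3)
  graphics::text(M[1], M[2], labels = "M", pos = 1, col = "blue")
  graphics::points(x$average[1], x$average[2], pch = 15, col = "red")
  graphics::text(x$average[1], x$average[2], labels = "wAIC", pos = 1,
                 col = "red")
  invisible(x)
}

#' Test whether a point lies in the convex hull of a planar configuration
#'
#' @param point Length-2 coordinate vector.
#' @param coords r x 2 coordinate matrix.
#' @param tol Boundary tolerance.
#' @return Logical.
#' @export
in_convex_hull <- function(point, coords, tol = 1e-9) {
  coords <- as.matrix(coords)
  hull <- grDevices::chull(coords)
  hp <- coords[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) return(FALSE)
  # point is inside iff it is on the same side of every hull edge
  signs <- vapply(seq_len(nh), function(i) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1 else i + 1, ]
    (b[1] - a[1]) * (point[2] - a[2]) - (b[2] - a[2]) * (point[1] - a[1])
  }, numeric(1))
  all(signs >= -tol) || all(signs <= tol)
}
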