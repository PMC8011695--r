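#' Construct a count dataset of replicate category frequencies
#'
#' Packages an N x k integer matrix of ordered category counts, one row per
#' replicate (e.g., one tide of horseshoe-crab survey data), where column i
#' holds the number of sampling units observed in category i - 1 and the last
#' column is the right-tail category ">= k - 1".
#'
#' @param counts Integer matrix or data frame, N replicates x k categories.
#' @param category_labels Optional character vector of length k; defaults to
#'   `"0", "1", ..., ">=k-1"`.
#' @return An object of class `count_dataset` with fields `counts`,
#'   `category_labels`, and `n_j` (per-replicate totals).
#' @export
#' @examples
#' count_dataset(rbind(c(112, 96, 101, 48, 22, 16)))
count_dataset <- function(counts, category_labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (ncol(counts) < 2) stop("need k >= 2 categories")
  n_j <- rowSums(counts)
  if (any(n_j < 1)) stop("every replicate must have total count >= 1 (row ",
                         paste(which(n_j < 1), collapse = ","), " empty)")
  k <- ncol(counts)
  if (is.null(category_labels))
    category_labels <- c(as.character(0:(k - 2)), paste0(">=", k - 1))
  if (length(category_labels) != k) stop("category_labels must have length k")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, category_labels)
  structure(list(counts = counts, category_labels = category_labels, n_j = n_j),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("Count dataset:", nrow(x$counts), "replicates x", ncol(x$counts),
      "categories (", format(sum(x$n_j), big.mark = ","), "observations )\n")
  utils::head(x$counts, 5) |> print()
  if (nrow(x$counts) > 5) cat("... (", nrow(x$counts) - 5, "more rows )\n")
  invisible(x)
}

as_count_dataset <- function(x) {
  if (inherits(x, "count_dataset")) x else count_dataset(x)
}
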