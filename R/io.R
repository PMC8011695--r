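# Delimited-text and JSON plumbing. Matrices are written with explicit row
# and column labels; numeric payloads at 12 significant digits.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a count dataset from delimited text
#'
#' One row per replicate, k integer columns, optional header of category
#' labels; comma- or tab-separated (auto-detected).
#'
#' @param path File path.
#' @return A [count_dataset()].
#' @export
read_counts <- function(path) {
  sep <- .detect_sep(path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  firstnum <- suppressWarnings(as.numeric(first))
  # a header is any non-numeric first row, or the printed-layout label row
  # "0 1 2 ... k-1"
  has_header <- any(is.na(firstnum)) ||
    identical(firstnum, as.numeric(seq_along(firstnum) - 1))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  count_dataset(m, category_labels = if (has_header) colnames(df))
}

#' Write a count dataset as CSV
#'
#' @param data A [count_dataset()].
#' @param path Output file.
#' @export
write_counts <- function(data, path) {
  data <- as_count_dataset(data)
  utils::write.csv(as.data.frame(data$counts), path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from delimited text
#'
#' Accepts the layout used for neg-crossentropy matrices: a header of model
#' names and one labelled row per model.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_labelled_matrix <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an entropy table as labelled delimited matrices plus JSON
#'
#' Produces `<stem>_sfifj.csv` and, when present, `<stem>_g.json` holding
#' `sgfi`, `sfig`, `sgg`, `n_list`, and the scale tag.
#'
#' @param table An `entropy_table`.
#' @param stem Output path stem.
#' @return The paths written, invisibly.
#' @export
write_entropy_table <- function(table, stem) {
  stopifnot(inherits(table, "entropy_table"))
  p1 <- paste0(stem, "_sfifj.csv")
  utils::write.csv(format(table$sfifj, digits = 12, trim = TRUE), p1)
  paths <- p1
  p2 <- paste0(stem, "_g.json")
  jsonlite::write_json(
    list(sgfi = table$sgfi, sfig = table$sfig, sgg = table$sgg,
         n_list = table$n_list, scale = table$scale, labels = table$labels),
    p2, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(c(paths, p2))
}

#' Read an entropy table written by [write_entropy_table()]
#'
#' @param stem Path stem used when writing.
#' @return An `entropy_table`.
#' @export
read_entropy_table <- function(stem) {
  sfifj <- read_labelled_matrix(paste0(stem, "_sfifj.csv"))
  g_path <- paste0(stem, "_g.json")
  if (file.exists(g_path)) {
    g <- jsonlite::read_json(g_path, simplifyVector = TRUE)
    entropy_table(sfifj, sgfi = stats::setNames(unlist(g$sgfi), rownames(sfifj)),
                  sfig = stats::setNames(unlist(g$sfig), rownames(sfifj)),
                  sgg = if (is.null(g$sgg)) NA_real_ else g$sgg,
                  n_list = unlist(g$n_list), scale = g$scale)
  } else entropy_table(sfifj)
}

#' Printed tables of the horseshoe-crab worked example
#'
#' Returns the published summary tables of the nine-model horseshoe-crab
#' satellite-count analysis, shipped as plain-text fixtures: the 9 x 9
#' estimated neg-crossentropy matrix among the fitted models, the AIC vector,
#' the estimated neg-crossentropies to and from the empirical generating
#' process, its estimated neg-selfentropy, and the first five simulated tide
#' count vectors.
#'
#' @return List with `sfifj` (entropy table), `aics`, `sgfi`, `sfig`, `sgg`,
#'   and `tides` (a [count_dataset()]).
#' @export
#' @examples
#' crab <- crab_example()
#' delta_aic(crab$aics)
crab_example <- function() {
  ext <- function(f) system.file("extdata", f, package = "modelspace",
                                 mustWork = TRUE)
  sfifj <- read_labelled_matrix(ext("crab_sfifj_hat.csv"))
  g <- jsonlite::read_json(ext("crab_g_hat.json"), simplifyVector = TRUE)
  aics_df <- utils::read.csv(ext("crab_aic.csv"))
  aics <- stats::setNames(aics_df$aic, aics_df$model)
  list(sfifj = entropy_table(sfifj, sgfi = stats::setNames(g$sgfi, rownames(sfifj)),
                             sfig = stats::setNames(g$sfig, rownames(sfifj)),
                             sgg = g$sgg),
       aics = aics,
       sgfi = stats::setNames(g$sgfi, rownames(sfifj)),
       sfig = stats::setNames(g$sfig, rownames(sfifj)),
       sgg = g$sgg,
       tides = read_counts(ext("crab_tides.csv")))
}
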