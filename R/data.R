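#' Construct an observed-data object
#'
#' Bundles a confounder matrix `W`, a binary exposure vector `X` and a
#' continuous outcome vector `Y` into the container used by all estimation
#' functions. No missing values are allowed anywhere: handling of incomplete
#' data is deliberately out of scope, and inputs with `NA`s are refused.
#'
#' @param W numeric matrix of confounders (columns `w1..wp`; binary columns
#'   are 0/1, categorical variables must already be indicator-coded).
#' @param X integer/numeric vector of 0/1 exposure indicators.
#' @param Y numeric outcome vector.
#' @return An object of class `observed_data`: a list with elements `W`, `X`,
#'   `Y` and `n`.
#' @examples
#' d <- observed_data(matrix(rnorm(20), 10, 2), rbinom(10, 1, 0.5), rnorm(10))
#' d$n
#' @export
observed_data <- function(W, X, Y) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  X <- as.vector(X)
  Y <- as.double(Y)
  n <- length(Y)
  if (nrow(W) != n || length(X) != n) {
    stop("W, X and Y must have the same number of records")
  }
  if (anyNA(W) || anyNA(X) || anyNA(Y)) {
    stop("missing values detected; drcfit does not handle incomplete data")
  }
  if (!all(X %in% c(0, 1))) {
    bad <- unique(X[!X %in% c(0, 1)])
    stop(
      "exposure must be coded 0/1; found value(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  structure(
    list(W = W, X = as.integer(X), Y = Y, n = n),
    class = "observed_data"
  )
}

#' Coerce a data frame (or CSV file) to an observed-data object
#'
#' Expects the column layout `y, x, w1..wp` (case-insensitive on `y`/`x`;
#' every remaining column is treated as a confounder).
#'
#' @param x a data frame, or the path to a CSV file with a header row.
#' @return An [observed_data()] object.
#' @export
as_observed_data <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.csv(x, check.names = FALSE)
  }
  if (inherits(x, "observed_data")) return(x)
  x <- as.data.frame(x)
  nms <- tolower(names(x))
  iy <- match("y", nms)
  ix <- match("x", nms)
  if (is.na(iy) || is.na(ix)) {
    stop("expected columns 'y' (outcome) and 'x' (exposure) in the data")
  }
  wcols <- setdiff(seq_along(x), c(iy, ix))
  if (length(wcols) == 0) stop("no confounder columns found")
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all columns must be numeric (indicator-code categorical variables)")
  }
  W <- as.matrix(x[wcols])
  observed_data(W, x[[ix]], x[[iy]])
}

#' @export
print.observed_data <- function(x, ...) {
  cat(
    "<observed_data> n =", x$n, ", p =", ncol(x$W),
    ", exposed =", sum(x$X), sprintf("(%.1f%%)\n", 100 * mean(x$X))
  )
  invisible(x)
}

#' @export
as.data.frame.observed_data <- function(x, ...) {
  data.frame(y = x$Y, x = x$X, x$W, check.names = FALSE)
}

#' Write an observed-data object to CSV (header `y, x, w1..wp`)
#'
#' @param data an [observed_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
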