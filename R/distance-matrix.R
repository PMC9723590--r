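#' Construct a labeled distance matrix
#'
#' A `distance_matrix` is a square numeric matrix with unique row/column
#' labels, symmetric to 1e-12, with a zero diagonal and non-negative
#' entries. Small asymmetries from floating-point round-off are
#' symmetrized away.
#'
#' @param values Square numeric matrix with matching dimnames, or a
#'   [stats::dist] object.
#' @return A matrix of class `distance_matrix`.
#' @export
distance_matrix <- function(values) {
  if (inherits(values, "dist")) values <- as.matrix(values)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values))) {
    stop("distance matrix must be labeled", call. = FALSE)
  }
  if (!identical(labels, colnames(values))) {
    stop("row and column labels differ", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  if (any(is.na(values))) stop("distance matrix contains NA/NaN", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal is not zero", call. = FALSE)
  if (any(values < -1e-12)) stop("negative distances", call. = FALSE)
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  diag(values) <- 0
  class(values) <- c("distance_matrix", class(values))
  values
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d objects\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

# plain matrix, validated
as_dm <- function(x) {
  m <- unclass(distance_matrix(unclass(x)))
  class(m) <- NULL
  m
}

#' Read / write a square tab-separated distance matrix
#'
#' The file carries labels in both the header row and the first column.
#'
#' @param path File path.
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param dm A [distance_matrix()].
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as_dm(dm)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align two distance matrices on an identical label set; errors on mismatch.
align_dms <- function(dm1, dm2) {
  m1 <- as_dm(dm1); m2 <- as_dm(dm2)
  d <- union(setdiff(rownames(m1), rownames(m2)), setdiff(rownames(m2), rownames(m1)))
  if (length(d)) stop("label mismatch between distance matrices: ",
                      paste(d, collapse = ", "), call. = FALSE)
  list(m1, m2[rownames(m1), rownames(m1)])
}

# Lower-triangle vectorization in a fixed label order.
dm_lower <- function(m) m[lower.tri(m)]
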