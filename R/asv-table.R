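#' Construct an ASV count table
#'
#' An `asv_table` is an integer matrix of sequence-read counts with samples
#' as rows and amplicon sequence variants (ASVs) as columns. Row and column
#' names are the unique sample and ASV identifiers.
#'
#' @param counts Numeric matrix of non-negative whole numbers with unique,
#'   non-empty row (sample) and column (ASV) names.
#' @return An object of class `asv_table` (a named integer matrix).
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' asv_table(m)
#' @export
asv_table <- function(counts) {
  counts <- as.matrix(counts)
  # a zero-extent margin legitimately has no labels (R stores them as NULL)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    stop("`counts` must have sample row names and ASV column names", call. = FALSE)
  }
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  dup_a <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_a)) {
    stop("duplicate ASV id(s): ", paste(dup_a, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(counts))) stop("counts contain NA", call. = FALSE)
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("count for sample '%s', ASV '%s' is not a non-negative integer",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("asv_table", class(counts))
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

# Validate/coerce to a plain counts matrix (samples x ASVs).
as_counts <- function(table) {
  x <- unclass(asv_table(unclass(table)))
  class(x) <- NULL
  x
}

#' Read an ASV count table from a tab-separated file
#'
#' Accepts either orientation of the usual QIIME-style export; the internal
#' canonical form is always samples-as-rows. A leading `#OTU ID`-style token
#' in the header is tolerated.
#'
#' @param path Path to a TSV file with a header row and identifiers in the
#'   first column.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(path, orientation = c("samples_as_rows", "features_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate identifier(s) in first column: ",
                        paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric cell(s) in count table body of ", path, call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "features_as_rows") m <- t(m)
  asv_table(m)
}

#' Write an ASV count table to a tab-separated file
#'
#' @param table An [asv_table()].
#' @param path Output file path.
#' @param orientation Orientation to write (see [read_asv_table()]).
#' @param id_header Header token for the identifier column.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path,
                            orientation = c("samples_as_rows", "features_as_rows"),
                            id_header = "sample_id") {
  orientation <- match.arg(orientation)
  m <- as_counts(table)
  if (orientation == "features_as_rows") {
    m <- t(m)
    if (identical(id_header, "sample_id")) id_header <- "#OTU ID"
  }
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `host_species`, `host_genus`,
#' `host_family`, `site`, `is_control`. Every non-control sample must carry
#' a non-empty species, genus and family.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of class `sample_info`.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  sample_info(df)
}

#' Validate a sample metadata table
#'
#' @param df A data frame with the columns listed in [read_sample_info()].
#' @return The validated data frame, with `is_control` coerced to logical.
#' @export
sample_info <- function(df) {
  req <- c("sample_id", "host_species", "host_genus", "host_family", "site", "is_control")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
                        call. = FALSE)
  if (is.character(df$is_control)) {
    df$is_control <- toupper(df$is_control) %in% c("TRUE", "T", "YES", "1")
  }
  df$is_control <- as.logical(df$is_control)
  tax <- c("host_species", "host_genus", "host_family")
  ok <- df$is_control |
    Reduce(`&`, lapply(df[tax], function(v) !is.na(v) & nzchar(as.character(v))))
  if (!all(ok)) {
    stop("non-control sample(s) with empty taxonomy: ",
         paste(df$sample_id[!ok], collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("sample_info", class(df)))
  df
}

#' Write sample metadata to a tab-separated file
#' @param meta A `sample_info` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove ASVs detected in PCR negative controls
#'
#' Every ASV with a non-zero count in any control sample is removed from all
#' samples, and the control samples themselves are dropped. This is the
#' blanket contaminant-removal rule used for PCR negatives; no
#' abundance-based decontamination is attempted.
#'
#' @param table An [asv_table()] containing both true samples and controls.
#' @param meta A `sample_info` data frame with controls flagged in
#'   `is_control`.
#' @return A filtered [asv_table()] without controls or control-borne ASVs.
#' @export
remove_control_asvs <- function(table, meta) {
  m <- as_counts(table)
  meta <- sample_info(as.data.frame(meta))
  controls <- intersect(meta$sample_id[meta$is_control], rownames(m))
  if (!length(controls)) {
    warning("no control samples present; table returned unchanged")
    return(asv_table(m))
  }
  contaminated <- colnames(m)[colSums(m[controls, , drop = FALSE] > 0) > 0]
  keep_samples <- setdiff(rownames(m), controls)
  keep_asvs <- setdiff(colnames(m), contaminated)
  if (!length(keep_asvs)) {
    warning("all ASVs were detected in controls; returning an empty feature set")
  }
  asv_table(m[keep_samples, keep_asvs, drop = FALSE])
}

#' Drop samples with too few reads
#'
#' Retains exactly the samples whose total read count is at least
#' `min_reads` (samples with fewer reads are removed).
#'
#' @param table An [asv_table()].
#' @param min_reads Minimum total reads per retained sample (default 2000).
#' @return A filtered [asv_table()] (possibly with zero samples).
#' @export
filter_min_depth <- function(table, min_reads = 2000) {
  assert_scalar_count(min_reads, "min_reads")
  m <- as_counts(table)
  asv_table(m[rowSums(m) >= min_reads, , drop = FALSE])
}

#' Rarefy a count table to even depth
#'
#' Each sample's reads are subsampled without replacement to exactly
#' `depth` reads (a multivariate-hypergeometric draw). Samples whose total
#' read count is below `depth` are dropped beforehand. The random draw for
#' each sample uses a seed derived from `seed` and the sample id, so the
#' result does not depend on sample order.
#'
#' @param table An [asv_table()].
#' @param depth Target reads per sample (default 2000).
#' @param seed Integer master seed.
#' @return A rarefied [asv_table()]; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = 2000, seed = 1) {
  assert_scalar_count(depth, "depth")
  m <- as_counts(filter_min_depth(table, depth))
  out <- m
  for (s in rownames(m)) {
    row <- m[s, ]
    if (sum(row) == depth) next
    idx <- rep.int(seq_along(row), row)
    set.seed(derive_seed(seed, paste0("rarefy:", s)))
    picked <- idx[sample.int(length(idx), depth)]
    out[s, ] <- tabulate(picked, nbins = length(row))
  }
  asv_table(out)
}
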