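#' Expression matrix with a unit tag
#'
#' A thin wrapper around a numeric features x samples matrix carrying the
#' expression unit (`"raw_count"`, `"FPKM"`, `"TPM"` or `"log2"`). Row names
#' are feature identifiers, column names are sample identifiers; both must be
#' present and unique. Values must be non-negative for count-like units.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique dimnames.
#' @param unit One of `"raw_count"`, `"FPKM"`, `"TPM"`, `"log2"`.
#' @return An `expr_matrix` object (a matrix with a `unit` attribute).
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expr_matrix(m, "raw_count")
expr_matrix <- function(values, unit = c("raw_count", "FPKM", "TPM", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires feature and sample names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (unit != "log2" && any(values < 0, na.rm = TRUE))
    stop("negative values not allowed for unit ", unit)
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("matrix carries no unit tag")
  u
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) out <- expr_matrix(out, expr_unit(x)) else out
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, unit = %s\n",
              nrow(x), ncol(x), expr_unit(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE],
                    4L), ...)
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk layout is a header line with `feature_id` followed by sample
#' identifiers, one feature per row. Round-trips are lossless for values
#' printed at full double precision.
#'
#' @param path File path.
#' @param unit Unit tag to attach on read.
#' @return `read_expr_matrix` returns an [expr_matrix]; `write_expr_matrix`
#'   returns `path` invisibly.
#' @export
read_expr_matrix <- function(path, unit = "raw_count") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "feature_id")
    stop("first column must be `feature_id`: ", path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  expr_matrix(m, unit)
}

#' @rdname read_expr_matrix
#' @param x An [expr_matrix].
#' @export
write_expr_matrix <- function(x, path) {
  dt <- data.table::data.table(feature_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a feature annotation table
#'
#' Columns: `feature_id`, `symbol`, `biotype` (coding / lncRNA / miRNA /
#' other), `length_bp`, logical flag columns `is_tf`, `is_histone`,
#' `is_membrane`, `is_car`, `is_cd19`, and `marker_of` (cell-type name or
#' `NA`).
#'
#' @param path File path.
#' @return A `data.frame` with one row per feature.
#' @export
read_annotation <- function(path) {
  an <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = "NA"))
  an$marker_of <- as.character(an$marker_of)
  validate_annotation(an)
  an
}

#' @rdname read_annotation
#' @param annotation Annotation `data.frame`.
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  data.table::fwrite(annotation, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

validate_annotation <- function(annotation) {
  need <- c("feature_id", "symbol", "biotype", "length_bp", "is_tf",
            "is_histone", "is_membrane", "is_car", "is_cd19", "marker_of")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$feature_id))
    stop("duplicate feature_id in annotation")
  if (any(annotation$length_bp < 1))
    stop("annotation length_bp must be >= 1")
  invisible(annotation)
}

# Lengths for the features of `x`, in matrix row order; errors name the
# first missing feature.
feature_lengths <- function(x, annotation) {
  idx <- match(rownames(x), annotation$feature_id)
  if (anyNA(idx)) {
    stop("feature missing from annotation: ",
         rownames(x)[which(is.na(idx))[1]])
  }
  len <- annotation$length_bp[idx]
  if (any(!is.finite(len) | len < 1))
    stop("invalid length for feature: ",
         rownames(x)[which(!is.finite(len) | len < 1)[1]])
  len
}
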