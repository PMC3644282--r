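#' @useDynLib ctxnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper sd setNames p.adjust cor
#' @importFrom utils read.delim write.table
NULL

# Internal encoding: DOWN = -1L, NOCHANGE = 0L, UP = +1L.
.TRI_STATES <- c(DOWN = -1L, NOCHANGE = 0L, UP = 1L)

.tri_to_int <- function(x) {
  up <- toupper(x)
  out <- .TRI_STATES[up]
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unknown state token(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected UP, DOWN or NOCHANGE)", call. = FALSE)
  }
  as.integer(out)
}

.int_to_tri <- function(x) {
  c("DOWN", "NOCHANGE", "UP")[x + 2L]
}

#' Trinary expression matrix
#'
#' Container for quantized expression data: rows are genes or gene sets,
#' columns are samples, and every entry is one of the three states
#' \code{UP}, \code{DOWN}, \code{NOCHANGE} (stored internally as
#' \code{+1, -1, 0}).
#'
#' @param values integer matrix in \code{\{-1, 0, 1\}} or character matrix
#'   of state tokens (case-insensitive).
#' @param row_ids,sample_ids unique identifiers; default taken from
#'   \code{dimnames(values)}.
#' @return An object of class \code{trinary_matrix}: an integer matrix with
#'   dimnames, entries in \code{\{-1, 0, 1\}}.
#' @export
trinary_matrix <- function(values, row_ids = rownames(values),
                           sample_ids = colnames(values)) {
  if (is.character(values)) {
    values <- matrix(.tri_to_int(values), nrow = nrow(values),
                     dimnames = dimnames(values))
  }
  storage.mode(values) <- "integer"
  if (is.null(row_ids) && nrow(values) == 0L) row_ids <- character()
  if (is.null(sample_ids) && ncol(values) == 0L) sample_ids <- character()
  if (is.null(row_ids) || is.null(sample_ids)) {
    stop("row_ids and sample_ids are required", call. = FALSE)
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifier(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(values %in% c(-1L, 0L, 1L))) {
    stop("trinary values must be -1, 0 or 1", call. = FALSE)
  }
  dimnames(values) <- list(as.character(row_ids), as.character(sample_ids))
  class(values) <- c("trinary_matrix", "matrix", "array")
  values
}

#' @export
print.trinary_matrix <- function(x, ...) {
  cat("trinary_matrix: ", nrow(x), " rows x ", ncol(x), " samples\n", sep = "")
  tab <- table(factor(.int_to_tri(as.integer(x)),
                      levels = c("UP", "DOWN", "NOCHANGE")))
  cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.trinary_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("trinary_matrix", "matrix", "array")
  out
}

#' Read an expression table
#'
#' Tab-separated table, first column row identifiers, header row of sample
#' identifiers. The \code{trinary} dialect validates the three-state
#' alphabet and returns a \code{\link{trinary_matrix}}; the
#' \code{continuous} dialect returns a numeric matrix for the quantization
#' functions.
#'
#' @param path file path.
#' @param dialect \code{"trinary"} or \code{"continuous"}.
#' @return \code{trinary_matrix} or numeric matrix.
#' @export
read_expression <- function(path, dialect = c("trinary", "continuous")) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(tab) < 2L) stop("expression table needs at least one sample column",
                           call. = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (dialect == "trinary") {
    bad <- matrix(!(toupper(m) %in% names(.TRI_STATES)), nrow(m))
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("unknown state token %s at row '%s', column '%s'",
                   dQuote(m[bad][1L]), ids[w[1L]], colnames(m)[w[2L]]),
           call. = FALSE)
    }
    return(trinary_matrix(matrix(.tri_to_int(m), nrow = nrow(m),
                                 dimnames = dimnames(m))))
  }
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  if (anyNA(num)) {
    w <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value %s at row '%s', column '%s'",
                 dQuote(m[is.na(num)][1L]), ids[w[1L]], colnames(m)[w[2L]]),
         call. = FALSE)
  }
  num
}

#' Write a trinary matrix as a tab-separated table
#'
#' Canonical upper-case state tokens; \code{read_expression} on the result
#' reproduces the matrix exactly.
#'
#' @param x a \code{trinary_matrix}.
#' @param path output file path.
#' @param id_column header for the identifier column.
#' @export
write_expression <- function(x, path, id_column = "id") {
  stopifnot(inherits(x, "trinary_matrix"))
  chars <- matrix(.int_to_tri(as.integer(x)), nrow = nrow(x),
                  dimnames = dimnames(x))
  df <- data.frame(rownames(chars), chars, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantize expression ratios by fold change
#'
#' Maps tumour/baseline expression ratios to trinary states with a
#' (default two-fold) threshold: ratio >= \code{fold} is \code{UP}, ratio
#' <= \code{1/fold} is \code{DOWN}, otherwise \code{NOCHANGE}. Boundaries
#' are inclusive: a ratio of exactly \code{fold} is called \code{UP}.
#'
#' @param expr numeric matrix of strictly positive ratios.
#' @param fold positive fold-change threshold, default 2.
#' @return \code{trinary_matrix} of the same dimensions.
#' @export
quantize_log_ratio <- function(expr, fold = 2) {
  stopifnot(is.numeric(expr), is.matrix(expr), fold > 0)
  if (any(!is.finite(expr)) || any(expr <= 0)) {
    stop("ratios must be finite and strictly positive", call. = FALSE)
  }
  q <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  q[expr >= fold] <- 1L
  q[expr <= 1 / fold] <- -1L
  trinary_matrix(q)
}

#' Quantize expression by z-score against reference samples
#'
#' Per gene, z-scores are computed against the mean and standard deviation
#' of the reference samples; \code{z > sd_threshold} is \code{UP},
#' \code{z < -sd_threshold} is \code{DOWN}, otherwise \code{NOCHANGE}
#' (boundary exclusive: |z| exactly at the threshold is \code{NOCHANGE}).
#' Genes with zero reference standard deviation are set to \code{NOCHANGE}
#' everywhere, with a warning.
#'
#' @param expr numeric matrix, genes x samples.
#' @param reference_samples column identifiers of the reference samples
#'   (at least two).
#' @param sd_threshold positive threshold in reference-SD units, default 1.
#' @return \code{trinary_matrix} over all columns of \code{expr}.
#' @export
quantize_zscore <- function(expr, reference_samples, sd_threshold = 1) {
  stopifnot(is.numeric(expr), is.matrix(expr), sd_threshold > 0)
  missing_ref <- setdiff(reference_samples, colnames(expr))
  if (length(missing_ref)) {
    stop("reference sample(s) not in matrix: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  if (length(reference_samples) < 2L) {
    stop("need at least two reference samples", call. = FALSE)
  }
  ref <- expr[, reference_samples, drop = FALSE]
  if (any(!is.finite(ref))) stop("non-finite reference values", call. = FALSE)
  mu <- rowMeans(ref)
  sigma <- apply(ref, 1L, sd)
  flat <- sigma == 0
  if (any(flat)) {
    warning("zero reference SD for ", sum(flat),
            " gene(s); set to NOCHANGE: ",
            paste(utils::head(rownames(expr)[flat], 5L), collapse = ", "))
    sigma[flat] <- Inf  # z = 0 everywhere -> NOCHANGE
  }
  z <- (expr - mu) / sigma
  q <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  q[z > sd_threshold] <- 1L
  q[z < -sd_threshold] <- -1L
  trinary_matrix(q)
}
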