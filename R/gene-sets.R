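# Gene set collections (GMT) and sample condition tables.

#' Gene set collection
#'
#' Named sets of gene identifiers, optionally carrying a description and a
#' direction tag (over-/under-expressed in the set's defining context). A
#' gene may belong to multiple sets.
#'
#' @param sets named list of character vectors (set name -> members).
#' @param description optional named character vector of descriptions.
#' @param direction optional named character vector, e.g. \code{"up"} /
#'   \code{"down"}, one entry per set.
#' @return An object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, description = NULL, direction = NULL) {
  stopifnot(is.list(sets))
  nm <- names(sets)
  if (length(sets) && (is.null(nm) || any(nm == ""))) {
    stop("all sets must be named", call. = FALSE)
  }
  nm <- nm %||% character()
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("empty set(s): ",
         paste(nm[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets,
                 description = description %||% setNames(rep("", length(nm)), nm),
                 direction = direction),
            class = "gene_set_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x$sets), " sets, ",
      length(unique(unlist(x$sets))), " distinct genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
`[[.gene_set_collection` <- function(x, i) x$sets[[i]]

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#' Duplicated members within a line are stored once (with a warning);
#' duplicated set names are an error.
#'
#' @param path GMT file path.
#' @return \code{gene_set_collection}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1L],
         " has fewer than 3 tab-separated fields (set '",
         fields[[which(short)[1L]]][1L], "' has no members)", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  desc <- setNames(vapply(fields, `[[`, "", 2L), nm)
  members <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(members, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning("duplicated members collapsed in set(s): ",
            paste(nm[dup], collapse = ", "))
  }
  gene_set_collection(setNames(members, nm), description = desc)
}

#' Write gene sets in GMT format
#' @param x \code{gene_set_collection}.
#' @param path output file path.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$description[[nm]] %||% "", x$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Sample condition table
#'
#' Maps condition labels to sample subsets. Conditions may overlap (the
#' same samples can carry a subtype label, a mutation label and an age
#' label at once); each condition must be a proper non-empty subset of the
#' sample universe.
#'
#' @param assignments named list: condition label -> character vector of
#'   sample identifiers.
#' @param universe character vector of all sample identifiers.
#' @return An object of class \code{condition_table}.
#' @export
condition_table <- function(assignments, universe) {
  stopifnot(is.list(assignments))
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("duplicate samples in universe",
                                    call. = FALSE)
  nm <- names(assignments)
  if (is.null(nm) || any(nm == "")) stop("all conditions must be named",
                                         call. = FALSE)
  assignments <- lapply(assignments, function(s) unique(as.character(s)))
  for (k in nm) {
    s <- assignments[[k]]
    extra <- setdiff(s, universe)
    if (length(extra)) {
      stop("condition '", k, "' has sample(s) outside the universe: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (length(s) < 1L || length(s) >= length(universe)) {
      stop("condition '", k,
           "' must cover at least one and fewer than all samples",
           call. = FALSE)
    }
  }
  structure(list(assignments = assignments, universe = universe),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat("condition_table: ", length(x$assignments), " conditions over ",
      length(x$universe), " samples\n", sep = "")
  for (k in names(x$assignments)) {
    cat("  ", k, ": ", length(x$assignments[[k]]), " samples\n", sep = "")
  }
  invisible(x)
}

#' Read a sample condition table
#'
#' Tab-separated file with columns \code{sample} and \code{condition}, one
#' row per sample-condition pair. The universe defaults to all samples seen
#' in the file; pass \code{universe} explicitly when some samples carry no
#' condition label.
#'
#' @param path file path.
#' @param universe optional full sample list.
#' @return \code{condition_table}.
#' @export
read_conditions <- function(path, universe = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  need <- c("sample", "condition")
  if (!all(need %in% colnames(tab))) {
    stop("condition file needs columns 'sample' and 'condition'",
         call. = FALSE)
  }
  universe <- universe %||% unique(tab$sample)
  condition_table(split(tab$sample, tab$condition), universe)
}

#' Write a sample condition table
#' @param x \code{condition_table}.
#' @param path output file path.
#' @export
write_conditions <- function(x, path) {
  stopifnot(inherits(x, "condition_table"))
  df <- data.frame(
    sample = unlist(x$assignments, use.names = FALSE),
    condition = rep(names(x$assignments), lengths(x$assignments)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
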