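# Gene-set comparison and over-representation utilities against
# user-supplied annotation collections.

#' Jaccard similarity matrix between gene sets
#'
#' Entry (i, j) is |intersection| / |union| of the two member lists;
#' the diagonal is 1.
#'
#' @param sets \code{gene_set_collection} (at least one set).
#' @param sets_b optional second collection; when given, the matrix is
#'   rectangular (rows = \code{sets}, columns = \code{sets_b}).
#' @return numeric matrix in [0, 1].
#' @export
jaccard_matrix <- function(sets, sets_b = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"), length(sets) >= 1L)
  a <- sets$sets
  b <- if (is.null(sets_b)) a else sets_b$sets
  genes <- unique(c(unlist(a), unlist(b)))
  ma <- vapply(a, function(g) genes %in% g, logical(length(genes)))
  mb <- vapply(b, function(g) genes %in% g, logical(length(genes)))
  inter <- crossprod(ma, mb)
  uni <- outer(colSums(ma), colSums(mb), `+`) - inter
  out <- inter / uni
  dimnames(out) <- list(names(a), names(b))
  out
}

#' Hypergeometric over-representation of a query gene set
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' the observed overlap: population = universe, successes = term members in
#' the universe, draws = |query|. Benjamini-Hochberg correction is applied
#' across all terms of the collection when \code{fdr} is set; results are
#' sorted by (corrected) p then term name.
#'
#' @param query character vector of gene identifiers (subset of
#'   \code{universe}), or a single set name into \code{annotations}.
#' @param annotations \code{gene_set_collection} of annotation terms
#'   (GO/MSigDB-style GMT export).
#' @param universe character vector of all genes under consideration.
#' @param p_theta significance threshold used for the \code{significant}
#'   flag, default 0.01.
#' @param fdr apply Benjamini-Hochberg correction (default \code{TRUE});
#'   the \code{significant} flag then uses \code{fdr_p}.
#' @return data.frame with columns \code{term}, \code{overlap},
#'   \code{query_size}, \code{term_size}, \code{universe_size}, \code{p},
#'   \code{fdr_p}, \code{significant}.
#' @export
enrich <- function(query, annotations, universe, p_theta = 0.01,
                   fdr = TRUE) {
  stopifnot(inherits(annotations, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 10L), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotations$sets), function(term) {
    members <- intersect(annotations$sets[[term]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (K == 0L) 1 else .hyper_tail(k, K, N, n)
    data.frame(term = term, overlap = k, query_size = n, term_size = K,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- p.adjust(out$p, method = "BH")
  out$significant <- if (fdr) out$fdr_p < p_theta else out$p < p_theta
  key <- if (fdr) out$fdr_p else out$p
  out <- out[order(key, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
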