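# STEP II: collapse each gene set's member states into one representative
# UP/DOWN/NOCHANGE value per sample.

#' Summarization parameters
#'
#' @param r majority fraction in (0, 1], default 0.5. A direction wins only
#'   when strictly more than \code{r * |set|} members show it.
#' @param p_threshold hypergeometric significance level in (0, 1),
#'   default 0.05.
#' @return list of class \code{summary_params}.
#' @export
summary_params <- function(r = 0.5, p_threshold = 0.05) {
  stopifnot(r > 0, r <= 1, p_threshold > 0, p_threshold < 1)
  structure(list(r = r, p_threshold = p_threshold), class = "summary_params")
}

# Upper-tail hypergeometric P(X >= k): k observed direction-members among n
# draws from a population of N genes of which K show the direction.
.hyper_tail <- function(k, K, N, n) {
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Summarize one gene set for one sample
#'
#' Returns \code{UP} when strictly more than \code{r * |set|} member genes
#' are UP in the sample and the hypergeometric upper-tail probability of
#' drawing that many UP genes from the background is below
#' \code{p_threshold}; symmetrically for \code{DOWN}; otherwise
#' \code{NOCHANGE}. Both clauses are conjunctive: a strict majority without
#' significance is \code{NOCHANGE}. The background universe is all rows of
#' \code{background}.
#'
#' @param genes_trinary \code{trinary_matrix} restricted to the set's
#'   member genes (or the full matrix plus \code{members}).
#' @param background \code{trinary_matrix} over all genes.
#' @param sample sample identifier, present in both matrices.
#' @param params \code{\link{summary_params}}.
#' @param members optional character vector naming the member genes; by
#'   default all rows of \code{genes_trinary}.
#' @return one of \code{"UP"}, \code{"DOWN"}, \code{"NOCHANGE"}.
#' @export
summarize_gene_set <- function(genes_trinary, background, sample,
                               params = summary_params(), members = NULL) {
  stopifnot(inherits(background, "trinary_matrix"))
  members <- members %||% rownames(genes_trinary)
  missing_g <- setdiff(members, rownames(background))
  if (length(missing_g)) {
    stop("gene(s) absent from background: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  if (!sample %in% colnames(background)) {
    stop("sample '", sample, "' not in background", call. = FALSE)
  }
  states <- genes_trinary[members, sample]
  bg <- background[, sample]
  .summ_one(sum(states == 1L), sum(states == -1L), length(members),
            sum(bg == 1L), sum(bg == -1L), nrow(background), params)
}

.summ_one <- function(n_up, n_down, m, K_up, K_down, N, params) {
  need <- params$r * m
  if (n_up > need &&
      .hyper_tail(n_up, K_up, N, m) < params$p_threshold) return("UP")
  if (n_down > need &&
      .hyper_tail(n_down, K_down, N, m) < params$p_threshold) return("DOWN")
  "NOCHANGE"
}

#' Summarize all gene sets across all samples
#'
#' Applies \code{\link{summarize_gene_set}} to every (set, sample) pair;
#' rows follow collection order. The result is the gene set expression
#' matrix fed to \code{\link{consensus}}.
#'
#' @param genes_trinary \code{trinary_matrix} over genes.
#' @param sets \code{\link{gene_set_collection}}; every member must be a
#'   row of \code{genes_trinary}.
#' @param params \code{\link{summary_params}}.
#' @param drop_flat drop sets that are \code{NOCHANGE} in every sample
#'   (default \code{FALSE}: all sets kept).
#' @return \code{trinary_matrix}, sets x samples.
#' @export
summarize_all <- function(genes_trinary, sets, params = summary_params(),
                          drop_flat = FALSE) {
  stopifnot(inherits(genes_trinary, "trinary_matrix"),
            inherits(sets, "gene_set_collection"))
  missing_g <- setdiff(unique(unlist(sets$sets)), rownames(genes_trinary))
  if (length(missing_g)) {
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing_g, 10L), collapse = ", "), call. = FALSE)
  }
  n_samp <- ncol(genes_trinary)
  K_up <- colSums(genes_trinary == 1L)
  K_down <- colSums(genes_trinary == -1L)
  N <- nrow(genes_trinary)
  out <- matrix(0L, length(sets$sets), n_samp,
                dimnames = list(names(sets$sets), colnames(genes_trinary)))
  for (i in seq_along(sets$sets)) {
    sub <- genes_trinary[sets$sets[[i]], , drop = FALSE]
    m <- length(sets$sets[[i]])
    n_up <- colSums(sub == 1L)
    n_down <- colSums(sub == -1L)
    for (k in seq_len(n_samp)) {
      v <- .summ_one(n_up[k], n_down[k], m, K_up[k], K_down[k], N, params)
      out[i, k] <- .TRI_STATES[[v]]
    }
  }
  res <- trinary_matrix(out)
  if (drop_flat) {
    keep <- rowSums(res != 0L) > 0L
    res <- res[keep, , drop = FALSE]
  }
  res
}
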