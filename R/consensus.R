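# STEP III: dependency likelihoods d_ij as undirected edge frequencies over
# R independent stochastic structure searches, thresholded at d_theta.

#' Structure-search configuration
#'
#' @param R number of independent search runs whose edge frequency defines
#'   the dependency likelihood; default 1024.
#' @param max_parents parent limit per node in each search, default 5.
#' @param ess equivalent sample size of the BDeu score's Dirichlet prior,
#'   default 1.
#' @param restarts_per_run random restarts within one run (best local
#'   optimum kept), default 1; run-to-run variability comes from the random
#'   initial DAG.
#' @param base_seed integer seed from which all per-run seeds derive.
#' @return list of class \code{search_config}.
#' @export
search_config <- function(R = 1024L, max_parents = 5L, ess = 1,
                          restarts_per_run = 1L, base_seed = 1L) {
  stopifnot(R >= 1L, max_parents >= 1L, ess > 0, restarts_per_run >= 1L)
  structure(list(R = as.integer(R), max_parents = as.integer(max_parents),
                 ess = ess, restarts_per_run = as.integer(restarts_per_run),
                 base_seed = as.numeric(base_seed)),
            class = "search_config")
}

# Map a trinary (or general discrete) matrix to 0-based integer codes plus
# arities for the C++ scorer. Rows constant across all samples carry no
# information for structure search; they are excluded here and reported
# with d = 0 to all partners by the callers.
.encode_discrete <- function(data) {
  stopifnot(is.matrix(data))
  codes <- data + 1L            # -1/0/1 -> 0/1/2
  storage.mode(codes) <- "integer"
  arity <- rep(3L, nrow(data))
  list(codes = codes, arity = arity)
}

.nonconstant_rows <- function(data) {
  apply(data, 1L, function(r) length(unique(r)) > 1L)
}

#' BDeu family score
#'
#' Log marginal likelihood of one child variable given a parent set, under
#' a Dirichlet prior of total mass \code{ess} spread uniformly over the
#' child's states within each parent configuration (Bayesian-Dirichlet
#' equivalent uniform score). Deterministic; used as the objective of
#' \code{\link{search_structure}}.
#'
#' @param data \code{trinary_matrix} (variables x samples).
#' @param child row identifier of the child variable.
#' @param parents character vector of parent row identifiers (may be
#'   empty).
#' @param ess equivalent sample size, default 1.
#' @return log score (scalar).
#' @export
family_score <- function(data, child, parents = character(), ess = 1) {
  stopifnot(inherits(data, "trinary_matrix") || is.matrix(data))
  ids <- rownames(data)
  if (!child %in% ids) stop("unknown child: ", child, call. = FALSE)
  bad <- setdiff(parents, ids)
  if (length(bad)) stop("unknown parent(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (child %in% parents) stop("child cannot be its own parent",
                               call. = FALSE)
  enc <- .encode_discrete(unclass(data))
  .family_score_cpp(enc$codes, enc$arity, match(child, ids) - 1L,
                    match(parents, ids) - 1L, ess)
}

#' Single stochastic structure search
#'
#' Greedy hill climbing over add/delete/reverse edge moves from a seeded
#' random acyclic start, respecting \code{max_parents}. Only strictly
#' improving moves are taken (a score tie between adding an edge and not
#' adding it resolves to not adding); equal best moves resolve by a fixed
#' lexicographic move order. Deterministic given (data, config, seed).
#'
#' @param data \code{trinary_matrix}.
#' @param config \code{\link{search_config}}.
#' @param seed run seed (defaults to \code{config$base_seed}).
#' @return list of class \code{dag_structure} with \code{node_ids} and
#'   \code{parents} (named list of parent id vectors).
#' @export
search_structure <- function(data, config = search_config(),
                             seed = config$base_seed) {
  stopifnot(nrow(data) >= 2L, ncol(data) >= 1L)
  ids <- rownames(data)
  keep <- .nonconstant_rows(data)
  adj_full <- matrix(0L, nrow(data), nrow(data), dimnames = list(ids, ids))
  if (sum(keep) >= 2L) {
    enc <- .encode_discrete(unclass(data)[keep, , drop = FALSE])
    adj <- .search_structure_cpp(enc$codes, enc$arity, config$max_parents,
                                 config$restarts_per_run, config$ess,
                                 as.numeric(seed))
    adj_full[keep, keep] <- adj
  }
  parents <- lapply(seq_along(ids), function(j) ids[adj_full[, j] == 1L])
  structure(list(node_ids = ids, parents = setNames(parents, ids)),
            class = "dag_structure")
}

#' Consensus dependency-likelihood network
#'
#' Runs \code{R} independent structure searches (per-run seeds derived from
#' \code{base_seed} and the run index) and reports, for every pair of
#' variables, the fraction of runs whose learned DAG contains an edge
#' between them in either direction. Edge direction is ignored throughout.
#'
#' @param data \code{trinary_matrix} (gene sets x samples).
#' @param config \code{\link{search_config}}.
#' @param d_theta edge-call threshold stored on the network, default 0.5.
#' @return object of class \code{consensus_network}: list with
#'   \code{node_ids}, symmetric matrix \code{d}, \code{R}, \code{d_theta}.
#' @export
consensus <- function(data, config = search_config(), d_theta = 0.5) {
  stopifnot(nrow(data) >= 2L, ncol(data) >= 1L)
  ids <- rownames(data)
  keep <- .nonconstant_rows(data)
  d <- matrix(0, nrow(data), nrow(data), dimnames = list(ids, ids))
  if (sum(keep) >= 2L) {
    enc <- .encode_discrete(unclass(data)[keep, , drop = FALSE])
    dk <- .consensus_cpp(enc$codes, enc$arity, config$R, config$max_parents,
                         config$restarts_per_run, config$ess,
                         as.numeric(config$base_seed), 0L)
    d[keep, keep] <- dk
  }
  diag(d) <- 0
  consensus_network(d, R = config$R, d_theta = d_theta)
}

#' Construct a consensus network from a dependency matrix
#'
#' @param d symmetric numeric matrix of dependency likelihoods in [0, 1]
#'   with row/column names.
#' @param R number of runs behind the frequencies.
#' @param d_theta edge-call threshold.
#' @return \code{consensus_network}.
#' @export
consensus_network <- function(d, R, d_theta = 0.5) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (any(d < 0 | d > 1)) stop("dependency likelihoods must lie in [0, 1]",
                               call. = FALSE)
  if (!isTRUE(all.equal(d, t(d)))) stop("dependency matrix must be symmetric",
                                        call. = FALSE)
  structure(list(node_ids = rownames(d), d = d, R = as.integer(R),
                 d_theta = d_theta),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  ne <- nrow(call_edges(x))
  cat("consensus_network: ", length(x$node_ids), " nodes, R = ", x$R,
      ", d_theta = ", x$d_theta, ", ", ne, " called edge(s)\n", sep = "")
  invisible(x)
}

#' Called edges of a consensus network
#'
#' Pairs with dependency likelihood strictly larger than \code{d_theta}
#' (a likelihood exactly at the threshold is not called), sorted
#' lexicographically with \code{set_i < set_j}.
#'
#' @param net \code{consensus_network}.
#' @param d_theta threshold override; defaults to the network's.
#' @return data.frame with columns \code{set_i}, \code{set_j}, \code{d}.
#' @export
call_edges <- function(net, d_theta = net$d_theta) {
  stopifnot(inherits(net, "consensus_network"))
  d <- net$d
  idx <- which(upper.tri(d) & d > d_theta, arr.ind = TRUE)
  out <- data.frame(set_i = rownames(d)[idx[, 1L]],
                    set_j = colnames(d)[idx[, 2L]],
                    d = d[idx], stringsAsFactors = FALSE)
  # canonical unordered pair: lexicographic within the pair, then sort rows
  swap <- out$set_i > out$set_j
  tmp <- out$set_i[swap]; out$set_i[swap] <- out$set_j[swap]
  out$set_j[swap] <- tmp
  out[order(out$set_i, out$set_j), , drop = FALSE]
}
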