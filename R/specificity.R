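# STEP IV: leave-condition-out dependency-likelihood ratio gamma with a
# permutation null, and the generic / condition-centric classification of
# gene sets.

#' Specificity-test parameters
#'
#' @param gamma_theta ratio threshold above which an edge's dependency is
#'   considered condition-driven; default 2 (two-fold or higher increase of
#'   the dependency likelihood contributed by the condition's samples).
#' @param p_theta permutation significance level, default 0.05.
#' @param M permutation count, default 100.
#' @param R_perm consensus runs per leave-out / permutation likelihood;
#'   defaults to the search configuration's \code{R}.
#' @return list of class \code{specificity_params}.
#' @export
specificity_params <- function(gamma_theta = 2, p_theta = 0.05, M = 100L,
                               R_perm = NULL) {
  stopifnot(gamma_theta > 0, p_theta > 0, p_theta < 1, M >= 1L)
  structure(list(gamma_theta = gamma_theta, p_theta = p_theta,
                 M = as.integer(M),
                 R_perm = if (is.null(R_perm)) NULL else as.integer(R_perm)),
            class = "specificity_params")
}

#' Condition-effect ratio
#'
#' Ratio of the dependency likelihood over all samples to the likelihood
#' after removing a condition's samples. A zero leave-out likelihood is
#' floored at \code{1/(R + 1)} (one pseudo-count at the frequency
#' resolution) so the ratio stays finite and permutation comparisons remain
#' well defined.
#'
#' @param d_all dependency likelihood from all samples, in [0, 1].
#' @param d_without dependency likelihood without the condition's samples.
#' @param R number of runs behind \code{d_without}.
#' @return positive finite ratio.
#' @export
gamma_ratio <- function(d_all, d_without, R) {
  stopifnot(all(d_all >= 0 & d_all <= 1), all(d_without >= 0 & d_without <= 1),
            R >= 1)
  d_all / pmax(d_without, 1 / (R + 1))
}

# Deterministic numeric seed from a base seed and one or more labels
# (polynomial string hash mod 2^31 - 1); feeds both the C++ consensus seeds
# and local R RNG scopes for permutation draws.
.derive_seed <- function(base, ...) {
  h <- as.numeric(base) %% 2147483647
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0("#", as.character(lab)))) {
      h <- (h * 131 + code) %% 2147483647
    }
  }
  h
}

# Evaluate an expression with a temporary R RNG seed, restoring the caller's
# RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shared engine: for one condition, compute d_without for every called
# edge, the observed gamma, and the M-permutation null. Permutation sample
# subsets are drawn once per condition and shared across edges, so a
# single-edge test and test_all() agree exactly for the same seed.
.specificity_condition <- function(data, edges, cond, s_cond, net, params,
                                   config, seed) {
  samples <- colnames(data)
  s_cond <- intersect(s_cond, samples)
  rest <- setdiff(samples, s_cond)
  if (length(s_cond) < 1L) {
    stop("condition '", cond, "' has no samples in the data", call. = FALSE)
  }
  if (length(rest) == 0L) {
    stop("leave-out set empty: condition '", cond,
         "' covers all samples", call. = FALSE)
  }
  if (length(rest) < 3L) {
    stop("fewer than 3 samples remain after removing condition '", cond, "'",
         call. = FALSE)
  }
  R_perm <- params$R_perm %||% config$R
  M <- params$M
  cfg_wo <- config
  cfg_wo$R <- R_perm

  pair_d <- function(net_wo) {
    mapply(function(i, j) net_wo$d[i, j], edges$set_i, edges$set_j)
  }

  cfg_wo$base_seed <- .derive_seed(seed, cond, "without")
  d_without <- pair_d(consensus(data[, rest, drop = FALSE], cfg_wo,
                                d_theta = net$d_theta))
  g_obs <- gamma_ratio(edges$d, d_without, R_perm)

  perms <- .with_seed(.derive_seed(seed, cond, "draws"), {
    lapply(seq_len(M), function(m) sample(samples, length(s_cond)))
  })
  H <- numeric(nrow(edges))
  for (m in seq_len(M)) {
    cfg_wo$base_seed <- .derive_seed(seed, cond, "perm", m)
    keep <- setdiff(samples, perms[[m]])
    d_m <- pair_d(consensus(data[, keep, drop = FALSE], cfg_wo,
                            d_theta = net$d_theta))
    g_m <- gamma_ratio(edges$d, d_m, R_perm)
    H <- H + (g_m >= g_obs)
  }
  p <- H / M
  data.frame(set_i = edges$set_i, set_j = edges$set_j, condition = cond,
             d_all = edges$d, d_without = d_without, gamma = g_obs,
             H = as.integer(H), M = M, p = p,
             specific = g_obs > params$gamma_theta & p < params$p_theta,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation test of one edge's specificity to one condition
#'
#' Computes the dependency likelihood of the edge without the condition's
#' samples (a fresh consensus over \code{R_perm} runs), the observed
#' condition-effect ratio, and its permutation significance: \code{M}
#' random sample subsets of the condition's size are left out in turn and
#' \code{H} counts permutations whose ratio meets or exceeds the observed
#' one (ties count towards \code{H}); \code{p = H/M} exactly. The edge is
#' specific when \code{gamma > gamma_theta} and \code{p < p_theta}.
#'
#' @param data \code{trinary_matrix} over all samples.
#' @param edge character vector of two node identifiers; must be a called
#'   edge of \code{net}.
#' @param condition condition label in \code{conditions}, or a list
#'   \code{list(label =, samples =)}.
#' @param net \code{consensus_network} built from \code{data}.
#' @param conditions \code{condition_table} (needed when \code{condition}
#'   is a label).
#' @param params \code{\link{specificity_params}}.
#' @param config \code{\link{search_config}} used for \code{net}.
#' @param seed integer seed; permutation draws derive from it and the
#'   condition label.
#' @return one-row data.frame: \code{set_i, set_j, condition, d_all,
#'   d_without, gamma, H, M, p, specific}.
#' @export
specificity_test <- function(data, edge, condition, net, conditions = NULL,
                             params = specificity_params(),
                             config = search_config(), seed = 1L) {
  stopifnot(inherits(net, "consensus_network"), length(edge) == 2L)
  edge <- sort(as.character(edge))
  called <- call_edges(net)
  row <- called[called$set_i == edge[1L] & called$set_j == edge[2L], ,
                drop = FALSE]
  if (nrow(row) == 0L) {
    stop("edge ", edge[1L], " -- ", edge[2L],
         " is not called in the network (d <= d_theta)", call. = FALSE)
  }
  if (is.list(condition)) {
    cond <- condition$label
    s_cond <- condition$samples
  } else {
    stopifnot(inherits(conditions, "condition_table"))
    cond <- as.character(condition)
    if (!cond %in% names(conditions$assignments)) {
      stop("unknown condition: ", cond, call. = FALSE)
    }
    s_cond <- conditions$assignments[[cond]]
  }
  .specificity_condition(data, row, cond, s_cond, net, params, config, seed)
}

#' Test an explicit list of edges against conditions
#'
#' Like \code{\link{test_all}} but for a caller-supplied edge list (for
#' example the regulations of a mechanistic model under validation),
#' whether or not each edge is called at the network's threshold: the
#' condition-effect ratio and its permutation null are well defined for
#' any pair with a recorded dependency likelihood.
#'
#' @param data \code{trinary_matrix} over all samples.
#' @param edges data.frame with columns \code{set_i}, \code{set_j} (node
#'   identifiers of \code{net}).
#' @param net \code{consensus_network} built from \code{data}.
#' @param conditions \code{condition_table}.
#' @param params \code{\link{specificity_params}}.
#' @param config \code{\link{search_config}}.
#' @param seed integer seed.
#' @return data.frame as in \code{\link{test_all}}.
#' @export
test_edges <- function(data, edges, net, conditions,
                       params = specificity_params(),
                       config = search_config(), seed = 1L) {
  stopifnot(inherits(net, "consensus_network"),
            inherits(conditions, "condition_table"))
  edges <- data.frame(set_i = pmin(edges$set_i, edges$set_j),
                      set_j = pmax(edges$set_i, edges$set_j),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(c(edges$set_i, edges$set_j)), net$node_ids)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  edges$d <- mapply(function(i, j) net$d[i, j], edges$set_i, edges$set_j)
  edges <- edges[order(edges$set_i, edges$set_j), , drop = FALSE]
  res <- lapply(names(conditions$assignments), function(cond) {
    .specificity_condition(data, edges, cond,
                           conditions$assignments[[cond]], net, params,
                           config, seed)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Test every called edge against every condition
#'
#' One \code{\link{specificity_test}} result per (called edge, condition)
#' pair. Leave-out and permutation consensus runs are seeded per condition,
#' so results are deterministic given \code{seed} and agree with
#' single-edge calls.
#'
#' @param data \code{trinary_matrix} over all samples.
#' @param net \code{consensus_network} built from \code{data}.
#' @param conditions \code{condition_table}.
#' @param params \code{\link{specificity_params}}.
#' @param config \code{\link{search_config}}.
#' @param seed integer seed.
#' @param bh also report Benjamini-Hochberg adjusted p-values in a
#'   \code{p_bh} column (the specificity call itself stays on raw p).
#' @return data.frame, one row per (edge, condition).
#' @export
test_all <- function(data, net, conditions, params = specificity_params(),
                     config = search_config(), seed = 1L, bh = FALSE) {
  stopifnot(inherits(net, "consensus_network"),
            inherits(conditions, "condition_table"))
  edges <- call_edges(net)
  if (nrow(edges) == 0L) {
    out <- data.frame(set_i = character(), set_j = character(),
                      condition = character(), d_all = numeric(),
                      d_without = numeric(), gamma = numeric(),
                      H = integer(), M = integer(), p = numeric(),
                      specific = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  res <- lapply(names(conditions$assignments), function(cond) {
    .specificity_condition(data, edges, cond,
                           conditions$assignments[[cond]], net, params,
                           config, seed)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (bh) out$p_bh <- p.adjust(out$p, method = "BH")
  out
}

#' Classify gene sets as generic, condition-centric or mixed
#'
#' A gene set with at least one called edge is \emph{generic} when none of
#' its incident edges is specific to any condition; \emph{T_k-centric} when
#' every incident edge is specific, and specific only to the same single
#' condition T_k; and \emph{mixed} otherwise.
#'
#' @param net \code{consensus_network}.
#' @param spec_results data.frame from \code{\link{test_all}}.
#' @return data.frame with columns \code{set}, \code{class} (one of
#'   \code{"generic"}, \code{"centric"}, \code{"mixed"}) and
#'   \code{condition} (the centric condition, else \code{NA}).
#' @export
classify_centricity <- function(net, spec_results) {
  stopifnot(inherits(net, "consensus_network"))
  edges <- call_edges(net)
  if (nrow(edges) == 0L) {
    return(data.frame(set = character(), class = character(),
                      condition = character(), stringsAsFactors = FALSE))
  }
  bad <- !(paste(spec_results$set_i, spec_results$set_j) %in%
             paste(edges$set_i, edges$set_j))
  if (any(bad)) {
    stop("specificity result(s) reference edges not called in the network",
         call. = FALSE)
  }
  key <- paste(spec_results$set_i, spec_results$set_j)
  spec_conds <- lapply(split(spec_results[spec_results$specific, ],
                             key[spec_results$specific]),
                       function(df) unique(df$condition))
  nodes <- sort(unique(c(edges$set_i, edges$set_j)))
  out <- lapply(nodes, function(v) {
    inc <- edges[edges$set_i == v | edges$set_j == v, , drop = FALSE]
    ks <- paste(inc$set_i, inc$set_j)
    conds_per_edge <- lapply(ks, function(k) spec_conds[[k]] %||% character())
    n_spec <- sum(lengths(conds_per_edge) > 0L)
    all_conds <- unique(unlist(conds_per_edge))
    if (n_spec == 0L) {
      data.frame(set = v, class = "generic", condition = NA_character_,
                 stringsAsFactors = FALSE)
    } else if (n_spec == nrow(inc) && length(all_conds) == 1L) {
      data.frame(set = v, class = "centric", condition = all_conds,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(set = v, class = "mixed", condition = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
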