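# Network export/import: edge-list TSV and GraphML.

#' Write a consensus network with optional specificity annotations
#'
#' The edge-list TSV has columns \code{set_i}, \code{set_j}, \code{d},
#' and, per tested condition, \code{gamma_<cond>}, \code{p_<cond>},
#' \code{specific_<cond>}. Only edges with \code{d > d_theta} are emitted,
#' in lexicographic pair order. GraphML output carries the same attributes
#' (via igraph) for hand-off to external viewers.
#'
#' @param net \code{consensus_network}.
#' @param spec optional data.frame from \code{\link{test_all}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @export
write_network <- function(net, spec = NULL, path,
                          format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "consensus_network"))
  format <- match.arg(format)
  edges <- call_edges(net)
  if (!is.null(spec) && nrow(spec)) {
    bad <- setdiff(unique(c(spec$set_i, spec$set_j)), net$node_ids)
    if (length(bad)) {
      stop("specificity record(s) reference unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    key <- paste(edges$set_i, edges$set_j)
    for (cond in unique(spec$condition)) {
      sc <- spec[spec$condition == cond, , drop = FALSE]
      sk <- paste(sc$set_i, sc$set_j)
      m <- match(key, sk)
      edges[[paste0("gamma_", cond)]] <- sc$gamma[m]
      edges[[paste0("p_", cond)]] <- sc$p[m]
      edges[[paste0("specific_", cond)]] <- sc$specific[m]
    }
  }
  if (format == "tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = net$node_ids))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list network written by \code{\link{write_network}}
#'
#' Reconstructs a \code{consensus_network} whose dependency matrix holds
#' the written \code{d} values (zero elsewhere). Round-trips the called
#' edge set exactly.
#'
#' @param path edge-list TSV path.
#' @param R run count to record on the network.
#' @param d_theta threshold to record, default 0.5.
#' @param node_ids optional full node list (edges may not cover isolated
#'   nodes).
#' @return \code{consensus_network}.
#' @export
read_network <- function(path, R, d_theta = 0.5, node_ids = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("set_i", "set_j", "d")
  if (!all(need %in% colnames(tab))) {
    stop("edge list needs columns set_i, set_j, d", call. = FALSE)
  }
  ids <- node_ids %||% sort(unique(c(tab$set_i, tab$set_j)))
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(tab))) {
    d[tab$set_i[r], tab$set_j[r]] <- tab$d[r]
    d[tab$set_j[r], tab$set_i[r]] <- tab$d[r]
  }
  consensus_network(d, R = R, d_theta = d_theta)
}

#' Write specificity results as a long-format TSV
#'
#' Columns: \code{set_i, set_j, condition, d_all, d_without, gamma, H, M,
#' p, specific}.
#'
#' @param spec data.frame from \code{\link{test_all}}.
#' @param path output path.
#' @export
write_specificity <- function(spec, path) {
  write.table(spec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
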