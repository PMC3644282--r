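# Synchronous boolean-network simulator with perturbation clamping, the
# cholesterol-pathway model, and the planted-dependency synthetic
# generator.

#' Boolean network
#'
#' Named binary nodes with logic rules over parent nodes built from
#' AND/OR/NOT. Clamped nodes ignore their rule and hold a fixed value
#' (modelling a perturbation such as statins administration).
#'
#' @param rules named character vector or list: \code{node = "EXPR"}, where
#'   EXPR uses node names, \code{AND}, \code{OR}, \code{NOT}, parentheses
#'   and the constants \code{0}/\code{1} (operators case-insensitive;
#'   \code{& | !} also accepted).
#' @param clamps optional named logical/0-1 vector of fixed node values.
#' @return object of class \code{boolean_network}.
#' @export
boolean_network <- function(rules, clamps = NULL) {
  rules <- unlist(rules)
  nodes <- names(rules)
  if (is.null(nodes) || any(nodes == "")) stop("all rules must be named",
                                               call. = FALSE)
  if (anyDuplicated(nodes)) {
    stop("duplicate rule(s) for node(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  }
  exprs <- lapply(rules, .parse_rule, nodes = nodes)
  net <- structure(list(nodes = nodes, rules = rules, exprs = exprs,
                        clamps = NULL),
                   class = "boolean_network")
  if (!is.null(clamps)) net <- clamp(net, clamps)
  net
}

# Translate a rule string into an R expression over logical node vectors.
.parse_rule <- function(rule, nodes) {
  txt <- rule
  txt <- gsub("\\bAND\\b", "&", txt, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
  ex <- tryCatch(str2lang(txt),
                 error = function(e) stop("cannot parse rule '", rule, "': ",
                                          conditionMessage(e), call. = FALSE))
  refs <- setdiff(all.vars(ex), nodes)
  if (length(refs)) {
    stop("rule '", rule, "' references undeclared node(s): ",
         paste(refs, collapse = ", "), call. = FALSE)
  }
  ok <- setdiff(all.names(ex), c(all.vars(ex), "&", "|", "!", "(", ")"))
  if (length(ok)) {
    stop("rule '", rule, "' uses unsupported operator(s): ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  ex
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("boolean_network: ", length(x$nodes), " nodes\n", sep = "")
  for (n in x$nodes) cat("  ", n, " = ", x$rules[[n]], "\n", sep = "")
  if (!is.null(x$clamps)) {
    cat("clamps: ",
        paste(names(x$clamps), as.integer(x$clamps), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Clamp nodes of a boolean network
#'
#' @param net \code{boolean_network}.
#' @param clamps named logical/0-1 vector; \code{NULL} removes all clamps.
#' @return the network with clamps set.
#' @export
clamp <- function(net, clamps) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(clamps)) { net$clamps <- NULL; return(net) }
  bad <- setdiff(names(clamps), net$nodes)
  if (length(bad)) stop("clamp on undeclared node(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  net$clamps <- setNames(as.logical(clamps), names(clamps))
  net
}

#' Edge list of a boolean network
#'
#' Parent-child pairs implied by the rules, with a flag for parents that
#' appear under a NOT in the child's rule.
#'
#' @param net \code{boolean_network}.
#' @return data.frame with columns \code{from}, \code{to}, \code{negated}.
#' @export
bn_edges <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  neg_vars <- function(ex, under_not = FALSE) {
    if (is.name(ex)) {
      return(if (under_not) as.character(ex) else character())
    }
    if (!is.call(ex)) return(character())
    op <- as.character(ex[[1L]])
    if (op == "!") return(unlist(lapply(as.list(ex)[-1L], neg_vars, TRUE)))
    unlist(lapply(as.list(ex)[-1L], neg_vars, under_not))
  }
  rows <- lapply(net$nodes, function(child) {
    ex <- net$exprs[[child]]
    parents <- setdiff(all.vars(ex), character())
    parents <- setdiff(parents, child)  # self-persistence is not an edge
    if (!length(parents)) return(NULL)
    data.frame(from = parents, to = child,
               negated = parents %in% neg_vars(ex),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One synchronous update step
#'
#' Every unclamped node simultaneously takes its rule's value on the
#' previous state; clamped nodes keep their clamp. Accepts a single state
#' (named logical/0-1 vector) or a matrix of states (rows = trajectories,
#' columns = nodes), which is updated vectorized.
#'
#' @param net \code{boolean_network}.
#' @param state named vector covering all nodes, or matrix with node
#'   columns.
#' @return object of the same shape.
#' @export
bn_step <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  vec <- !is.matrix(state)
  if (vec) state <- matrix(state, nrow = 1L,
                           dimnames = list(NULL, names(state)))
  if (!all(net$nodes %in% colnames(state))) {
    stop("state must cover all nodes", call. = FALSE)
  }
  env <- new.env(parent = baseenv())
  for (n in net$nodes) assign(n, as.logical(state[, n]), envir = env)
  out <- matrix(FALSE, nrow(state), length(net$nodes),
                dimnames = list(rownames(state), net$nodes))
  for (n in net$nodes) out[, n] <- as.logical(eval(net$exprs[[n]], env))
  for (n in names(net$clamps)) out[, n] <- net$clamps[[n]]
  if (vec) setNames(out[1L, ], colnames(out)) else out
}

#' Simulation design
#'
#' @param n_samples samples per arm.
#' @param arms named list of clamp settings, e.g.
#'   \code{list(statins_off = c(Statins = 0), statins_on = c(Statins = 1))}.
#' @param max_steps update-step cap per trajectory, default 512.
#' @param seed integer seed.
#' @return list of class \code{simulation_design}.
#' @export
simulation_design <- function(n_samples = 100L, arms, max_steps = 512L,
                              seed = 1L) {
  stopifnot(n_samples >= 1L, max_steps >= 1L, is.list(arms),
            !is.null(names(arms)))
  structure(list(n_samples = as.integer(n_samples), arms = arms,
                 max_steps = as.integer(max_steps), seed = seed),
            class = "simulation_design")
}

#' Sample attractor states from a boolean network
#'
#' Per sample: a uniformly random initial state is drawn, clamps applied,
#' and the network iterated synchronously until the trajectory revisits a
#' state (attractor). A fixed point emits itself; a cycle emits one
#' uniformly chosen state of the cycle. If \code{max_steps} is reached
#' without an attractor the last state is emitted with a warning. Arms are
#' concatenated; boolean states map 1 to \code{UP} and 0 to \code{DOWN} so
#' the data flows through the standard pipeline unchanged.
#'
#' @param net \code{boolean_network}.
#' @param design \code{\link{simulation_design}}.
#' @return list: \code{data} (\code{trinary_matrix}, nodes x samples),
#'   \code{conditions} (\code{condition_table} with one condition per arm;
#'   \code{NULL} for a single-arm design, which admits no proper subset).
#' @export
sample_steady_states <- function(net, design) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(design, "simulation_design"))
  nn <- length(net$nodes)
  .with_seed(design$seed, {
    arm_mats <- lapply(names(design$arms), function(arm) {
      anet <- clamp(net, design$arms[[arm]])
      states <- matrix(stats::runif(design$n_samples * nn) < 0.5,
                       design$n_samples, nn,
                       dimnames = list(NULL, net$nodes))
      for (cn in names(anet$clamps)) states[, cn] <- anet$clamps[[cn]]
      emitted <- matrix(NA, design$n_samples, nn,
                        dimnames = list(NULL, net$nodes))
      state_key <- function(m) apply(m, 1L, function(r)
        paste(as.integer(r), collapse = ""))
      history <- vector("list", design$max_steps + 1L)
      history[[1L]] <- states
      keys <- matrix(NA_character_, design$n_samples, design$max_steps + 1L)
      keys[, 1L] <- state_key(states)
      active <- rep(TRUE, design$n_samples)
      for (t in seq_len(design$max_steps)) {
        states <- bn_step(anet, states)
        history[[t + 1L]] <- states
        keys[, t + 1L] <- state_key(states)
        # first occurrence of the new key among earlier steps closes a cycle
        for (i in which(active)) {
          prev <- match(keys[i, t + 1L], keys[i, seq_len(t)])
          if (!is.na(prev)) {
            cyc <- seq.int(prev, t)   # states at steps prev-1 .. t-1 (0-based)
            pick <- cyc[[sample.int(length(cyc), 1L)]]
            emitted[i, ] <- history[[pick]][i, ]
            active[i] <- FALSE
          }
        }
        if (!any(active)) break
      }
      if (any(active)) {
        warning(sum(active), " trajectory(ies) hit max_steps without an ",
                "attractor in arm '", arm, "'; last state emitted")
        emitted[active, ] <- states[active, ]
      }
      emitted
    })
    names(arm_mats) <- names(design$arms)
    all_states <- do.call(rbind, arm_mats)
    sample_ids <- unlist(lapply(names(design$arms), function(a)
      paste0(a, "_", seq_len(design$n_samples))))
    vals <- t(ifelse(all_states, 1L, -1L))
    colnames(vals) <- sample_ids
    rownames(vals) <- net$nodes
    # with a single arm there is no proper condition subset to annotate
    conds <- if (length(design$arms) >= 2L) {
      condition_table(
        setNames(lapply(names(design$arms), function(a)
          paste0(a, "_", seq_len(design$n_samples))), names(design$arms)),
        sample_ids)
    } else NULL
    list(data = trinary_matrix(vals), conditions = conds)
  })
}

#' Read a boolean network model file
#'
#' Human-readable rule format, one line per node: \code{node = EXPR} with
#' AND/OR/NOT and parentheses; \code{#} starts a comment.
#'
#' @param path model file path.
#' @return \code{boolean_network}.
#' @export
read_boolean_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$",
                                 lines))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("cannot parse model line: '", lines[bad][1L], "'",
                     call. = FALSE)
  rules <- setNames(vapply(m, `[[`, "", 3L), vapply(m, `[[`, "", 2L))
  boolean_network(rules)
}

#' The cholesterol regulatory pathway model
#'
#' Boolean model of cholesterol synthesis from acetyl-CoA, with the
#' SREBP-SCAP feedback and the statins inhibition of HMG-CoA reductase,
#' shipped as a human-readable model file under \code{inst/extdata}. Used
#' by the packaged statins perturbation experiment.
#'
#' @return \code{boolean_network}.
#' @export
cholesterol_network <- function() {
  read_boolean_network(system.file("extdata", "cholesterol.bn",
                                   package = "ctxnet", mustWork = TRUE))
}

#' Synthetic trinary data with planted condition-specific dependencies
#'
#' Background variables are i.i.d. over the three states with configurable
#' marginals. For each planted edge (i, j, condition, strength), variable j
#' copies variable i with probability \code{strength} within the
#' condition's samples and stays independent elsewhere. Entry-wise noise
#' then replaces each value, with probability \code{noise}, by one of the
#' other two states (chosen uniformly).
#'
#' @param n_sets number of variables (gene sets).
#' @param n_samples number of samples.
#' @param conditions \code{condition_table}, or a named list of sample-id
#'   vectors over samples \code{s1..sN}.
#' @param planted_edges data.frame with columns \code{i}, \code{j}
#'   (variable indices or names), \code{condition}, \code{strength}.
#' @param noise flip probability in [0, 1), default 0.
#' @param seed integer seed.
#' @param marginals probabilities of \code{DOWN}, \code{NOCHANGE},
#'   \code{UP}; default \code{c(0.25, 0.5, 0.25)}.
#' @return list: \code{data} (\code{trinary_matrix}), \code{conditions}
#'   (\code{condition_table}), \code{truth} (the planted edge table with
#'   resolved names).
#' @export
generate_planted <- function(n_sets, n_samples, conditions, planted_edges,
                             noise = 0, seed = 1L,
                             marginals = c(0.25, 0.5, 0.25)) {
  stopifnot(n_sets >= 2L, n_samples >= 1L, noise >= 0, noise < 1,
            length(marginals) == 3L, all(marginals >= 0))
  marginals <- marginals / sum(marginals)
  ids <- sprintf("S%02d", seq_len(n_sets))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  if (!inherits(conditions, "condition_table")) {
    conditions <- condition_table(conditions, sample_ids)
  }
  if (!setequal(conditions$universe, sample_ids)) {
    stop("condition universe must be the generated samples s001..s", n_samples,
         call. = FALSE)
  }
  pe <- as.data.frame(planted_edges, stringsAsFactors = FALSE)
  if (nrow(pe)) {
    if (is.numeric(pe$i)) pe$i <- ids[pe$i]
    if (is.numeric(pe$j)) pe$j <- ids[pe$j]
    stopifnot(all(pe$i %in% ids), all(pe$j %in% ids),
              all(pe$strength >= 0 & pe$strength <= 1))
    if (anyDuplicated(t(apply(pe[, c("i", "j")], 1L, sort)))) {
      stop("planted pairs must be distinct", call. = FALSE)
    }
    badc <- setdiff(pe$condition, names(conditions$assignments))
    if (length(badc)) stop("condition block unknown: ",
                           paste(badc, collapse = ", "), call. = FALSE)
  }
  .with_seed(seed, {
    x <- matrix(sample(c(-1L, 0L, 1L), n_sets * n_samples, replace = TRUE,
                       prob = marginals),
                n_sets, n_samples, dimnames = list(ids, sample_ids))
    for (row in seq_len(nrow(pe))) {
      s_cond <- conditions$assignments[[pe$condition[row]]]
      copy <- s_cond[stats::runif(length(s_cond)) < pe$strength[row]]
      x[pe$j[row], copy] <- x[pe$i[row], copy]
    }
    if (noise > 0) {
      flip <- which(matrix(stats::runif(length(x)) < noise, nrow(x)))
      if (length(flip)) {
        # replace by one of the two other states, uniformly
        shift <- sample(1:2, length(flip), replace = TRUE)
        x[flip] <- ((x[flip] + 1L + shift) %% 3L) - 1L
      }
    }
    list(data = trinary_matrix(x), conditions = conditions, truth = pe)
  })
}
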