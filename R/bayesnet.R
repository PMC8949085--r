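# Discrete Bayesian networks over disease/drug/symptom variables:
# CPT estimation, chain-rule joint probability, exact inference by
# enumeration, BDeu-scored MCMC structure sampling, and arc strength.

as_edge_df <- function(dag) {
  if (is.null(dag) || (is.data.frame(dag) && nrow(dag) == 0L) ||
      (is.matrix(dag) && nrow(dag) == 0L)) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  dag <- as.data.frame(dag, stringsAsFactors = FALSE)
  names(dag)[1:2] <- c("from", "to")
  dag$from <- as.character(dag$from)
  dag$to <- as.character(dag$to)
  dag[, c("from", "to")]
}

# topological order; error if cyclic
topo_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  avail <- nodes[indeg == 0L]
  indeg2 <- indeg
  edges2 <- edges
  while (length(avail) > 0L) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    ch <- edges2$to[edges2$from == v]
    edges2 <- edges2[edges2$from != v, , drop = FALSE]
    for (w in ch) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != length(nodes)) {
    stop(depdst_error("edge set contains a directed cycle", "cyclic_dag"))
  }
  out
}

config_key <- function(states) paste(states, collapse = "\x1f")

#' Fit conditional probability tables for a given DAG
#'
#' Estimates, for every node, `P(node | parents)` from a table of categorical
#' records by Laplace-smoothed relative frequencies (one pseudo-count per
#' cell), so every CPT row over a fixed parent configuration sums to one and
#' no cell is exactly zero.
#'
#' @param data Data frame of categorical records; every DAG node must be a
#'   column. Columns are coerced to factors (observed levels define states).
#' @param dag Two-column (from, to) data frame or matrix of directed edges;
#'   must be acyclic. May be empty (all nodes marginal).
#' @param alpha Laplace pseudo-count per CPT cell (default 1).
#' @return An object of class `discrete_bayes_net`: list with `nodes` (state
#'   lists), `edges`, and `cpts` (per node: states, parents, parent state
#'   lists, and a states x parent-configuration probability matrix).
#' @examples
#' d <- data.frame(drug = c("A", "A", "B"), reaction = c("yes", "no", "no"))
#' fit_cpts(d, data.frame(from = "drug", to = "reaction"))
#' @export
fit_cpts <- function(data, dag, alpha = 1) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop(depdst_error("data must be a non-empty data frame", "empty_data"))
  }
  edges <- as_edge_df(dag)
  nodes <- union(names(data), unique(c(edges$from, edges$to)))
  missing <- setdiff(unique(c(edges$from, edges$to)), names(data))
  if (length(missing) > 0L) {
    stop(depdst_error(sprintf("dag node(s) not in data: %s",
                              paste(missing, collapse = ", ")), "unseen_node"))
  }
  nodes <- names(data)
  topo_order(nodes, edges)  # acyclicity check
  fac <- lapply(data, function(col) factor(col))
  states <- lapply(fac, levels)
  cpts <- list()
  for (v in nodes) {
    pa <- edges$from[edges$to == v]
    r <- length(states[[v]])
    if (length(pa) == 0L) {
      cnt <- table(fac[[v]])
      prob <- matrix((as.numeric(cnt) + alpha) / (sum(cnt) + alpha * r),
                     nrow = r, ncol = 1,
                     dimnames = list(states[[v]], "(marginal)"))
      pa_states <- list()
    } else {
      grid <- expand.grid(lapply(pa, function(p) states[[p]]),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      names(grid) <- pa
      cfg_keys <- apply(grid, 1L, config_key)
      conf <- interaction(fac[pa], drop = FALSE, lex.order = FALSE)
      cnt <- table(fac[[v]], conf)
      # interaction() enumerates in the same order as expand.grid over levels
      prob <- (unclass(cnt) + alpha)
      prob <- sweep(prob, 2L, colSums(prob), "/")
      dimnames(prob) <- list(states[[v]], cfg_keys)
      pa_states <- states[pa]
    }
    cpts[[v]] <- list(node = v, states = states[[v]], parents = pa,
                      parent_states = pa_states, prob = prob)
  }
  structure(list(nodes = states, edges = edges, cpts = cpts),
            class = "discrete_bayes_net")
}

#' @export
print.discrete_bayes_net <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  for (v in names(x$nodes)) {
    pa <- x$cpts[[v]]$parents
    cat(sprintf("  %s (%d states)%s\n", v, length(x$nodes[[v]]),
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

cpt_prob <- function(net, v, state, assignment) {
  cpt <- net$cpts[[v]]
  i <- match(state, cpt$states)
  if (is.na(i)) {
    stop(depdst_error(sprintf("unknown state '%s' for node '%s'", state, v),
                      "unknown_state"))
  }
  if (length(cpt$parents) == 0L) return(cpt$prob[i, 1L])
  pa_states <- unlist(assignment[cpt$parents], use.names = FALSE)
  j <- match(config_key(pa_states), colnames(cpt$prob))
  if (is.na(j)) {
    stop(depdst_error(sprintf("unknown parent state for node '%s'", v),
                      "unknown_state"))
  }
  cpt$prob[i, j]
}

#' Joint probability of a full assignment (chain rule)
#'
#' Computes `P(X1, ..., Xn)` as the product over nodes of
#' `P(Xi | parents(Xi))` taken from the fitted CPTs.
#'
#' @param net A `discrete_bayes_net` from [fit_cpts()].
#' @param assignment Named list or character vector mapping every node to one
#'   of its states.
#' @return A probability in \[0, 1\].
#' @export
joint_probability <- function(net, assignment) {
  stopifnot(inherits(net, "discrete_bayes_net"))
  assignment <- as.list(assignment)
  miss <- setdiff(names(net$nodes), names(assignment))
  if (length(miss) > 0L) {
    stop(depdst_error(sprintf("assignment missing node(s): %s",
                              paste(miss, collapse = ", ")), "missing_node"))
  }
  p <- 1
  for (v in names(net$nodes)) {
    p <- p * cpt_prob(net, v, assignment[[v]], assignment)
    if (p == 0) return(0)
  }
  p
}

#' Exact conditional query by enumeration
#'
#' Computes `P(target | evidence)` by summing the chain-rule joint over all
#' assignments of the hidden nodes. Intended for the small
#' disease/drug/symptom networks this package works with.
#'
#' @param net A `discrete_bayes_net`.
#' @param target Node name to query.
#' @param evidence Named list of observed node states (may be empty).
#' @return Named probability vector over the target's states (sums to 1).
#' @export
conditional_query <- function(net, target, evidence = list()) {
  stopifnot(inherits(net, "discrete_bayes_net"))
  if (!target %in% names(net$nodes)) {
    stop(depdst_error(sprintf("unknown target node '%s'", target), "missing_node"))
  }
  evidence <- as.list(evidence)
  for (v in names(evidence)) {
    if (!v %in% names(net$nodes) || !evidence[[v]] %in% net$nodes[[v]]) {
      stop(depdst_error(sprintf("invalid evidence for node '%s'", v),
                        "unknown_state"))
    }
  }
  free <- setdiff(names(net$nodes), names(evidence))
  grid <- expand.grid(net$nodes[free], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- stats::setNames(numeric(length(net$nodes[[target]])),
                         net$nodes[[target]])
  for (i in seq_len(nrow(grid))) {
    a <- c(as.list(grid[i, , drop = FALSE]), evidence)
    out[[a[[target]]]] <- out[[a[[target]]]] + joint_probability(net, a)
  }
  z <- sum(out)
  if (z <= 0) {
    stop(depdst_error("impossible evidence: zero marginal probability",
                      "impossible_evidence"))
  }
  out / z
}

# ---- BDeu score -------------------------------------------------------------

# log BDeu family score of one node given parent columns (list of factors)
bdeu_node_score <- function(node_f, parent_fs, ess = 10) {
  r <- nlevels(node_f)
  if (length(parent_fs) == 0L) {
    N <- matrix(as.numeric(table(node_f)), ncol = 1)
  } else {
    conf <- interaction(parent_fs, drop = FALSE, lex.order = FALSE)
    N <- unclass(table(node_f, conf))
  }
  q <- ncol(N)
  a_jk <- ess / (r * q)
  a_j <- ess / q
  sum(lgamma(a_j) - lgamma(a_j + colSums(N))) +
    sum(lgamma(a_jk + N) - lgamma(a_jk))
}

# is there a directed path from `from` to `to` in adjacency matrix adj?
has_path <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(adj))
  stack <- from
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ]))
  }
  FALSE
}

#' Sample DAG structures by Markov chain Monte Carlo
#'
#' Metropolis walk over directed acyclic graphs scored by the BDeu marginal
#' likelihood (default equivalent sample size 10). Proposals are symmetric:
#' with probability `1 - rev_prob` a uniformly chosen ordered node pair has
#' its edge toggled (add if absent, delete if present); otherwise a uniformly
#' chosen existing edge is reversed. Proposals that would create a cycle or
#' exceed `max_parents` are rejected, so the chain never visits an invalid
#' graph. Acceptance uses score differences only.
#'
#' @param data Data frame of categorical records (all columns used as nodes);
#'   no column may be constant.
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded from the front; `n_iter > burn_in >= 0`.
#' @param seed Integer seed; the walk is fully deterministic given it.
#' @param ess BDeu equivalent sample size.
#' @param max_parents Cap on parents per node (default 3).
#' @param rev_prob Probability of proposing an edge reversal.
#' @return List of `n_iter - burn_in` edge sets, each a two-column character
#'   matrix with columns `from`, `to`.
#' @export
sample_structures_mcmc <- function(data, n_iter, burn_in, seed, ess = 10,
                                   max_parents = 3, rev_prob = 0.25) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    stop(depdst_error("data must have at least two variables", "empty_data"))
  }
  if (!(n_iter > burn_in && burn_in >= 0)) {
    stop(depdst_error("need n_iter > burn_in >= 0", "bad_iterations"))
  }
  fac <- lapply(data, factor)
  nlev <- vapply(fac, nlevels, integer(1))
  if (any(nlev < 2L)) {
    stop(depdst_error(sprintf("constant column(s): %s",
                              paste(names(fac)[nlev < 2L], collapse = ", ")),
                      "constant_column"))
  }
  nodes <- names(fac)
  p <- length(nodes)
  with_seed(seed, {
    adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    score <- vapply(seq_len(p), function(v) {
      bdeu_node_score(fac[[v]], list(), ess)
    }, numeric(1))
    node_score <- function(v) bdeu_node_score(fac[[v]], fac[which(adj[, v])], ess)
    samples <- vector("list", n_iter - burn_in)
    for (it in seq_len(n_iter)) {
      move <- NULL
      if (stats::runif(1) < rev_prob) {
        ecount <- sum(adj)
        if (ecount > 0L) {
          idx <- which(adj)
          e <- idx[ceiling(stats::runif(1) * length(idx))]
          u <- (e - 1L) %% p + 1L
          v <- (e - 1L) %/% p + 1L
          # reverse u->v: valid if no other path u->...->v and parent cap on u
          adj[u, v] <- FALSE
          ok <- !has_path(adj, u, v) && sum(adj[, u]) < max_parents
          adj[u, v] <- TRUE
          if (ok) move <- list(type = "rev", u = u, v = v)
        }
      } else {
        u <- ceiling(stats::runif(1) * p)
        v <- ceiling(stats::runif(1) * (p - 1L))
        if (v >= u) v <- v + 1L
        if (adj[u, v]) {
          move <- list(type = "del", u = u, v = v)
        } else {
          if (!has_path(adj, v, u) && sum(adj[, v]) < max_parents) {
            move <- list(type = "add", u = u, v = v)
          }
        }
      }
      if (!is.null(move)) {
        u <- move$u; v <- move$v
        if (move$type == "add") adj[u, v] <- TRUE
        if (move$type == "del") adj[u, v] <- FALSE
        if (move$type == "rev") { adj[u, v] <- FALSE; adj[v, u] <- TRUE }
        touched <- if (move$type == "rev") c(u, v) else v
        new_scores <- vapply(touched, node_score, numeric(1))
        delta <- sum(new_scores) - sum(score[touched])
        if (log(stats::runif(1)) < delta) {
          score[touched] <- new_scores
        } else {
          if (move$type == "add") adj[u, v] <- FALSE
          if (move$type == "del") adj[u, v] <- TRUE
          if (move$type == "rev") { adj[v, u] <- FALSE; adj[u, v] <- TRUE }
        }
      }
      if (it > burn_in) {
        idx <- which(adj, arr.ind = TRUE)
        samples[[it - burn_in]] <- matrix(
          c(nodes[idx[, 1L]], nodes[idx[, 2L]]), ncol = 2,
          dimnames = list(NULL, c("from", "to")))
      }
    }
    samples
  })
}

#' Arc strength from sampled structures
#'
#' The strength of a directed arc is the fraction of sampled structures that
#' contain it: a posterior edge-support measure. With `undirected = TRUE` the
#' two orientations of a pair are pooled (structure MCMC often cannot resolve
#' Markov-equivalent orientations), and both directions report the pooled
#' value.
#'
#' @param samples List of edge sets as returned by [sample_structures_mcmc()].
#' @param nodes Character vector naming all network nodes (needed so that
#'   never-sampled arcs are known to have strength 0).
#' @param undirected Pool orientations? Default `FALSE`.
#' @return An object of class `arc_strength_table`: list with `entries`
#'   (data frame from, to, strength), `n_samples`, `nodes`, `undirected`.
#' @export
arc_strength <- function(samples, nodes, undirected = FALSE) {
  if (length(samples) == 0L) {
    stop(depdst_error("empty structure sample list", "empty_samples"))
  }
  nodes <- as.character(nodes)
  counts <- new.env(parent = emptyenv())
  for (s in samples) {
    if (nrow(s) == 0L) next
    keys <- paste(s[, 1L], s[, 2L], sep = "\x1f")
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys) > 0L) {
    parts <- strsplit(keys, "\x1f", fixed = TRUE)
    entries <- data.frame(
      from = vapply(parts, `[`, character(1), 1L),
      to = vapply(parts, `[`, character(1), 2L),
      count = vapply(keys, function(k) counts[[k]], integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    entries <- data.frame(from = character(0), to = character(0),
                          count = integer(0))
  }
  if (undirected && nrow(entries) > 0L) {
    pk <- ifelse(entries$from < entries$to,
                 paste(entries$from, entries$to, sep = "\x1f"),
                 paste(entries$to, entries$from, sep = "\x1f"))
    pooled <- tapply(entries$count, pk, sum)
    parts <- strsplit(names(pooled), "\x1f", fixed = TRUE)
    a <- vapply(parts, `[`, character(1), 1L)
    b <- vapply(parts, `[`, character(1), 2L)
    entries <- data.frame(from = c(a, b), to = c(b, a),
                          count = c(as.integer(pooled), as.integer(pooled)),
                          stringsAsFactors = FALSE)
  }
  entries$strength <- entries$count / length(samples)
  entries$count <- NULL
  structure(list(entries = entries, n_samples = length(samples),
                 nodes = nodes, undirected = undirected),
            class = "arc_strength_table")
}

#' @export
print.arc_strength_table <- function(x, n = 10, ...) {
  cat(sprintf("Arc strengths from %d sampled structures (%s)\n", x$n_samples,
              if (x$undirected) "orientation-pooled" else "directed"))
  e <- x$entries[order(-x$entries$strength), , drop = FALSE]
  print(utils::head(e, n), row.names = FALSE)
  if (nrow(e) > n) cat("  ...", nrow(e) - n, "more arcs\n")
  invisible(x)
}

#' Causal-strength credibility component
#'
#' Looks up the posterior support for the drug-to-symptom arc of a candidate
#' ADR record: the fraction of MCMC-sampled structures containing that arc.
#' An arc that never appeared has strength 0.
#'
#' @param drug,symptom Node names of the record's drug and symptom.
#' @param table An `arc_strength_table` whose node set contains both.
#' @return A value in \[0, 1\].
#' @export
dep_causal_strength <- function(drug, symptom, table) {
  stopifnot(inherits(table, "arc_strength_table"))
  if (!drug %in% table$nodes || !symptom %in% table$nodes) {
    stop(depdst_error(sprintf("unknown node(s): %s",
                              paste(setdiff(c(drug, symptom), table$nodes),
                                    collapse = ", ")), "unknown_node"))
  }
  hit <- table$entries$from == drug & table$entries$to == symptom
  if (any(hit)) table$entries$strength[which(hit)[1L]] else 0
}

# ---- CSV / JSON interchange -------------------------------------------------

#' Export fitted CPTs as a long-format CSV table
#'
#' Columns: `parent_node` (semicolon-joined), `parent_state` (semicolon-joined
#' configuration), `node`, `state`, `probability`. Marginal nodes have empty
#' parent fields.
#'
#' @param net A `discrete_bayes_net`.
#' @param path Optional file path; when `NULL` the data frame is returned.
#' @return The CPT data frame (invisibly when written to file).
#' @export
cpt_export <- function(net, path = NULL) {
  stopifnot(inherits(net, "discrete_bayes_net"))
  rows <- list()
  for (v in names(net$cpts)) {
    cpt <- net$cpts[[v]]
    for (j in seq_len(ncol(cpt$prob))) {
      cfg <- if (length(cpt$parents) == 0L) "" else {
        paste(strsplit(colnames(cpt$prob)[j], "\x1f", fixed = TRUE)[[1L]],
              collapse = ";")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parent_node = paste(cpt$parents, collapse = ";"),
        parent_state = cfg, node = v, state = cpt$states,
        probability = cpt$prob[, j], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a CPT table in the long CSV dialect
#'
#' Validates that every (node, parent configuration) row sums to 1 within
#' `tol`.
#'
#' @param path CSV file path (or a data frame in the same layout).
#' @param tol Row-sum tolerance.
#' @return Data frame with columns parent_node, parent_state, node, state,
#'   probability.
#' @export
cpt_import <- function(path, tol = 1e-6) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(parent_node = "character",
                                   parent_state = "character",
                                   node = "character", state = "character"))
  }
  need <- c("parent_node", "parent_state", "node", "state", "probability")
  if (!all(need %in% names(df))) {
    stop(depdst_error("CPT table must have columns parent_node, parent_state, node, state, probability",
                      "cpt_format"))
  }
  df$parent_node[is.na(df$parent_node)] <- ""
  df$parent_state[is.na(df$parent_state)] <- ""
  key <- paste(df$node, df$parent_node, df$parent_state, sep = "\x1f")
  sums <- tapply(df$probability, key, sum)
  bad <- abs(sums - 1) > tol
  if (any(bad)) {
    stop(depdst_error(sprintf("CPT row(s) do not sum to 1: %s",
                              paste(utils::head(names(sums)[bad], 3), collapse = "; ")),
                      "cpt_rowsum"))
  }
  df
}

#' Export structure samples as an edge-list JSON document
#'
#' @param samples List of edge matrices from [sample_structures_mcmc()].
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
structures_to_json <- function(samples, path = NULL) {
  lst <- lapply(samples, function(s) {
    if (nrow(s) == 0L) list() else
      lapply(seq_len(nrow(s)), function(i) list(from = s[i, 1L], to = s[i, 2L]))
  })
  txt <- as.character(jsonlite::toJSON(lst, auto_unbox = TRUE))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
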