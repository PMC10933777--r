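# Linear-Gaussian Bayesian-network structure learning with genetic
# directional anchors: decomposable BIC scoring, greedy hill climbing under
# white/black-list constraints, and bootstrap edge/direction probabilities
# with a consensus graph. Variables are treated as continuous; SNP dosages
# enter as numeric 0/1/2 regressors, which matches their use as anchors.

#' Construct a directed acyclic graph
#'
#' @param nodes character vector of variable names.
#' @param edges two-column character matrix or data.frame of
#'   (parent, child) pairs; may be empty.
#' @return Object of class `dag`: list `nodes`, `edges` (2-column matrix).
#' @export
dag <- function(nodes, edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("parent", "child")
  assert_that(all(edges %in% nodes), "edge endpoints must be nodes")
  assert_that(all(edges[, 1] != edges[, 2]), "self-edges are not allowed")
  key <- paste(edges[, 1], edges[, 2])
  assert_that(!any(duplicated(key)), "duplicate edges")
  g <- structure(list(nodes = nodes, edges = edges), class = "dag")
  assert_that(is_acyclic(g), "graph contains a cycle")
  g
}

#' Test a directed graph for acyclicity (Kahn's algorithm)
#' @param g a [dag()] (or unvalidated list with `nodes`, `edges`).
#' @return TRUE iff a topological order exists.
#' @export
is_acyclic <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  if (nrow(edges) == 0) return(TRUE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2])
  indeg[names(tab)] <- as.integer(tab)
  queue <- nodes[indeg == 0]
  removed <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    removed <- removed + 1L
    children <- edges[edges[, 1] == v, 2]
    for (c in children) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
    edges <- edges[edges[, 1] != v, , drop = FALSE]
  }
  removed == length(nodes)
}

has_edge <- function(g, parent, child) {
  any(g$edges[, 1] == parent & g$edges[, 2] == child)
}

add_edge <- function(g, parent, child) {
  g$edges <- rbind(g$edges, c(parent, child))
  g
}

remove_edge <- function(g, parent, child) {
  keep <- !(g$edges[, 1] == parent & g$edges[, 2] == child)
  g$edges <- g$edges[keep, , drop = FALSE]
  g
}

parents_of <- function(g, node) g$edges[g$edges[, 2] == node, 1]

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("<dag> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Edge constraints: white- and black-lists (directional anchors)
#'
#' Whitelisted edges are forced present with fixed direction (e.g. known
#' SNP -> phenotype associations); blacklisted edges can never be added
#' (e.g. anything directed into a SNP or into age).
#'
#' @param whitelist,blacklist two-column matrices/data.frames of
#'   (parent, child) pairs, or NULL.
#' @return Object of class `edge_constraints`.
#' @export
edge_constraints <- function(whitelist = NULL, blacklist = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0) return(matrix(character(0), 0, 2))
    x <- as.matrix(x)
    storage.mode(x) <- "character"
    colnames(x) <- c("parent", "child")
    x
  }
  wl <- norm(whitelist)
  bl <- norm(blacklist)
  overlap <- intersect(paste(wl[, 1], wl[, 2]), paste(bl[, 1], bl[, 2]))
  assert_that(length(overlap) == 0,
              "whitelist and blacklist must be disjoint")
  structure(list(whitelist = wl, blacklist = bl), class = "edge_constraints")
}

is_blacklisted <- function(constraints, parent, child) {
  bl <- constraints$blacklist
  any(bl[, 1] == parent & bl[, 2] == child)
}

is_whitelisted <- function(constraints, parent, child) {
  wl <- constraints$whitelist
  any(wl[, 1] == parent & wl[, 2] == child)
}

# Local Gaussian BIC for one node given its parents: maximised log
# likelihood minus (parameters / 2) * log(n). Parameters count the
# intercept, one coefficient per parent, and the residual variance.
local_bic <- function(data, node, parents) {
  y <- data[, node]
  n <- length(y)
  x <- cbind(`(intercept)` = rep(1, n),
             if (length(parents)) as.matrix(data[, parents, drop = FALSE]))
  degenerate <- FALSE
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    # Singular parent design: minimum-norm least squares via pseudo-inverse.
    degenerate <- TRUE
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    resid <- y - x %*% coefs
  } else {
    resid <- stats::residuals(stats::lm.fit(x, y))
  }
  sigma2 <- max(sum(resid^2) / n, 1e-300)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  n_par <- length(parents) + 2
  list(score = loglik - n_par / 2 * log(n), degenerate = degenerate)
}

#' Decomposable Gaussian BIC score of a DAG
#'
#' Sum over nodes of the Gaussian log-likelihood of each node regressed on
#' its parents minus `(parameters / 2) * log(n)`. Higher is better. The
#' score decomposes by node, so single-edge moves only touch the affected
#' local terms.
#'
#' @param data numeric matrix or data.frame of observations over the nodes.
#' @param g a [dag()] whose nodes are columns of `data`.
#' @return List `total`, `local` (named numeric), `degenerate` (named
#'   logical; TRUE where a singular parent design was fit by
#'   pseudo-inverse).
#' @export
bic_score <- function(data, g) {
  data <- as.matrix(data)
  max_parents <- if (nrow(g$edges)) max(table(g$edges[, 2])) else 0
  assert_that(nrow(data) >= max_parents + 2,
              "need at least 2 more observations than the largest parent set")
  locals <- lapply(g$nodes, function(v) local_bic(data, v, parents_of(g, v)))
  local_scores <- vapply(locals, `[[`, numeric(1), "score")
  names(local_scores) <- g$nodes
  degenerate <- vapply(locals, `[[`, logical(1), "degenerate")
  names(degenerate) <- g$nodes
  list(total = sum(local_scores), local = local_scores,
       degenerate = degenerate)
}

#' Greedy hill-climbing structure search under constraints
#'
#' Starts from the whitelist-only graph and repeatedly applies the single
#' best score-improving move among edge additions, deletions and reversals,
#' respecting acyclicity, the whitelist (never deletable or reversible) and
#' the blacklist (never addable), until no move improves the BIC or
#' `max_iter` is reached. With `restarts > 0`, additional searches start
#' from random constraint-respecting graphs (seeded) and the best-scoring
#' result wins.
#'
#' @param data numeric matrix or data.frame (columns are the nodes).
#' @param constraints an [edge_constraints()] or NULL.
#' @param max_iter maximum number of moves (default `10 * p^2`).
#' @param restarts number of random restarts (default 0).
#' @param seed RNG seed (used only for restarts).
#' @return The best [dag()] found, with attributes `score` and
#'   `start_score`.
#' @export
hill_climb <- function(data, constraints = NULL, max_iter = NULL,
                       restarts = 0, seed = 1L) {
  data <- as.matrix(data)
  nodes <- colnames(data)
  assert_that(!is.null(nodes), "data must have column names")
  constraints <- constraints %||% edge_constraints()
  assert_that(all(constraints$whitelist %in% nodes) &&
                all(constraints$blacklist %in% nodes),
              "constraint endpoints must be data columns")
  max_iter <- max_iter %||% (10 * length(nodes)^2)

  start <- dag(nodes, constraints$whitelist)  # also checks whitelist acyclicity
  runs <- list(search_from(data, start, constraints, max_iter))
  if (restarts > 0) {
    seeds <- derive_seeds(seed, restarts)
    for (r in seq_len(restarts)) {
      g0 <- with_seed(seeds[r], random_start(nodes, constraints))
      runs[[r + 1]] <- search_from(data, g0, constraints, max_iter)
    }
  }
  scores <- vapply(runs, function(g) attr(g, "score"), numeric(1))
  best <- runs[[which.max(scores)]]
  attr(best, "start_score") <- attr(runs[[1]], "start_score")
  stopifnot(is_acyclic(best))
  best
}

random_start <- function(nodes, constraints) {
  g <- dag(nodes, constraints$whitelist)
  candidates <- expand.grid(parent = nodes, child = nodes,
                            stringsAsFactors = FALSE)
  candidates <- candidates[candidates$parent != candidates$child, ]
  candidates <- candidates[sample.int(nrow(candidates)), ]
  for (i in seq_len(nrow(candidates))) {
    p <- candidates$parent[i]
    c <- candidates$child[i]
    if (stats::runif(1) > 0.2) next
    if (is_blacklisted(constraints, p, c) || has_edge(g, p, c) ||
        has_edge(g, c, p)) next
    g2 <- add_edge(g, p, c)
    if (is_acyclic(g2)) g <- g2
  }
  g
}

search_from <- function(data, g, constraints, max_iter) {
  nodes <- g$nodes
  local <- vapply(nodes, function(v) local_bic(data, v, parents_of(g, v))$score,
                  numeric(1))
  start_score <- sum(local)
  score <- start_score

  for (iter in seq_len(max_iter)) {
    best_gain <- 1e-9
    best_move <- NULL
    for (p in nodes) {
      for (ch in nodes) {
        if (p == ch) next
        if (has_edge(g, p, ch)) {
          # Deletion (not whitelisted).
          if (!is_whitelisted(constraints, p, ch)) {
            new_local <- local_bic(data, ch,
                                   setdiff(parents_of(g, ch), p))$score
            gain <- new_local - local[ch]
            if (gain > best_gain) {
              best_gain <- gain
              best_move <- list(op = "delete", parent = p, child = ch,
                                local_child = new_local)
            }
          }
          # Reversal (not whitelisted, not blacklisted in reverse).
          if (!is_whitelisted(constraints, p, ch) &&
              !is_blacklisted(constraints, ch, p)) {
            g2 <- add_edge(remove_edge(g, p, ch), ch, p)
            if (is_acyclic(g2)) {
              new_ch <- local_bic(data, ch, parents_of(g2, ch))$score
              new_p <- local_bic(data, p, parents_of(g2, p))$score
              gain <- (new_ch + new_p) - (local[ch] + local[p])
              if (gain > best_gain) {
                best_gain <- gain
                best_move <- list(op = "reverse", parent = p, child = ch,
                                  local_child = new_ch, local_parent = new_p)
              }
            }
          }
        } else if (!is_blacklisted(constraints, p, ch) &&
                     !has_edge(g, ch, p)) {
          # Addition.
          g2 <- add_edge(g, p, ch)
          if (is_acyclic(g2)) {
            new_local <- local_bic(data, ch, parents_of(g2, ch))$score
            gain <- new_local - local[ch]
            if (gain > best_gain) {
              best_gain <- gain
              best_move <- list(op = "add", parent = p, child = ch,
                                local_child = new_local)
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    if (best_move$op == "add") {
      g <- add_edge(g, best_move$parent, best_move$child)
    } else if (best_move$op == "delete") {
      g <- remove_edge(g, best_move$parent, best_move$child)
    } else {
      g <- add_edge(remove_edge(g, best_move$parent, best_move$child),
                    best_move$child, best_move$parent)
      local[best_move$parent] <- best_move$local_parent
    }
    local[best_move$child] <- best_move$local_child
    score <- score + best_gain
  }
  attr(g, "score") <- sum(local)
  attr(g, "start_score") <- start_score
  g
}

#' Bootstrap edge and direction probabilities with a consensus graph
#'
#' Runs [hill_climb()] on `n_boot` nonparametric row-resamples of the data
#' and tallies, for every ordered node pair, the fraction of replicates in
#' which the adjacency is present (`presence_prob`, direction ignored) and
#' the fraction of those in which it points the stated way
#' (`direction_prob`; the two orientations of one adjacency sum to 1). The
#' consensus graph keeps adjacencies with `presence_prob >= threshold`,
#' oriented by majority direction; rare cycles are broken by dropping the
#' lowest-presence edge.
#'
#' @param data numeric matrix or data.frame (columns are the nodes).
#' @param constraints an [edge_constraints()] or NULL.
#' @param n_boot bootstrap replicates (default 1000).
#' @param threshold presence probability required for a consensus edge
#'   (default 0.8).
#' @param seed master RNG seed; per-replicate seeds derive from it.
#' @return List with `support` (data.frame `parent`, `child`,
#'   `presence_prob`, `direction_prob`, `n_boot`) and `consensus`
#'   (a [dag()]).
#' @export
bootstrap_edges <- function(data, constraints = NULL, n_boot = 1000,
                            threshold = 0.8, seed = 1L) {
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  data <- as.matrix(data)
  nodes <- colnames(data)
  constraints <- constraints %||% edge_constraints()
  seeds <- derive_seeds(seed, n_boot)

  counts <- new.env(parent = emptyenv())
  bump <- function(key) {
    assign(key, (get0(key, envir = counts) %||% 0L) + 1L, envir = counts)
  }
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b], sample.int(nrow(data), replace = TRUE))
    g <- hill_climb(data[idx, , drop = FALSE], constraints)
    if (nrow(g$edges)) {
      apply(g$edges, 1, function(e) bump(paste(e[1], e[2], sep = "\r")))
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(list(support = data.frame(parent = character(0),
                                     child = character(0),
                                     presence_prob = numeric(0),
                                     direction_prob = numeric(0),
                                     n_boot = integer(0)),
                consensus = dag(nodes)))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  dir_count <- vapply(keys, function(k) as.numeric(get(k, envir = counts)),
                      numeric(1))
  # Expand to both orientations of every observed adjacency.
  adj_key <- apply(parts, 1, function(e) paste(sort(e), collapse = "\r"))
  adj_total <- tapply(dir_count, adj_key, sum)

  all_pairs <- unique(rbind(parts, parts[, 2:1, drop = FALSE]))
  support <- data.frame(parent = all_pairs[, 1], child = all_pairs[, 2],
                        stringsAsFactors = FALSE)
  sup_adj_key <- apply(all_pairs, 1, function(e) paste(sort(e), collapse = "\r"))
  sup_dir_key <- paste(all_pairs[, 1], all_pairs[, 2], sep = "\r")
  present <- as.numeric(adj_total[sup_adj_key])
  this_dir <- vapply(sup_dir_key,
                     function(k) as.numeric(get0(k, envir = counts) %||% 0L),
                     numeric(1))
  support$presence_prob <- present / n_boot
  support$direction_prob <- this_dir / present
  support$n_boot <- n_boot
  rownames(support) <- NULL
  support <- support[order(-support$presence_prob, support$parent,
                           support$child), ]

  keep <- support[support$presence_prob >= threshold &
                    support$direction_prob > 0.5, , drop = FALSE]
  # Ties at exactly 0.5 are oriented lexicographically, once per adjacency.
  tied <- support[support$presence_prob >= threshold &
                    support$direction_prob == 0.5 &
                    support$parent < support$child, , drop = FALSE]
  keep <- rbind(keep, tied)
  consensus_edges <- as.matrix(keep[, c("parent", "child")])
  # Break rare cycles by dropping the lowest-presence edge until acyclic.
  repeat {
    g_try <- list(nodes = nodes, edges = consensus_edges)
    if (is_acyclic(g_try)) break
    drop <- which.min(keep$presence_prob)
    keep <- keep[-drop, , drop = FALSE]
    consensus_edges <- as.matrix(keep[, c("parent", "child")])
  }
  list(support = support, consensus = dag(nodes, consensus_edges))
}

#' Write a DAG as an edge-list TSV
#' @param g a [dag()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_dag <- function(g, path) {
  utils::write.table(as.data.frame(g$edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a DAG in a minimal DOT dialect
#' @param g a [dag()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_dot <- function(g, path) {
  lines <- c("digraph {",
             paste0("  \"", g$nodes, "\";"),
             if (nrow(g$edges)) paste0("  \"", g$edges[, 1], "\" -> \"",
                                       g$edges[, 2], "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}
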