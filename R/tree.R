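#' Cohort-level trajectory tree of most likely progressions
#'
#' Groups the cohort's samples by identical genotype, reconstructs the
#' most likely chronological event order of every genotype shared by at
#' least \code{min_count} patients, and merges the resulting root-to-leaf
#' paths by common prefix into a rooted tree.  The root is the healthy
#' state; every node is a prefix of some reconstruction; node and edge
#' counts are the total number of patients whose path passes through;
#' terminal nodes mark where an observed cohort genotype's ordering ends
#' (a leaf, or an internal node drawn with a black outline in the DOT
#' export).
#'
#' @inheritParams log_likelihood
#' @param min_count minimum number of patients sharing a genotype for it
#'   to enter the tree (default 3).
#' @return an object of class \code{"mhn_tree"}: list with data frames
#'   \code{nodes} (\code{id}, \code{prefix}, \code{event} of the incoming
#'   edge, \code{count}, \code{terminal}, \code{terminal_count}) and
#'   \code{edges} (\code{from}, \code{to}, \code{event}, \code{count}),
#'   plus \code{n_patients}, the number of patients represented.
#' @export
trajectory_tree <- function(model, data, min_count = 3L) {
  data <- validate_dataset(data, events = model$events)
  agg <- aggregate_dataset(data)
  keep <- which(agg$counts >= min_count)
  env <- new.env(parent = emptyenv())
  env$prefix <- ""            # node prefixes, node 1 = root
  env$event <- NA_character_  # label of incoming edge
  env$count <- 0L
  env$terminal <- FALSE
  env$terminal_count <- 0L
  env$edge_from <- integer(0)
  env$edge_to <- integer(0)
  env$edge_event <- character(0)
  env$edge_count <- integer(0)
  for (u in keep) {
    cnt <- agg$counts[u]
    ord <- most_likely_order(model, agg$genotypes[u, ])$ordering
    env$count[1L] <- env$count[1L] + cnt
    node <- 1L
    for (s in seq_along(ord)) {
      pfx <- paste(ord[seq_len(s)], collapse = "|")
      at <- match(pfx, env$prefix)
      if (is.na(at)) {
        env$prefix <- c(env$prefix, pfx)
        env$event <- c(env$event, ord[s])
        env$count <- c(env$count, 0L)
        env$terminal <- c(env$terminal, FALSE)
        env$terminal_count <- c(env$terminal_count, 0L)
        at <- length(env$prefix)
        env$edge_from <- c(env$edge_from, node)
        env$edge_to <- c(env$edge_to, at)
        env$edge_event <- c(env$edge_event, ord[s])
        env$edge_count <- c(env$edge_count, 0L)
      }
      ei <- which(env$edge_to == at)
      env$edge_count[ei] <- env$edge_count[ei] + cnt
      env$count[at] <- env$count[at] + cnt
      node <- at
    }
    env$terminal[node] <- TRUE
    env$terminal_count[node] <- env$terminal_count[node] + cnt
  }
  nodes <- data.frame(id = paste0("n", seq_along(env$prefix) - 1L),
                      prefix = env$prefix,
                      event = env$event,
                      count = env$count,
                      terminal = env$terminal,
                      terminal_count = env$terminal_count,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = nodes$id[env$edge_from],
                      to = nodes$id[env$edge_to],
                      event = env$edge_event,
                      count = env$edge_count,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 n_patients = sum(agg$counts[keep]),
                 min_count = min_count),
            class = "mhn_tree")
}

#' @export
print.mhn_tree <- function(x, ...) {
  cat(sprintf(
    "trajectory tree: %d nodes, %d edges, %d patients (genotypes with >= %d patients)\n",
    nrow(x$nodes), nrow(x$edges), x$n_patients, x$min_count))
  invisible(x)
}

#' Export a trajectory tree
#'
#' \code{write_tree_dot} writes the tree in DOT graph format: node size
#' and edge width scale linearly with patient counts, the root is a white
#' circle, and nodes where a cohort genotype's reconstruction ends carry a
#' black outline.  \code{write_tree_json} writes
#' \code{\{nodes: [\{id, prefix, count, terminal\}], edges: [\{from, to,
#' event, count\}]\}}.
#'
#' @param tree an \code{"mhn_tree"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "mhn_tree"))
  nd <- tree$nodes
  ed <- tree$edges
  cmax <- max(nd$count, 1L)
  lines <- c("digraph trajectories {",
             "  rankdir=TB;",
             "  node [shape=circle, style=filled, fixedsize=true];")
  for (i in seq_len(nrow(nd))) {
    root <- i == 1L
    width <- 0.3 + 0.9 * nd$count[i] / cmax
    lines <- c(lines, sprintf(
      '  %s [label="%s", width=%.3f, fillcolor="%s", color="%s", penwidth=%.1f, tooltip="%d patients"];',
      nd$id[i],
      if (root) "" else nd$event[i],
      width,
      if (root) "white" else "lightsteelblue",
      if (nd$terminal[i]) "black" else "gray60",
      if (nd$terminal[i]) 2.5 else 1.0,
      nd$count[i]))
  }
  emax <- max(ed$count, 1L)
  for (i in seq_len(nrow(ed))) {
    lines <- c(lines, sprintf(
      '  %s -> %s [penwidth=%.3f, label="%d"];',
      ed$from[i], ed$to[i], 0.5 + 4.5 * ed$count[i] / emax, ed$count[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tree_dot
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "mhn_tree"))
  obj <- list(
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i)
      list(id = tree$nodes$id[i],
           prefix = tree$nodes$prefix[i],
           count = tree$nodes$count[i],
           terminal = tree$nodes$terminal[i],
           terminal_count = tree$nodes$terminal_count[i])),
    edges = lapply(seq_len(nrow(tree$edges)), function(i)
      list(from = tree$edges$from[i],
           to = tree$edges$to[i],
           event = tree$edges$event[i],
           count = tree$edges$count[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
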