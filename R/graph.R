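#' Typed concept graph
#'
#' The knowledge base is a three-tier structure: terms link to concepts
#' (CUIs), concepts link to semantic types, and typed undirected edges
#' connect concepts (e.g. `"is-a"`, `"cause-of"`). Path queries run over
#' the concept tier only; the term and type tiers are stored and exposed
#' read-only.
#'
#' On construction, self-loops are dropped and identical `(a, b, type)`
#' triples are deduplicated treating `(a, b)` and `(b, a)` as equal.
#' Parallel edges with distinct relation types are kept. Loading is
#' order-independent: permuting input rows yields an identical graph.
#'
#' @param edges data.frame with columns `cui_a`, `cui_b`, `relation_type`.
#' @param concepts optional character vector of concept ids to declare in
#'   addition to edge endpoints (isolated concepts).
#' @param term_tier optional data.frame `term`, `cui`.
#' @param type_tier optional data.frame `cui`, `semantic_type`.
#' @return an object of class `ade_concept_graph` with elements `concepts`,
#'   `edges` (canonicalized: `cui_a < cui_b`), `adjacency` (named list of
#'   sorted neighbor vectors), `edge_types` (named list keyed
#'   `"a\rb"`), `term_tier`, `type_tier`.
#' @export
concept_graph <- function(edges, concepts = character(), term_tier = NULL,
                          type_tier = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("cui_a", "cui_b", "relation_type") %in% names(edges)))
  edges$cui_a <- as.character(edges$cui_a)
  edges$cui_b <- as.character(edges$cui_b)
  edges$relation_type <- as.character(edges$relation_type)
  edges <- edges[edges$cui_a != edges$cui_b, c("cui_a", "cui_b",
                                               "relation_type")]
  if (nrow(edges)) {
    lo <- pmin(edges$cui_a, edges$cui_b)
    hi <- pmax(edges$cui_a, edges$cui_b)
    edges$cui_a <- lo
    edges$cui_b <- hi
    edges <- edges[!duplicated(edges), ]
    edges <- edges[order(edges$cui_a, edges$cui_b, edges$relation_type), ]
  }
  rownames(edges) <- NULL
  concepts <- sort(unique(c(as.character(concepts), edges$cui_a,
                            edges$cui_b)))
  adjacency <- lapply(
    split(c(edges$cui_b, edges$cui_a), c(edges$cui_a, edges$cui_b)),
    function(x) sort(unique(x)))
  ekey <- paste(edges$cui_a, edges$cui_b, sep = "\r")
  edge_types <- lapply(split(edges$relation_type, ekey), function(x) {
    sort(unique(x))
  })
  structure(list(concepts = concepts, edges = edges, adjacency = adjacency,
                 edge_types = edge_types,
                 term_tier = term_tier, type_tier = type_tier),
            class = "ade_concept_graph")
}

#' @export
print.ade_concept_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("<ade_concept_graph>", s$concept_count, "concepts,", s$edge_count,
      "typed edges (", s$relation_type_count, "relation types,",
      s$isolated_concept_count, "isolated concepts )\n")
  invisible(x)
}

#' Graph bookkeeping summary
#'
#' @param graph an [concept_graph()].
#' @return list with `concept_count`, `edge_count` (typed triples),
#'   `relation_type_count`, `isolated_concept_count`, `degree_median`.
#' @export
graph_summary <- function(graph) {
  deg <- vapply(graph$concepts, function(c) {
    length(graph$adjacency[[c]] %||% character())
  }, integer(1L))
  list(concept_count = length(graph$concepts),
       edge_count = nrow(graph$edges),
       relation_type_count = length(unique(graph$edges$relation_type)),
       isolated_concept_count = sum(deg == 0L),
       degree_median = if (length(deg)) stats::median(deg) else NA_real_)
}

#' Load a concept graph from a relation table
#'
#' Accepts TSV rows `cui_a TAB cui_b TAB relation_type`, or RRF-style
#' pipe-delimited rows with configurable 0-based column indices (defaults
#' match the public relations-table layout: first CUI at column 0, relation
#' label at column 7, second CUI at column 4). Malformed rows are collected
#' as warnings with line numbers, not fatal.
#'
#' @param file path or character vector of lines.
#' @param format `"tsv"` or `"rrf"`.
#' @param rrf_cui1_col,rrf_cui2_col,rrf_type_col 0-based columns for RRF.
#' @param concepts optional isolated-concept declarations.
#' @return an [concept_graph()]; skipped line numbers are attached as
#'   attribute `"parse_errors"`.
#' @export
load_concept_graph <- function(file, format = c("tsv", "rrf"),
                               rrf_cui1_col = 0L, rrf_type_col = 7L,
                               rrf_cui2_col = 4L, concepts = character()) {
  format <- match.arg(format)
  lines <- read_lines_arg(file)
  sep <- if (format == "tsv") "\t" else "|"
  cols <- if (format == "tsv") c(1L, 2L, 3L) else {
    c(rrf_cui1_col, rrf_cui2_col, rrf_type_col) + 1L
  }
  parts <- strsplit(lines, sep, fixed = TRUE)
  ok <- vapply(parts, length, 0L) >= max(cols)
  errors <- character()
  if (any(!ok)) {
    errors <- sprintf("line %d: fewer than %d fields", which(!ok), max(cols))
    warning(length(errors), " malformed relation row(s) skipped")
  }
  edges <- new_df(
    cui_a = vapply(parts[ok], `[[`, "", cols[1L]),
    cui_b = vapply(parts[ok], `[[`, "", cols[2L]),
    relation_type = vapply(parts[ok], `[[`, "", cols[3L]))
  g <- concept_graph(edges, concepts = concepts)
  attr(g, "parse_errors") <- errors
  g
}

## ---------------------------------------------------------------------------
## Distance and shortest paths

#' Shortest-path distance between two concepts
#'
#' Breadth-first search over undirected edges. `distance(a, a)` is 0; an
#' unknown concept or a disconnected pair yields `Inf`. When `horizon` is
#' finite the search stops beyond it and returns `Inf` (beyond-horizon),
#' which bounds cost on dense hub concepts.
#'
#' @param graph an [concept_graph()].
#' @param cui_a,cui_b concept identifiers.
#' @param horizon maximum depth to explore (`Inf` = unbounded).
#' @return a nonnegative integer distance, or `Inf`.
#' @export
graph_distance <- function(graph, cui_a, cui_b, horizon = Inf) {
  if (identical(cui_a, cui_b)) {
    return(if (cui_a %in% graph$concepts) 0L else Inf)
  }
  if (!(cui_a %in% graph$concepts) || !(cui_b %in% graph$concepts)) {
    return(Inf)
  }
  dist <- bfs_levels(graph, cui_a, horizon, stop_at = cui_b)
  dist[[cui_b]] %||% Inf
}

# BFS level sets from `source` up to `horizon`; returns an environment-free
# named list cui -> depth. Stops early once `stop_at` is settled.
bfs_levels <- function(graph, source, horizon = Inf, stop_at = NULL) {
  depth <- new.env(parent = emptyenv())
  assign(source, 0L, envir = depth)
  frontier <- source
  d <- 0L
  while (length(frontier) && d < horizon) {
    d <- d + 1L
    nxt <- character()
    for (v in frontier) {
      for (w in graph$adjacency[[v]] %||% character()) {
        if (!exists(w, envir = depth, inherits = FALSE)) {
          assign(w, d, envir = depth)
          nxt <- c(nxt, w)
        }
      }
    }
    if (!is.null(stop_at) &&
        exists(stop_at, envir = depth, inherits = FALSE)) {
      break
    }
    frontier <- nxt
  }
  as.list(depth)
}

#' Enumerate shortest paths with their relation types
#'
#' Finds the shortest-path distance between two concepts and enumerates up
#' to `path_cap` distinct shortest paths in deterministic order (neighbors
#' visited in lexicographic CUI order). Each hop of a path contributes the
#' set of relation types of all parallel edges on that hop. There may be
#' multiple shortest paths but only one shortest path length.
#'
#' @param graph an [concept_graph()].
#' @param cui_a,cui_b concept identifiers.
#' @param horizon maximum distance considered (beyond it the pair counts as
#'   unreachable).
#' @param path_cap maximum number of shortest paths to enumerate.
#' @return list of class `ade_path_summary`: `distance` (integer or `Inf`),
#'   `paths` (list of paths; a path is a list of character vectors, one
#'   type-set per hop), `nodes` (list of node sequences, parallel to
#'   `paths`), `truncated` (TRUE when more shortest paths exist than
#'   `path_cap`). `paths` is empty iff `distance` is `Inf` or 0.
#' @export
shortest_path_summary <- function(graph, cui_a, cui_b, horizon = Inf,
                                  path_cap = 64L) {
  stopifnot(path_cap >= 1L)
  res <- structure(list(distance = Inf, paths = list(), nodes = list(),
                        truncated = FALSE),
                   class = "ade_path_summary")
  if (!(cui_a %in% graph$concepts) || !(cui_b %in% graph$concepts)) {
    return(res)
  }
  if (identical(cui_a, cui_b)) {
    res$distance <- 0L
    return(res)
  }
  # distances measured from the target so the forward walk can descend
  dist_b <- bfs_levels(graph, cui_b, horizon)
  d <- dist_b[[cui_a]]
  if (is.null(d)) return(res)
  res$distance <- d
  paths <- list()
  nodes <- list()
  truncated <- FALSE
  walk <- function(v, acc_nodes, acc_hops) {
    if (truncated) return(invisible())
    if (identical(v, cui_b)) {
      if (length(paths) >= path_cap) {
        truncated <<- TRUE
      } else {
        paths[[length(paths) + 1L]] <<- acc_hops
        nodes[[length(nodes) + 1L]] <<- acc_nodes
      }
      return(invisible())
    }
    dv <- dist_b[[v]]
    for (w in graph$adjacency[[v]] %||% character()) {   # lexicographic
      dw <- dist_b[[w]]
      if (is.null(dw) || dw != dv - 1L) next
      key <- paste(min(v, w), max(v, w), sep = "\r")
      walk(w, c(acc_nodes, w),
           c(acc_hops, list(graph$edge_types[[key]])))
      if (truncated) return(invisible())
    }
    invisible()
  }
  walk(cui_a, cui_a, list())
  res$paths <- paths
  res$nodes <- nodes
  res$truncated <- truncated
  res
}

#' Semantic types of a concept (read-only type-tier query)
#'
#' @param graph an [concept_graph()] built with a `type_tier`.
#' @param cui a concept identifier.
#' @return character vector of semantic-type ids (empty when unknown).
#' @export
concept_semantic_types <- function(graph, cui) {
  tt <- graph$type_tier
  if (is.null(tt)) return(character())
  sort(unique(tt$semantic_type[tt$cui == cui]))
}
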