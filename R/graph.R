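#' Build an electron-transfer graph from cofactor geometry
#'
#' Cofactors become nodes; an undirected edge joins every pair whose
#' edge-to-edge distance is at most `cutoff`. Each edge is classified by the
#' empirical tunneling thresholds: `"efficient"` at or below
#' `efficient_cutoff` (default 15 Angstrom, the per-step distance compatible
#' with fast physiological electron transfer) and `"possible"` above that up
#' to `cutoff` (default 20 Angstrom, where transfer may still occur but
#' slowly). Edges are returned in deterministic (label-sorted) order.
#'
#' @param cofactors list of `cofactor_instance`.
#' @param cutoff maximum edge distance retained, Angstrom (> 0).
#' @param efficient_cutoff efficient/possible classification threshold,
#'   Angstrom.
#' @param mode atom-set mode passed to [edge_to_edge()].
#' @return object of class `transfer_graph`: list with `nodes` (labels),
#'   `edges` (data.frame `from`, `to`, `distance_A`, `class`), `cutoff`,
#'   `efficient_cutoff`.
#' @export
build_transfer_graph <- function(cofactors, cutoff = 20,
                                 efficient_cutoff = 15,
                                 mode = c("all", "conjugated")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be > 0")
  labs <- vapply(cofactors, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("cofactor labels must be unique")
  edges <- data.frame(from = character(0), to = character(0),
                      distance_A = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (length(cofactors) >= 2L) {
    D <- distance_matrix(cofactors, mode)
    n <- length(labs)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- D[i, j]
        if (d <= cutoff) {
          pair <- sort(c(labs[i], labs[j]))
          edges <- rbind(edges, data.frame(
            from = pair[1], to = pair[2], distance_A = d,
            class = if (d <= efficient_cutoff) "efficient" else "possible",
            stringsAsFactors = FALSE))
        }
      }
    }
    if (nrow(edges) > 0L)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = labs, edges = edges, cutoff = cutoff,
                 efficient_cutoff = efficient_cutoff),
            class = "transfer_graph")
}

#' @export
print.transfer_graph <- function(x, ...) {
  cat(sprintf(
    "Electron-transfer graph: %d cofactors, %d edges (cutoff %g A, efficient <= %g A)\n",
    length(x$nodes), nrow(x$edges), x$cutoff, x$efficient_cutoff))
  if (nrow(x$edges) > 0L) print(x$edges)
  invisible(x)
}

as_igraph <- function(graph, max_distance = Inf) {
  e <- graph$edges[graph$edges$distance_A <= max_distance, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("from", "to", "distance_A")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
}

#' Bottleneck-optimal electron-transfer pathway
#'
#' Finds the path from `source_label` to `target_label` that minimizes the
#' longest single tunneling step (the bottleneck), the quantity that
#' dominates the rate of a multistep electron-transfer chain. Ties are
#' broken by fewer steps, then by lexicographic label order, so the result
#' is deterministic. A long shortcut is therefore rejected in favor of a
#' detour of shorter individual hops.
#'
#' @param graph a [build_transfer_graph()] result.
#' @param source_label,target_label node labels.
#' @return object of class `cofactor_path`: list with `disconnected`
#'   (logical), `labels` (ordered node labels; `character(0)` when source
#'   equals target), `steps` (data.frame `from`, `to`, `distance_A`,
#'   `class`), and `bottleneck_A` (maximum step distance; `NA` for an empty
#'   or missing path). No exception is raised for disconnected endpoints.
#' @export
find_path <- function(graph, source_label, target_label) {
  stopifnot(inherits(graph, "transfer_graph"))
  if (!source_label %in% graph$nodes)
    stop("unknown source node: ", source_label)
  if (!target_label %in% graph$nodes)
    stop("unknown target node: ", target_label)
  empty_steps <- graph$edges[0, , drop = FALSE]
  if (identical(source_label, target_label))
    return(structure(list(disconnected = FALSE, labels = character(0),
                          steps = empty_steps, bottleneck_A = NA_real_),
                     class = "cofactor_path"))

  # smallest edge length whose induced subgraph connects the endpoints
  cand <- sort(unique(graph$edges$distance_A))
  bottleneck <- NA_real_
  for (d in cand) {
    g <- as_igraph(graph, d)
    if (is.finite(igraph::distances(g, source_label, target_label)[1, 1])) {
      bottleneck <- d
      break
    }
  }
  if (is.na(bottleneck))
    return(structure(list(disconnected = TRUE, labels = character(0),
                          steps = empty_steps, bottleneck_A = NA_real_),
                     class = "cofactor_path"))

  # among edges within the bottleneck, walk the lexicographically smallest
  # of the fewest-step paths: greedy descent on BFS distance-to-target
  g <- as_igraph(graph, bottleneck)
  dist_to_target <- igraph::distances(g, v = igraph::V(g),
                                      to = target_label)[, 1]
  labels <- source_label
  cur <- source_label
  while (!identical(cur, target_label)) {
    nb <- names(igraph::neighbors(g, cur))
    nb <- nb[dist_to_target[nb] == dist_to_target[cur] - 1]
    cur <- sort(nb)[1]
    labels <- c(labels, cur)
  }
  key_graph <- paste(graph$edges$from, graph$edges$to)
  steps <- do.call(rbind, lapply(seq_len(length(labels) - 1L), function(i) {
    pair <- sort(c(labels[i], labels[i + 1L]))
    row <- graph$edges[match(paste(pair[1], pair[2]), key_graph), ,
                       drop = FALSE]
    row$from <- labels[i]
    row$to <- labels[i + 1L]
    row
  }))
  rownames(steps) <- NULL
  structure(list(disconnected = FALSE, labels = labels, steps = steps,
                 bottleneck_A = max(steps$distance_A)),
            class = "cofactor_path")
}

#' @export
print.cofactor_path <- function(x, ...) {
  if (x$disconnected) {
    cat("Pathway: disconnected (no route within the distance cutoff)\n")
  } else if (length(x$labels) == 0L) {
    cat("Pathway: source equals target (empty path)\n")
  } else {
    cat(sprintf("Pathway (%d steps, bottleneck %.2f A):\n",
                nrow(x$steps), x$bottleneck_A))
    cat(" ", paste(x$labels, collapse = " -> "), "\n")
    print(x$steps)
  }
  invisible(x)
}

#' Minimum edge-to-edge distance between two groups of cofactors
#'
#' Convenience for questions of the form "how closely does any heme of the
#' soluble multiheme cytochrome approach the membrane-embedded cofactors":
#' the minimum of [edge_to_edge()] over all cross pairs of the two label
#' sets. Intended for integration checks on full structural models supplied
#' by the user; nothing is downloaded.
#'
#' @param cofactors list of `cofactor_instance`.
#' @param labels_a,labels_b disjoint character vectors of cofactor labels.
#' @param mode passed to [edge_to_edge()].
#' @return list with `distance_A`, `pair` (the closest labels).
#' @export
group_min_distance <- function(cofactors, labels_a, labels_b,
                               mode = c("all", "conjugated")) {
  mode <- match.arg(mode)
  labs <- vapply(cofactors, `[[`, character(1), "label")
  if (!all(labels_a %in% labs) || !all(labels_b %in% labs))
    stop("unknown cofactor label(s): ",
         paste(setdiff(c(labels_a, labels_b), labs), collapse = ", "))
  if (length(intersect(labels_a, labels_b)) > 0L)
    stop("label groups must be disjoint")
  best <- list(distance_A = Inf, pair = c(NA_character_, NA_character_))
  for (la in labels_a) {
    for (lb in labels_b) {
      d <- edge_to_edge(cofactors[[match(la, labs)]],
                        cofactors[[match(lb, labs)]], mode)
      if (d < best$distance_A)
        best <- list(distance_A = d, pair = c(la, lb))
    }
  }
  best
}

#' Write a transfer graph as an edge-list TSV
#'
#' @param graph a [build_transfer_graph()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_graph_tsv <- function(graph, file) {
  stopifnot(inherits(graph, "transfer_graph"))
  utils::write.table(graph$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
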