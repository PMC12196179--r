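#' Protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph over gene-symbol nodes with
#' a confidence score in \[0, 1\] on each edge. Self-loops and parallel
#' edges are disallowed; edges are stored with `from < to` lexicographically.
#'
#' @param edges data frame with columns `from`, `to`, `confidence`.
#' @return object of class `ppi_network` with elements `nodes` (character)
#'   and `edges` (tibble).
#' @export
ppi_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("from", "to", "confidence") %in% names(edges))) {
    stop_validation("`edges` must have columns from, to, confidence")
  }
  edges <- tibble::as_tibble(edges)
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop_validation("edge confidence must lie in [0, 1]")
  }
  if (any(edges$from == edges$to)) stop_validation("self-loops are not allowed")
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- tibble::tibble(from = a, to = b, confidence = edges$confidence) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  structure(
    list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a `ppi_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Build a confidence-filtered PPI network from a scored edge list
#'
#' Reads a STRING-style edge list (`node1 node2 score`), normalizes the
#' score dialect (the 0-1000 integer convention is auto-detected and mapped
#' to \[0, 1\]), drops edges at or below the confidence threshold, collapses
#' parallel edges and self-loops, and removes nodes left without any edge.
#'
#' @param edges data frame whose first three columns are the two endpoint
#'   gene symbols and the interaction score.
#' @param min_confidence confidence threshold (default 0.4).
#' @param strict if `TRUE` (default) keep edges with confidence strictly
#'   greater than the threshold; if `FALSE`, greater or equal.
#' @param largest_component if `TRUE`, additionally restrict the network to
#'   its largest connected component (default keeps every non-isolated
#'   node).
#' @return a [ppi_network()].
#' @export
build_ppi_network <- function(edges, min_confidence = 0.4, strict = TRUE,
                              largest_component = FALSE) {
  if (!is.data.frame(edges) || ncol(edges) < 3 || nrow(edges) == 0) {
    stop_validation("`edges` must be a nonempty data frame with >= 3 columns")
  }
  e <- tibble::tibble(
    from = toupper(trimws(as.character(edges[[1]]))),
    to = toupper(trimws(as.character(edges[[2]]))),
    score = suppressWarnings(as.numeric(edges[[3]]))
  )
  bad <- which(is.na(e$score) | e$from == "" | e$to == "")
  if (length(bad) > 0) {
    stop_validation(sprintf("malformed edge row(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(e$score < 0) || any(e$score > 1000)) {
    stop_validation("edge scores must lie in [0, 1] or the 0-1000 STRING dialect")
  }
  if (any(e$score > 1)) e$score <- e$score / 1000
  keep <- if (strict) e$score > min_confidence else e$score >= min_confidence
  e <- e[keep & e$from != e$to, , drop = FALSE]
  if (nrow(e) == 0) {
    warn("no edges survive the confidence filter; returning an empty network")
    return(structure(
      list(nodes = character(0), edges = tibble::tibble(
        from = character(0), to = character(0), confidence = numeric(0)
      )),
      class = "ppi_network"
    ))
  }
  net <- ppi_network(tibble::tibble(from = e$from, to = e$to, confidence = e$score))
  if (largest_component) net <- induce_subnetwork(net, largest_component_nodes(net))
  net
}

# adjacency list of integer neighbor indices, aligned with net$nodes
adjacency_list <- function(net) {
  n <- length(net$nodes)
  idx_from <- match(net$edges$from, net$nodes)
  idx_to <- match(net$edges$to, net$nodes)
  adj <- vector("list", n)
  for (k in seq_along(idx_from)) {
    adj[[idx_from[k]]] <- c(adj[[idx_from[k]]], idx_to[k])
    adj[[idx_to[k]]] <- c(adj[[idx_to[k]]], idx_from[k])
  }
  adj
}

largest_component_nodes <- function(net) {
  n <- length(net$nodes)
  if (n == 0) return(character(0))
  adj <- adjacency_list(net)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  net$nodes[comp == which.max(tabulate(comp))]
}

induce_subnetwork <- function(net, nodes) {
  keep <- net$edges$from %in% nodes & net$edges$to %in% nodes
  edges <- net$edges[keep, , drop = FALSE]
  structure(
    list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges),
    class = "ppi_network"
  )
}

#' Degree, betweenness and closeness centralities
#'
#' Computes, for every node of an unweighted undirected network (edge
#' confidences are used only for filtering, never for path lengths):
#'
#' * `dc` — degree, the number of incident edges;
#' * `bc` — shortest-path betweenness (Brandes' algorithm), each unordered
#'   pair counted once, path endpoints excluded, unnormalized raw pair
#'   counts;
#' * `cc` — closeness normalized to \[0, 1\]: with `r` reachable nodes and
#'   total distance `S` to them, `cc = (r / S) * (r / (n - 1))`, which on a
#'   connected graph reduces to the standard `(n - 1) / S` and degrades
#'   gracefully on disconnected ones.
#'
#' @param net a [ppi_network()].
#' @return tibble with columns `node`, `dc`, `bc`, `cc`.
#' @export
centralities <- function(net) {
  if (!inherits(net, "ppi_network")) stop_validation("`net` must be a ppi_network")
  n <- length(net$nodes)
  if (n == 0) stop_validation("cannot compute centralities of an empty network")
  if (n == 1) {
    return(tibble::tibble(node = net$nodes, dc = 0L, bc = 0, cc = 0))
  }
  adj <- adjacency_list(net)
  dc <- vapply(adj, length, integer(1))
  bc <- numeric(n)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    # single-source BFS with Brandes path counting
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(n)
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    nv <- 0L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nv <- nv + 1L
      order_visited[nv] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    reached <- dist > 0L
    r <- sum(reached)
    total_d <- sum(dist[reached])
    cc[s] <- if (r > 0) (r / total_d) * (r / (n - 1)) else 0
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (i in rev(seq_len(nv))) {
      v <- order_visited[i]
      for (p in preds[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  tibble::tibble(node = net$nodes, dc = dc, bc = bc / 2, cc = cc)
}

#' Intersect compound targets with disease genes
#'
#' The union of the per-compound predicted target sets is intersected with
#' the curated disease gene set (the Venn overlap of the two universes).
#' Gene symbols are uppercased and deduplicated before counting.
#'
#' @param compound_targets either a named list of gene-symbol vectors (one
#'   element per compound) or a two-column data frame (`compound`, `gene`).
#' @param disease_genes character vector of disease-associated gene symbols.
#' @return list with `counts` (tibble: `n_compound_union`, `n_disease`,
#'   `n_overlap`) and `overlap` (sorted gene symbols).
#' @export
intersect_targets <- function(compound_targets, disease_genes) {
  if (is.data.frame(compound_targets)) {
    if (ncol(compound_targets) < 2) {
      stop_validation("data-frame mapping needs columns compound, gene")
    }
    compound_targets <- split(
      as.character(compound_targets[[2]]),
      as.character(compound_targets[[1]])
    )
  }
  if (!is.list(compound_targets) || length(compound_targets) == 0) {
    stop_validation("`compound_targets` must be a nonempty list or data frame")
  }
  union_set <- sort(unique(toupper(unlist(compound_targets, use.names = FALSE))))
  disease <- sort(unique(toupper(disease_genes)))
  if (length(union_set) == 0 || length(disease) == 0) {
    stop_validation("compound target union and disease set must be nonempty")
  }
  overlap <- intersect(union_set, disease)
  list(
    counts = tibble::tibble(
      n_compound_union = length(union_set),
      n_disease = length(disease),
      n_overlap = length(overlap)
    ),
    overlap = overlap
  )
}

#' First-tier hub filter: degree at least a multiple of the median
#'
#' Retains nodes whose degree is at least `multiplier` times the median
#' degree of the network, induces the subgraph on them, and drops any node
#' left isolated by the induction. The realized threshold is recorded on the
#' result.
#'
#' @param net a [ppi_network()].
#' @param multiplier degree-threshold multiplier (default 2, i.e. twice the
#'   median degree; 0 is the identity filter).
#' @return list of class `tier1_screen`: `network` (induced subnetwork),
#'   `dc_threshold` (realized threshold), `median_dc`, and `table` (the
#'   centrality table the filter was computed on).
#' @export
tier1_screen <- function(net, multiplier = 2) {
  tab <- centralities(net)
  med <- median(tab$dc)
  thr <- multiplier * med
  keep <- tab$node[tab$dc >= thr]
  sub <- induce_subnetwork(net, keep)
  if (length(sub$nodes) == 0) {
    warn("tier-1 screen removed every node; returning an empty network")
  }
  structure(
    list(network = sub, dc_threshold = thr, median_dc = med, table = tab),
    class = "tier1_screen"
  )
}

#' Apply explicit hub thresholds to a centrality table
#'
#' Retains rows with `bc >= bc_min`, `cc >= cc_min` and `dc >= dc_min`
#' simultaneously, ranked by degree (descending), ties broken by
#' betweenness (descending) then node name.
#'
#' @param table data frame with columns `node`, `dc`, `bc`, `cc`.
#' @param bc_min,cc_min,dc_min inclusive lower thresholds.
#' @return filtered, ranked tibble.
#' @export
apply_hub_thresholds <- function(table, bc_min, cc_min, dc_min) {
  if (!is.data.frame(table) || !all(c("node", "dc", "bc", "cc") %in% names(table))) {
    stop_validation("`table` must have columns node, dc, bc, cc")
  }
  tibble::as_tibble(table) |>
    dplyr::filter(.data$bc >= bc_min, .data$cc >= cc_min, .data$dc >= dc_min) |>
    dplyr::arrange(dplyr::desc(.data$dc), dplyr::desc(.data$bc), .data$node)
}

#' Second-tier hub filter: joint median thresholds on BC, CC and DC
#'
#' Recomputes all three centralities on the (tier-1) subnetwork, takes the
#' median of each as its threshold, and retains nodes meeting or exceeding
#' all three medians. Core nodes are ranked by degree descending, ties by
#' betweenness descending then name.
#'
#' @param subnet a [ppi_network()] (typically the `network` element of a
#'   [tier1_screen()] result, which is also accepted directly).
#' @return list of class `hub_screen`: `core` (ranked tibble of surviving
#'   nodes with their centralities), `thresholds` (named list `bc_min`,
#'   `cc_min`, `dc_min` as applied), and `table` (full subnetwork centrality
#'   table).
#' @export
tier2_screen <- function(subnet) {
  if (inherits(subnet, "tier1_screen")) subnet <- subnet$network
  if (!inherits(subnet, "ppi_network")) stop_validation("`subnet` must be a ppi_network")
  if (length(subnet$nodes) < 2) {
    stop_validation("tier-2 screen needs a network with at least two nodes")
  }
  tab <- centralities(subnet)
  thr <- list(bc_min = median(tab$bc), cc_min = median(tab$cc), dc_min = median(tab$dc))
  core <- apply_hub_thresholds(tab, thr$bc_min, thr$cc_min, thr$dc_min)
  structure(list(core = core, thresholds = thr, table = tab), class = "hub_screen")
}

#' @export
print.hub_screen <- function(x, ...) {
  cat(sprintf(
    "<hub_screen> %d core nodes (BC >= %.2f, CC >= %.3f, DC >= %g)\n",
    nrow(x$core), x$thresholds$bc_min, x$thresholds$cc_min, x$thresholds$dc_min
  ))
  print(utils::head(as.data.frame(x$core), 10), row.names = FALSE)
  invisible(x)
}

#' Two-tier median hub screen
#'
#' Convenience wrapper running [tier1_screen()] (degree at least
#' `multiplier` times the median) followed by [tier2_screen()] (joint
#' median thresholds on the recomputed subnetwork centralities).
#'
#' @inheritParams tier1_screen
#' @return list with elements `tier1` and `tier2`.
#' @export
hub_screen <- function(net, multiplier = 2) {
  t1 <- tier1_screen(net, multiplier = multiplier)
  list(tier1 = t1, tier2 = tier2_screen(t1$network))
}

#' Rank compounds by degree in a compound-target bipartite network
#'
#' Each compound's score is its number of distinct targets. The cutoff is
#' the median compound score; compounds at or above it form the core set,
#' ranked by score descending with ties broken by name.
#'
#' @param x either a bipartite edge list (data frame with columns
#'   `compound` and `target`, one row per interaction) or a precomputed
#'   score table (columns `compound` and `score`).
#' @return list with `ranking` (tibble: `compound`, `score`, `core`),
#'   `cutoff` (the median score) and `core` (character vector of core
#'   compounds in rank order).
#' @export
ct_degree_rank <- function(x) {
  if (!is.data.frame(x) || nrow(x) == 0) {
    stop_validation("`x` must be a nonempty data frame")
  }
  if (all(c("compound", "target") %in% names(x))) {
    scores <- x |>
      dplyr::distinct(.data$compound, .data$target) |>
      dplyr::count(.data$compound, name = "score")
  } else if (all(c("compound", "score") %in% names(x))) {
    scores <- tibble::tibble(compound = x$compound, score = x$score)
  } else {
    stop_validation("`x` needs columns compound+target (edges) or compound+score")
  }
  cutoff <- median(scores$score)
  ranking <- scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$compound) |>
    dplyr::mutate(core = .data$score >= cutoff)
  list(ranking = ranking, cutoff = cutoff, core = ranking$compound[ranking$core])
}

#' Write a network as a SIF interaction file
#'
#' @param net a [ppi_network()].
#' @param path output file path.
#' @param interaction interaction type label (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, interaction = "pp") {
  lines <- sprintf("%s\t%s\t%s", net$edges$from, interaction, net$edges$to)
  writeLines(lines, path)
  invisible(path)
}
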