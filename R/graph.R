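#' Heterogeneous graph with structural encodings
#'
#' Wraps the bipartite heterogeneous adjacency `[[0, A], [A^T, 0]]` together
#' with the structural quantities consumed by the transformer channel: the
#' per-node degree vector and the clipped shortest-path-distance (SPD) matrix.
#' Finite distances longer than `spd_clip` are clipped to `spd_clip`;
#' unreachable pairs are stored as the sentinel `spd_clip + 1`.
#'
#' @param assoc An [association_matrix()].
#' @param spd_clip Maximum path length retained (default 8).
#' @return An object of class `mda_graph` with elements `adjacency`,
#'   `degrees`, `spd`, `spd_clip`, `unreachable_code`, `node_ids`, `M`, `N`.
#' @export
hetero_graph <- function(assoc, spd_clip = 8L) {
  spd_clip <- as.integer(spd_clip)
  if (spd_clip < 1L) stop("spd_clip must be >= 1")
  G <- hetero_adjacency(assoc)
  deg <- as.integer(rowSums(G))
  spd <- shortest_path_matrix(G, clip = spd_clip)
  structure(list(adjacency = G, degrees = deg, spd = spd,
                 spd_clip = spd_clip, unreachable_code = spd_clip + 1L,
                 node_ids = rownames(G),
                 M = length(assoc$mirna_ids), N = length(assoc$disease_ids)),
            class = "mda_graph")
}

#' @export
print.mda_graph <- function(x, ...) {
  cat(sprintf("<mda_graph> %d nodes (%d miRNA + %d disease), %d edges, SPD clip %d\n",
              x$M + x$N, x$M, x$N, sum(x$adjacency) / 2, x$spd_clip))
  invisible(x)
}

#' Node degrees and degree summaries
#'
#' @param g An `mda_graph`.
#' @return List with `degrees` (integer vector), `mean_degree` (2E/(M+N)),
#'   `mean_degree_mirna` (E/M), `mean_degree_disease` (E/N), and
#'   `centrality` = degree / (M+N-1) per node.
#' @export
degree_vector <- function(g) {
  E <- sum(g$adjacency) / 2
  n <- g$M + g$N
  list(degrees = g$degrees,
       mean_degree = 2 * E / n,
       mean_degree_mirna = E / g$M,
       mean_degree_disease = E / g$N,
       centrality = g$degrees / (n - 1))
}

#' Bipartite graph density
#' @param assoc An [association_matrix()].
#' @return `E / (M * N)`.
#' @export
graph_density <- function(assoc) {
  sum(assoc$entries) / (nrow(assoc$entries) * ncol(assoc$entries))
}

#' Clipped all-pairs shortest-path matrix
#'
#' Breadth-first search from every node of an unweighted graph. Finite
#' distances above `clip` are stored as `clip`; unreachable pairs as
#' `clip + 1`.
#'
#' @param adjacency Binary symmetric matrix.
#' @param clip Maximum retained path length.
#' @return Integer matrix with zero diagonal.
#' @export
shortest_path_matrix <- function(adjacency, clip = 8L) {
  n <- nrow(adjacency)
  clip <- as.integer(clip)
  nbrs <- apply(adjacency > 0, 1L, which, simplify = FALSE)
  spd <- matrix(clip + 1L, n, n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    dist[s] <- 0L
    frontier <- s
    level <- 0L
    while (length(frontier)) {
      level <- level + 1L
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[dist[nxt] < 0L]
      if (!length(nxt)) break
      dist[nxt] <- level
      frontier <- nxt
    }
    reach <- dist >= 0L
    spd[s, reach] <- pmin(dist[reach], clip)
  }
  dimnames(spd) <- dimnames(adjacency)
  spd
}

#' Clip node degrees into embedding-lookup buckets
#'
#' Realises the learnable degree-centrality embedding lookup: degree `k` maps
#' to bucket `min(k, max_bucket)` so the embedding table stays finite.
#'
#' @param degrees Nonnegative integer vector.
#' @param max_bucket Largest bucket index (default 64).
#' @return Integer vector of bucket indices in `0..max_bucket`.
#' @export
degree_bucket <- function(degrees, max_bucket = 64L) {
  if (max_bucket < 1L) stop("max_bucket must be >= 1")
  if (any(degrees < 0)) stop("negative degree")
  pmin(as.integer(degrees), as.integer(max_bucket))
}

#' Summary statistics of an association network
#'
#' Derived quantities of the bipartite graph: node/edge counts, density,
#' mean degrees (overall and per node family) and mean normalised degree
#' centralities, i.e. the descriptive rows usually tabulated for MDA
#' benchmark datasets.
#'
#' @param M,N,E miRNA count, disease count, association count. Alternatively
#'   pass an `mda_assoc` as `M`.
#' @return List of class `mda_stats`.
#' @export
graph_stats <- function(M, N = NULL, E = NULL) {
  if (inherits(M, "mda_assoc")) {
    assoc <- M
    M <- length(assoc$mirna_ids); N <- length(assoc$disease_ids)
    E <- sum(assoc$entries)
  }
  n <- M + N
  structure(list(
    nodes = n, nodes_mirna = M, nodes_disease = N, edges = E,
    density = E / (M * N),
    mean_degree = 2 * E / n,
    mean_degree_mirna = E / M,
    mean_degree_disease = E / N,
    centrality = (2 * E / n) / (n - 1),
    centrality_mirna = (E / M) / (n - 1),
    centrality_disease = (E / N) / (n - 1)
  ), class = "mda_stats")
}

#' @export
print.mda_stats <- function(x, ...) {
  cat(format_stats(x), sep = "\n")
  invisible(x)
}

#' Format network statistics as a tab-separated table
#' @param stats An `mda_stats` list from [graph_stats()].
#' @return Character vector of table lines.
#' @export
format_stats <- function(stats) {
  c(paste("Property", "Full Data", "miRNA", "Disease", sep = "\t"),
    paste("# nodes", stats$nodes, stats$nodes_mirna, stats$nodes_disease, sep = "\t"),
    paste("# edges", stats$edges, "-", "-", sep = "\t"),
    paste("# density", format(round(stats$density, 4L), nsmall = 4L), "-", "-", sep = "\t"),
    paste("# degree",
          format(round(stats$mean_degree, 3L), nsmall = 3L),
          format(round(stats$mean_degree_mirna, 3L), nsmall = 3L),
          format(round(stats$mean_degree_disease, 3L), nsmall = 3L), sep = "\t"),
    paste("# Ave_cen",
          format(round(stats$centrality, 4L), nsmall = 4L),
          format(round(stats$centrality_mirna, 4L), nsmall = 4L),
          format(round(stats$centrality_disease, 4L), nsmall = 4L), sep = "\t"))
}
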