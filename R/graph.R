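#' Proportional threshold of a band connectivity matrix
#'
#' Symmetrizes the directed connectivity by
#' `w_ij = max(conn[i, j], conn[j, i])`, ranks the undirected edges and
#' keeps the strongest `round(density * n * (n - 1) / 2)` of them as a
#' binary graph. Ties are broken deterministically by (weight descending,
#' row ascending, column ascending).
#'
#' @param conn square numeric matrix (target x source); the diagonal is
#'   ignored.
#' @param density fraction of possible edges to keep, in `(0, 1]`
#'   (default 0.15).
#' @return a `thresholded_graph` list: `adjacency` (symmetric binary, zero
#'   diagonal), `density`, `edge_weights` (the symmetrized weights, for
#'   provenance).
#' @export
threshold_network <- function(conn, density = 0.15) {
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn),
            density > 0, density <= 1)
  n <- nrow(conn)
  w <- pmax(conn, t(conn))
  diag(w) <- 0
  m_keep <- round(density * n * (n - 1) / 2)
  if (m_keep < 1) stop("density too small: it keeps zero edges")
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[pairs], pairs[, 1], pairs[, 2])
  sel <- pairs[ord[seq_len(min(m_keep, nrow(pairs)))], , drop = FALSE]
  adj <- matrix(0L, n, n)
  adj[sel] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = density, edge_weights = w),
            class = "thresholded_graph")
}

# all-pairs shortest path lengths of a binary undirected graph via
# breadth-first expansion of the reachability matrix (fast for the small
# dense adjacency matrices this package produces); unreachable pairs
# are Inf
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  reached <- (adj > 0) | diag(n) > 0
  for (d in 2:max(2, n - 1)) {
    new <- (reached %*% adj > 0) & !reached
    if (!any(new)) break
    D[new] <- d
    reached <- reached | new
  }
  D
}

# Brandes' betweenness for unweighted undirected graphs (unnormalized,
# each undirected path counted once)
brandes_betweenness <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer(0)
    preds <- vector("list", n)
    queue <- c(s)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # each unordered (s, t) pair counted twice
}

#' Node-level graph metrics
#'
#' Computes, for every node of a simple undirected binary graph, the six
#' local network measures used in the pipeline:
#' \describe{
#'   \item{degree}{number of neighbors.}
#'   \item{cost}{degree / (n - 1), the node's share of possible edges.}
#'   \item{clustering}{edges among neighbors / `k(k-1)/2`; 0 when the
#'     node has fewer than 2 neighbors.}
#'   \item{local_efficiency}{mean inverse shortest-path length between
#'     neighbor pairs within the neighbor-induced subgraph
#'     (Latora-Marchiori); unreachable pairs contribute 0; 0 when degree
#'     is below 2.}
#'   \item{betweenness}{fraction of all-pairs shortest paths passing
#'     through the node, normalized by `(n-1)(n-2)/2` so values lie in
#'     `[0, 1]`.}
#'   \item{avg_path_length}{mean shortest-path length from the node to
#'     the nodes it can reach (unreachable nodes excluded; `NA` for an
#'     isolated node). The reachable fraction is reported alongside so
#'     disconnected graphs never produce infinities.}
#' }
#'
#' @param graph a [threshold_network()] result or a symmetric binary
#'   adjacency matrix.
#' @return a data.frame with one row per node and columns `node`,
#'   `degree`, `cost`, `clustering`, `local_efficiency`, `betweenness`,
#'   `avg_path_length`, `reachable_frac`.
#' @export
node_metrics <- function(graph) {
  adj <- if (inherits(graph, "thresholded_graph")) graph$adjacency else graph
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj),
            all(adj %in% c(0, 1)), all(diag(adj) == 0),
            isTRUE(all.equal(adj, t(adj))))
  n <- nrow(adj)
  deg <- rowSums(adj)
  clustering <- numeric(n)
  leff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- adj[nb, nb, drop = FALSE]
    clustering[i] <- sum(sub) / (k * (k - 1))
    Ds <- bfs_distances(sub)
    inv <- 1 / Ds[upper.tri(Ds)]
    leff[i] <- mean(inv)
  }
  btw <- if (n > 2) brandes_betweenness(adj) / ((n - 1) * (n - 2) / 2)
         else numeric(n)
  D <- bfs_distances(adj)
  diag(D) <- Inf
  apl <- apply(D, 1, function(v) {
    fin <- is.finite(v)
    if (!any(fin)) NA_real_ else mean(v[fin])
  })
  reach <- apply(D, 1, function(v) sum(is.finite(v)) / (n - 1))
  data.frame(node = seq_len(n), degree = as.integer(deg),
             cost = deg / (n - 1), clustering = clustering,
             local_efficiency = leff, betweenness = btw,
             avg_path_length = apl, reachable_frac = reach)
}

#' Assemble the per-patient SOZ feature vector
#'
#' Extracts, for each frequency band, the SOZ region's inflow, outflow
#' and six node metrics, giving the 8-measure x 4-band feature record
#' used by the group comparison.
#'
#' @param flow an [inflow_outflow()] result (matrices
#'   `n_regions x n_bands`).
#' @param metrics_per_band named list of [node_metrics()] data frames, one
#'   per band (same band names as `flow`).
#' @param soz_region SOZ region index.
#' @param patient_id,group patient metadata carried through.
#' @return a data.frame in long format with columns `patient_id`, `group`,
#'   `band`, `measure`, `value` (32 rows).
#' @export
extract_soz_features <- function(flow, metrics_per_band, soz_region,
                                 patient_id, group) {
  bands <- colnames(flow$inflow)
  if (is.null(bands)) bands <- names(metrics_per_band)
  missing_b <- setdiff(bands, names(metrics_per_band))
  if (length(missing_b) > 0)
    stop(sprintf("missing node metrics for band(s): %s",
                 paste(missing_b, collapse = ", ")))
  stopifnot(soz_region >= 1, soz_region <= nrow(flow$inflow))
  rows <- lapply(bands, function(b) {
    nm <- metrics_per_band[[b]]
    data.frame(patient_id = patient_id, group = group, band = b,
               measure = c("inflow", "outflow", "degree", "cost",
                           "clustering", "local_efficiency", "betweenness",
                           "avg_path_length"),
               value = as.numeric(c(flow$inflow[soz_region, b],
                         flow$outflow[soz_region, b],
                         nm$degree[soz_region], nm$cost[soz_region],
                         nm$clustering[soz_region],
                         nm$local_efficiency[soz_region],
                         nm$betweenness[soz_region],
                         nm$avg_path_length[soz_region])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
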