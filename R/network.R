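# Density-thresholded graph series and node-strength AUC.
#
# Graphs are built from a symmetric correlation matrix by (1) a maximum
# spanning tree on |r| (n-1 edges, guaranteeing connectedness), then (2)
# appending the remaining edges in descending |r| -- positive and negative
# correlations of equal magnitude share a rank, the retained weight keeps
# its sign. The series covers densities 5%..50% in 1% steps; node strength
# is the signed sum of retained incident weights and is summarised across
# the sweep by a trapezoidal AUC.

#' Number of edges retained at a target density
#'
#' `max(n - 1, round(density * n(n-1)/2))` with round-half-away-from-zero;
#' the floor of `n - 1` keeps the spanning-tree backbone intact at very
#' low densities.
#'
#' @param density Density fraction in (0, 1].
#' @param n_nodes Number of nodes.
#' @return Integer edge count.
#' @export
#' @examples
#' edge_count_at_density(0.05, 122) # 369
edge_count_at_density <- function(density, n_nodes) {
  n_edges <- n_nodes * (n_nodes - 1) / 2
  pmax(n_nodes - 1, round_half_away(density * n_edges))
}

# Kruskal maximum spanning tree over a pre-sorted edge list (union-find).
# Returns logical vector marking tree edges.
.mst_edges <- function(ei, ej, ord, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(length(ei))
  picked <- 0L
  for (k in ord) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[k] <- TRUE
      picked <- picked + 1L
      if (picked == n_nodes - 1L) break
    }
  }
  in_tree
}

#' Build the nested density-thresholded graph series
#'
#' @param mat Symmetric numeric matrix (signed correlation weights) with
#'   region labels as dimnames; the diagonal is ignored.
#' @param densities Density grid (default `seq(0.05, 0.50, by = 0.01)`).
#' @return An object of class `density_series`: the inclusion-ordered edge
#'   list (backbone first, then descending `|r|`), per-density edge counts,
#'   and the backbone flag. Edge sets are nested across densities by
#'   construction.
#' @details Ties in `|r|` are broken by ascending `(i, j)` index order so
#'   the series is deterministic. A test-only density of 1 retains all
#'   edges.
#' @export
build_density_series <- function(mat, densities = seq(0.05, 0.50, by = 0.01)) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stopf("`mat` must be a square matrix")
  if (anyNA(mat)) stopf("`mat` contains NA entries")
  if (max(abs(mat - t(mat))) > 1e-8)
    stopf("`mat` is not symmetric (max |M - t(M)| = %.3g)",
          max(abs(mat - t(mat))))
  n <- nrow(mat)
  labs <- rownames(mat) %||% as.character(seq_len(n))
  ut <- upper.tri(mat)
  idx <- which(ut, arr.ind = TRUE)
  ei <- idx[, 1L]; ej <- idx[, 2L]
  w <- mat[ut]
  # Descending magnitude; ties by ascending (i, j).
  ord <- order(-abs(w), ei, ej)
  in_tree <- .mst_edges(ei, ej, ord, n)
  seq_order <- c(ord[in_tree[ord]], ord[!in_tree[ord]])
  counts <- edge_count_at_density(densities, n)
  counts <- pmin(counts, length(w))
  structure(list(
    n_nodes = n, labels = labs,
    i = ei[seq_order], j = ej[seq_order], w = w[seq_order],
    backbone = c(rep(TRUE, n - 1L), rep(FALSE, length(w) - (n - 1L))),
    densities = densities, counts = as.integer(counts)
  ), class = "density_series")
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf("density_series: %d nodes, %d densities (%.2f..%.2f), %d..%d edges\n",
              x$n_nodes, length(x$densities), min(x$densities),
              max(x$densities), min(x$counts), max(x$counts)))
  invisible(x)
}

#' Adjacency matrix of one graph in the series
#'
#' @param series A `density_series`.
#' @param density One density from the series grid.
#' @return Symmetric weighted adjacency matrix (zero where no edge).
#' @export
graph_at_density <- function(series, density) {
  k <- match(TRUE, abs(series$densities - density) < 1e-9)
  if (is.na(k)) stopf("density %.3f not in the series grid", density)
  m <- series$counts[k]
  adj <- matrix(0, series$n_nodes, series$n_nodes,
                dimnames = list(series$labels, series$labels))
  ii <- series$i[seq_len(m)]; jj <- series$j[seq_len(m)]
  adj[cbind(ii, jj)] <- series$w[seq_len(m)]
  adj[cbind(jj, ii)] <- series$w[seq_len(m)]
  adj
}

#' Node strength at every density of a series
#'
#' Strength of node i at density rho is the sum of the retained incident
#' edge weights. By default weights are signed (negative correlations
#' subtract); `weights = "absolute"` sums magnitudes instead.
#'
#' @param series A `density_series`.
#' @param weights `"signed"` (default) or `"absolute"`.
#' @return Matrix nodes x densities of strengths.
#' @export
node_strength <- function(series, weights = c("signed", "absolute")) {
  weights <- match.arg(weights)
  w <- if (weights == "absolute") abs(series$w) else series$w
  n <- series$n_nodes
  out <- matrix(0, n, length(series$densities),
                dimnames = list(series$labels,
                                sprintf("d%02d", round(series$densities * 100))))
  s <- numeric(n)
  prev <- 0L
  for (k in seq_along(series$counts)) {
    m <- series$counts[k]
    if (m > prev) {
      sel <- (prev + 1L):m
      inc <- rowsum(c(w[sel], w[sel]), c(series$i[sel], series$j[sel]))
      s[as.integer(rownames(inc))] <- s[as.integer(rownames(inc))] + inc[, 1L]
      prev <- m
    }
    out[, k] <- s
  }
  out
}

#' Area under the node-strength curve across the density sweep
#'
#' Trapezoidal integral of strength over the density axis (default grid
#' 0.05..0.50, step 0.01, so a constant curve `c` gives `0.45 * c`).
#'
#' @param strength Numeric vector (one node's curve) or matrix
#'   (nodes x densities) as returned by [node_strength()].
#' @param densities Density grid matching the curve columns.
#' @return Numeric AUC (vector if `strength` is a matrix).
#' @export
strength_auc <- function(strength, densities = seq(0.05, 0.50, by = 0.01)) {
  if (is.matrix(strength)) {
    if (ncol(strength) != length(densities))
      stopf("strength has %d columns but %d densities", ncol(strength),
            length(densities))
    dx <- diff(densities)
    return(as.numeric((strength[, -ncol(strength), drop = FALSE] +
                         strength[, -1L, drop = FALSE]) %*% (dx / 2)) |>
             stats::setNames(rownames(strength)))
  }
  if (length(strength) != length(densities))
    stopf("strength curve length %d does not match %d densities",
          length(strength), length(densities))
  sum(diff(densities) * (utils::head(strength, -1) + utils::tail(strength, -1)) / 2)
}

#' Node-strength AUC for every node of a connectivity matrix
#'
#' Convenience wrapper: builds the density series and integrates strength
#' over the 5%-50% sweep.
#'
#' @inheritParams build_density_series
#' @inheritParams node_strength
#' @return Named numeric vector of AUC values, one per node.
#' @export
strength_auc_matrix <- function(mat, densities = seq(0.05, 0.50, by = 0.01),
                                weights = "signed") {
  series <- build_density_series(mat, densities)
  strength_auc(node_strength(series, weights), densities)
}

#' Edges from one thalamic subdivision to every other region
#'
#' @param mat Connectivity matrix with atlas dimnames.
#' @param subdivision Thalamic subdivision name.
#' @param side `"L"` or `"R"`.
#' @param atlas Atlas data frame.
#' @return Data frame `target`, `value` with one row per other region
#'   (121 for the 122-region atlas; includes the other thalamic nodes).
#' @export
extract_thalamic_edges <- function(mat, subdivision, side,
                                   atlas = thalamus_atlas()) {
  node <- thalamic_region(subdivision, side, atlas)
  if (!node %in% rownames(mat)) stopf("region %s absent from matrix", node)
  targets <- setdiff(rownames(mat), node)
  data.frame(target = targets, value = mat[node, targets],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Is every node reachable in the graph at the given density? (test helper)
is_connected_at_density <- function(series, density) {
  adj <- graph_at_density(series, density) != 0
  n <- nrow(adj)
  seen <- logical(n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}
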