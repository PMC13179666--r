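# Shared fixtures, built in code at test time.

small_config <- function(seed = 42, ...) {
  cohort_config(group_sizes = c(control = 24, TLE = 18, FLE = 8, PQE = 6),
                conn_calibration_n = 15, seed = seed, ...)
}

# Random symmetric correlation-like matrix with labels.
random_sym_matrix <- function(n, seed = 1, labels = sprintf("R%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -0.9, 0.9), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

# Independent strength oracle: igraph maximum spanning tree on |r| plus
# naive descending-|r| prefix selection, strengths by masked row sums.
oracle_strength <- function(mat, density) {
  n <- nrow(mat)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  w <- mat[upper.tri(mat)]
  ord <- order(-abs(w), ut[, 1], ut[, 2])
  g <- igraph::graph_from_adjacency_matrix(abs(mat) * upper.tri(mat),
                                           mode = "upper", weighted = TRUE)
  mstg <- igraph::mst(g, weights = -abs(igraph::E(g)$weight))
  mst_pairs <- apply(igraph::as_edgelist(mstg, names = FALSE), 1, function(e)
    paste(sort(e), collapse = "-"))
  key <- paste(ut[, 1], ut[, 2], sep = "-")
  in_mst <- key %in% mst_pairs
  k <- max(n - 1, thalnet::round_half_away(density * length(w)))
  k <- min(k, length(w))
  chosen <- logical(length(w))
  chosen[in_mst] <- TRUE
  for (e in ord) {
    if (sum(chosen) >= k) break
    chosen[e] <- TRUE
  }
  adj <- matrix(0, n, n)
  sel <- which(chosen)
  adj[cbind(ut[sel, 1], ut[sel, 2])] <- w[sel]
  adj <- adj + t(adj)
  rowSums(adj)
}

# One-time cached small pipeline run shared across test files.
.cache <- new.env(parent = emptyenv())
cached_small_result <- function() {
  if (is.null(.cache$res))
    .cache$res <- run_pipeline(config = small_config())
  .cache$res
}
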