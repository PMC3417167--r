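#' Planted-partition weighted graph
#'
#' Test bed for community detection: nodes are split into modules; each
#' within-module pair gets an edge with probability `p_in`, each
#' between-module pair with probability `p_out` (`p_in > p_out`), with
#' weights drawn uniformly from the given ranges. With `p_out = 0` the
#' planted modules are exactly the connected components.
#'
#' @param n_nodes Number of nodes.
#' @param n_modules Number of planted modules.
#' @param p_in,p_out Within- / between-module edge probabilities.
#' @param sizes Optional module sizes (must sum to `n_nodes`); default
#'   near-equal.
#' @param weight_in,weight_out Uniform weight ranges for within / between
#'   edges.
#' @param seed RNG seed.
#' @return List: `weights` (symmetric matrix), `labels` (planted modules),
#'   `nodes` (names).
#' @export
planted_partition_graph <- function(n_nodes = 14, n_modules = 4,
                                    p_in = 0.9, p_out = 0.05,
                                    sizes = NULL,
                                    weight_in = c(0.5, 1),
                                    weight_out = c(0.1, 0.4),
                                    seed = NULL) {
  if (p_in <= p_out) stop_socmap("p_in must exceed p_out", "validation")
  if (is.null(sizes)) {
    sizes <- rep(n_nodes %/% n_modules, n_modules)
    extra <- n_nodes - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  if (sum(sizes) != n_nodes || length(sizes) != n_modules) {
    stop_socmap("sizes must have length n_modules and sum to n_nodes", "validation")
  }
  labels <- rep(seq_len(n_modules), times = sizes)
  nodes <- paste0("n", seq_len(n_nodes))
  with_seed(seed, {
    w <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        same <- labels[i] == labels[j]
        p <- if (same) p_in else p_out
        if (runif(1) < p) {
          rng <- if (same) weight_in else weight_out
          w[i, j] <- w[j, i] <- runif(1, rng[1], rng[2])
        }
      }
    }
    # guarantee each planted module is internally connected (chain its
    # within-module components), so modules are identifiable communities
    for (m in seq_len(n_modules)) {
      members <- which(labels == m)
      if (length(members) < 2) next
      comp <- seq_along(members)
      find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
      for (a in seq_along(members)) for (b in seq_along(members)) {
        if (w[members[a], members[b]] > 0) comp[find(a)] <- find(b)
      }
      roots <- unique(vapply(seq_along(members), find, integer(1)))
      while (length(roots) > 1) {
        a <- members[which(vapply(seq_along(members), find, integer(1)) == roots[1])[1]]
        b <- members[which(vapply(seq_along(members), find, integer(1)) == roots[2])[1]]
        w[a, b] <- w[b, a] <- runif(1, weight_in[1], weight_in[2])
        comp[find(which(members == a))] <- find(which(members == b))
        roots <- unique(vapply(seq_along(members), find, integer(1)))
      }
    }
    list(weights = w, labels = labels, nodes = nodes)
  })
}
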