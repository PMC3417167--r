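#' Two-level map equation (description length)
#'
#' Description length, in bits per step, of a random walk on an undirected
#' weighted graph under a two-level coding with one index codebook for
#' between-module moves and one codebook per module. Node visit rates are
#' proportional to node strength (no teleportation); module exit rates are
#' the stationary probabilities of crossing the module boundary:
#' `L = q H(module exits) + sum_m p_m H(within-module visits and exit)`.
#' For a single module this reduces to the entropy of the node visit rates.
#'
#' @param w Symmetric non-negative weight matrix (zero diagonal assumed).
#' @param assignment Integer/character module label per node.
#' @return Description length in bits.
#' @export
map_equation <- function(w, assignment) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (length(assignment) != n || anyNA(assignment)) {
    stop_socmap("every node needs a module assignment", "validation")
  }
  s <- rowSums(w)
  tw <- sum(s)
  if (tw <= 0) stop_socmap("graph has no edge weight", "validation")
  p <- s / tw
  grp <- canonical_assignment(assignment)
  # module-by-module weight totals via two rowsum passes
  w_mod <- rowsum(t(rowsum(w, grp)), grp)
  q_m <- (rowSums(w_mod) - diag(as.matrix(w_mod))) / tw
  q <- sum(q_m)
  plogp <- function(x) {
    x <- x[x > 0]
    sum(x * log2(x))
  }
  index_term <- if (q > 0) -q * plogp(q_m[q_m > 0] / q) else 0
  p_in <- drop(rowsum(p, grp))
  pm <- q_m + p_in
  # sum_m pm * H({q_m, p_i in m} / pm), expanded to avoid per-module loops
  h_inner <- -(ifelse(q_m > 0, q_m * log2(q_m), 0) +
                 drop(rowsum(ifelse(p > 0, p * log2(p), 0), grp))) +
    ifelse(pm > 0, pm * log2(pm), 0)
  index_term + sum(h_inner)
}

# Canonical labeling: modules renumbered 1.. in order of first appearance.
canonical_assignment <- function(assignment) {
  match(assignment, unique(assignment))
}

# TRUE if a is lexicographically smaller than b (both canonical).
lex_smaller <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

# One greedy optimization pass from an initial assignment: node-move sweeps
# to convergence, then module agglomeration, repeated until stable.
greedy_map_equation <- function(w, init) {
  n <- nrow(w)
  assignment <- canonical_assignment(init)
  l_cur <- map_equation(w, assignment)
  repeat {
    changed_outer <- FALSE
    # local node moves
    repeat {
      changed <- FALSE
      for (i in sample.int(n)) {
        nbr_mods <- unique(assignment[w[i, ] > 0])
        cand <- unique(c(nbr_mods, max(assignment) + 1L))
        cand <- setdiff(cand, assignment[i])
        for (m in cand) {
          trial <- assignment
          trial[i] <- m
          l_new <- map_equation(w, trial)
          if (l_new < l_cur - 1e-12) {
            assignment <- canonical_assignment(trial)
            l_cur <- l_new
            changed <- TRUE
          }
        }
      }
      if (!changed) break
      changed_outer <- TRUE
    }
    # agglomeration: best single module merge, repeated
    repeat {
      mods <- unique(assignment)
      if (length(mods) < 2) break
      best <- NULL
      best_l <- l_cur
      pairs <- utils::combn(mods, 2)
      for (k in seq_len(ncol(pairs))) {
        trial <- assignment
        trial[trial == pairs[2, k]] <- pairs[1, k]
        l_new <- map_equation(w, trial)
        if (l_new < best_l - 1e-12) {
          best_l <- l_new
          best <- trial
        }
      }
      if (is.null(best)) break
      assignment <- canonical_assignment(best)
      l_cur <- best_l
      changed_outer <- TRUE
    }
    if (!changed_outer) break
  }
  list(assignment = assignment, description_length = l_cur)
}

#' Map-equation community detection with restarts
#'
#' Greedy local-move and agglomeration minimization of the two-level
#' [map_equation()], run from `n_restarts` random initial assignments; the
#' partition with the lowest description length is selected (ties broken by
#' the lexicographically smallest canonical labeling), and the fraction of
#' restarts converging to it is reported as the modal fraction.
#'
#' @param graph A `connectivity_graph` from [build_graph()], or a symmetric
#'   weight matrix.
#' @param n_restarts Number of random restarts (e.g. 100).
#' @param seed RNG seed; the same seed yields the identical partition.
#' @return A `community_partition`: `assignment` tibble (`node`, `module`),
#'   `description_length` (bits), `n_restarts`, `modal_fraction`.
#' @export
detect_communities <- function(graph, n_restarts = 100, seed = NULL) {
  w <- if (inherits(graph, "connectivity_graph")) graph_adjacency(graph) else as.matrix(graph)
  nodes <- colnames(w) %||% paste0("n", seq_len(nrow(w)))
  n <- nrow(w)
  if (n == 0) stop_socmap("empty graph", "validation")
  with_seed(seed, {
    results <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      # singleton start; randomness enters through the node sweep orders
      results[[r]] <- greedy_map_equation(w, seq_len(n))
    }
    ls <- vapply(results, `[[`, numeric(1), "description_length")
    best <- results[[1]]
    for (r in results[-1]) {
      if (r$description_length < best$description_length - 1e-10) {
        best <- r
      } else if (abs(r$description_length - best$description_length) <= 1e-10 &&
                 lex_smaller(r$assignment, best$assignment)) {
        best <- r
      }
    }
    modal <- mean(vapply(results, function(r) {
      identical(r$assignment, best$assignment)
    }, logical(1)))
    structure(
      list(
        assignment = tibble::tibble(node = nodes, module = best$assignment),
        description_length = best$description_length,
        n_restarts = n_restarts,
        modal_fraction = modal,
        restart_lengths = ls
      ),
      class = "community_partition"
    )
  })
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf(
    "<community_partition> %d modules over %d nodes, L = %.4f bits, modal fraction %.2f (%d restarts)\n",
    length(unique(x$assignment$module)), nrow(x$assignment),
    x$description_length, x$modal_fraction, x$n_restarts
  ))
  invisible(x)
}

#' @export
tidy.community_partition <- function(x, ...) x$assignment

#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(
    n_modules = length(unique(x$assignment$module)),
    description_length = x$description_length,
    modal_fraction = x$modal_fraction,
    n_restarts = x$n_restarts
  )
}

#' Write a community partition as JSON
#'
#' @param partition A `community_partition`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(
    list(
      assignment = partition$assignment,
      description_length = partition$description_length,
      n_restarts = partition$n_restarts,
      modal_fraction = partition$modal_fraction
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
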