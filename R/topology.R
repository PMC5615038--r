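# Tree-like topologies: directed functional graphs (each node has exactly one
# off-diagonal outgoing link), i.e. a tree with a single loop. With the S
# self-interactions these have connectivity C = 2S/S^2 = 2/S, the sparsest
# structure that keeps the interaction network connected.

#' Tree-like topology (tree with one loop)
#'
#' A directed interaction topology on `S` nodes in which every node has
#' exactly one off-diagonal outgoing link, encoded as a successor map
#' `sigma(i) != i`. The functional graph is weakly connected and contains
#' exactly one directed cycle of length `loop_length`. Together with the `S`
#' self-interactions the connectivity is `2/S`.
#'
#' @param n_nodes Number of nodes `S >= 2`.
#' @param successor Integer vector of length `S`; `successor[i]` is the target
#'   of node `i`'s single off-diagonal link.
#' @param loop_length Length of the unique directed cycle.
#' @return An object of class `tree_topology`.
#' @seealso [make_tree_like()], [join_tree_like()]
#' @export
tree_topology <- function(n_nodes, successor, loop_length) {
  n_nodes <- as.integer(n_nodes)
  successor <- as.integer(successor)
  loop_length <- as.integer(loop_length)
  obj <- structure(
    list(n_nodes = n_nodes, successor = successor, loop_length = loop_length),
    class = "tree_topology"
  )
  validate_tree_topology(obj)
  obj
}

#' @export
print.tree_topology <- function(x, ...) {
  cat(sprintf("Tree-like topology: S = %d nodes, loop length %d, C = 2/S = %.4g\n",
              x$n_nodes, x$loop_length, 2 / x$n_nodes))
  invisible(x)
}

validate_tree_topology <- function(x) {
  S <- x$n_nodes
  if (S < 2) stop("tree-like topology needs at least 2 nodes", call. = FALSE)
  if (length(x$successor) != S || anyNA(x$successor) ||
      any(x$successor < 1L) || any(x$successor > S))
    stop("successor map must assign every node a valid node index", call. = FALSE)
  if (any(x$successor == seq_len(S)))
    stop("successor map may not contain self-links", call. = FALSE)
  cyc <- functional_cycle(x$successor)
  if (length(cyc) != x$loop_length)
    stop(sprintf("stored loop_length %d does not match actual cycle length %d",
                 x$loop_length, length(cyc)), call. = FALSE)
  comp <- weak_components(x$successor)
  if (comp != 1L)
    stop("functional graph must be weakly connected", call. = FALSE)
  invisible(x)
}

# Nodes of the unique directed cycle of a functional graph, found by walking
# S steps from node 1 (guaranteed to land on the cycle) and then tracing it.
functional_cycle <- function(successor) {
  v <- 1L
  for (k in seq_along(successor)) v <- successor[v]
  cyc <- v
  u <- successor[v]
  while (u != v) {
    cyc <- c(cyc, u)
    u <- successor[u]
  }
  cyc
}

# Number of weakly connected components of the functional graph.
weak_components <- function(successor) {
  S <- length(successor)
  adj <- vector("list", S)
  for (i in seq_len(S)) {
    j <- successor[i]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(S)
  ncomp <- 0L
  for (start in seq_len(S)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ncomp
}

#' Generate a random tree-like topology
#'
#' Places a directed cycle of length `loop_length` on randomly chosen nodes,
#' then attaches every remaining node by pointing its successor at a uniformly
#' chosen already-placed node. The construction guarantees weak connectivity
#' and a unique cycle of the requested length.
#'
#' @param S Number of nodes (`S >= 2`).
#' @param loop_length Cycle length `L`, with `2 <= L <= S`. Defaults to 3, the
#'   loop length that maximizes explorability.
#' @param seed Optional integer seed.
#' @return A [tree_topology()] object.
#' @examples
#' topo <- make_tree_like(10, loop_length = 3, seed = 1)
#' connectivity(adjacency_mask(topo))  # 2/S = 0.2
#' @export
make_tree_like <- function(S, loop_length = 3L, seed = NULL) {
  S <- as.integer(S)
  L <- as.integer(loop_length)
  if (S < 2L) stop("S must be at least 2", call. = FALSE)
  if (L < 2L || L > S)
    stop(sprintf("loop_length must lie in [2, S]; got L = %d, S = %d", L, S),
         call. = FALSE)
  with_seed(seed, {
    successor <- integer(S)
    cyc <- sample.int(S, L)
    successor[cyc] <- c(cyc[-1L], cyc[1L])
    placed <- cyc
    rest <- setdiff(seq_len(S), cyc)
    if (length(rest) > 1) rest <- sample(rest)  # sample(x) pitfall at length 1
    for (v in rest) {
      successor[v] <- placed[sample.int(length(placed), 1L)]
      placed <- c(placed, v)
    }
    tree_topology(S, successor, L)
  })
}

#' Adjacency mask of a topology
#'
#' Boolean `S x S` matrix of active interactions. The diagonal
#' (self-interactions) is always active; the off-diagonal pattern comes from
#' the tree links plus any extra links.
#'
#' @param topo A [tree_topology()].
#' @param extra Optional [extra_links()] to include.
#' @return Logical `S x S` matrix.
#' @export
adjacency_mask <- function(topo, extra = NULL) {
  S <- topo$n_nodes
  A <- diag(S) > 0
  A[cbind(seq_len(S), topo$successor)] <- TRUE
  if (!is.null(extra) && nrow(extra$positions))
    A[extra$positions] <- TRUE
  A
}

#' Connectivity of an adjacency mask
#'
#' The fraction of active entries among the `S^2` possible links,
#' self-interactions included.
#'
#' @param mask Logical square matrix with an all-active diagonal.
#' @return A fraction in `(0, 1]`.
#' @export
connectivity <- function(mask) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask))
  if (!all(diag(mask) != 0))
    stop("diagonal (self-interaction) entries must all be active", call. = FALSE)
  sum(mask != 0) / length(mask)
}

#' Extra links on top of a base topology
#'
#' A set of off-diagonal positions, disjoint from the base tree links, each
#' carrying a fixed weight `eps`. These weights are held fixed while the tree
#' weights are tuned.
#'
#' @param positions Two-column integer matrix of (row, column) indices.
#' @param weights Numeric vector of link weights, one per position.
#' @param n_nodes Number of nodes of the host network.
#' @return An object of class `extra_links`.
#' @export
extra_links <- function(positions, weights, n_nodes) {
  positions <- matrix(as.integer(positions), ncol = 2)
  weights <- as.numeric(weights)
  if (nrow(positions) != length(weights))
    stop("one weight per position required", call. = FALSE)
  if (nrow(positions)) {
    if (any(positions < 1L) || any(positions > n_nodes))
      stop("positions out of range", call. = FALSE)
    if (any(positions[, 1] == positions[, 2]))
      stop("extra links may not touch the diagonal", call. = FALSE)
    if (anyDuplicated(positions))
      stop("duplicate extra-link positions", call. = FALSE)
    if (!all(is.finite(weights)))
      stop("extra-link weights must be finite", call. = FALSE)
  }
  structure(list(positions = positions, weights = weights,
                 n_nodes = as.integer(n_nodes)),
            class = "extra_links")
}

#' Empty extra-link set
#' @param n_nodes Number of nodes.
#' @return An [extra_links()] object with no links.
#' @export
no_extra_links <- function(n_nodes) {
  extra_links(matrix(integer(0), ncol = 2), numeric(0), n_nodes)
}

#' Add random fixed-weight links up to a target connectivity
#'
#' Samples `round(target_C * S^2) - 2 S` off-diagonal positions uniformly
#' without replacement from the cells not used by the base topology, and
#' draws their weights i.i.d. from `Normal(0, sigma_eps^2)`.
#'
#' @param base A [tree_topology()].
#' @param target_C Target connectivity, in `[2/S, 1]`.
#' @param sigma_eps Standard deviation of the Gaussian link weights.
#' @param seed Optional integer seed.
#' @return An [extra_links()] object.
#' @examples
#' topo <- make_tree_like(20, seed = 1)
#' ex <- add_random_links(topo, target_C = 0.5, sigma_eps = 0.1, seed = 2)
#' nrow(ex$positions)  # 0.5 * 400 - 40 = 160
#' @export
add_random_links <- function(base, target_C, sigma_eps = 0.1, seed = NULL) {
  S <- base$n_nodes
  if (target_C < 2 / S - 1e-12)
    stop(sprintf("target_C = %g below the tree-like floor 2/S = %g; base links cannot be removed",
                 target_C, 2 / S), call. = FALSE)
  if (target_C > 1) stop("target_C cannot exceed 1", call. = FALSE)
  n_extra <- round(target_C * S^2) - 2L * S
  if (n_extra == 0L) return(no_extra_links(S))
  A <- adjacency_mask(base)
  free <- which(!A)  # linear indices; excludes diagonal and tree links
  if (n_extra > length(free))
    stop("target_C leaves no room for the requested extra links", call. = FALSE)
  with_seed(seed, {
    pick <- free[sample.int(length(free), n_extra)]
    pos <- cbind((pick - 1L) %% S + 1L, (pick - 1L) %/% S + 1L)
    extra_links(pos, stats::rnorm(n_extra, 0, sigma_eps), S)
  })
}

#' Join two tree-like networks into one tree-like network
#'
#' Opens the cycle of `a` by redirecting one of its cycle links into a node of
#' `b`; the unique cycle of the joined network is `b`'s cycle. Every node
#' keeps exactly one off-diagonal outgoing link, so the result is again
#' tree-like: sparsity is closed under assembly.
#'
#' @param a,b [tree_topology()] objects.
#' @param seed Optional integer seed (choice of cut point and attachment).
#' @return A [tree_topology()] on `S_a + S_b` nodes with `b`'s loop length.
#' @export
join_tree_like <- function(a, b, seed = NULL) {
  Sa <- a$n_nodes
  Sb <- b$n_nodes
  with_seed(seed, {
    succ <- c(a$successor, b$successor + Sa)
    cyc_a <- functional_cycle(a$successor)
    u <- cyc_a[sample.int(length(cyc_a), 1L)]
    succ[u] <- Sa + sample.int(Sb, 1L)
    tree_topology(Sa + Sb, succ, b$loop_length)
  })
}

#' Link count of a merged sparse network
#'
#' If sparse networks with `S` nodes have `a*S - b` links, joining two of them
#' (sizes `S` and `S_prime`) with `b` links yields `a*(S + S_prime) - b`
#' links: the sparse class is self-similar. This is the arithmetic identity
#' used to property-test concrete join implementations.
#'
#' @param S,S_prime Node counts of the two networks.
#' @param a,b Integer constants of the sparse link-count law.
#' @return The merged link count `a*(S + S_prime) - b`.
#' @export
merge_sparse_counts <- function(S, S_prime, a, b) {
  if (a < 1 || b < 0) stop("need a >= 1 and b >= 0", call. = FALSE)
  if (a * S - b <= 0 || a * S_prime - b <= 0)
    stop("component link counts must be positive", call. = FALSE)
  (a * S - b) + (a * S_prime - b) + b
}

#' Write a weight matrix or topology as an edge-list TSV
#'
#' Three tab-separated columns `source`, `target`, `weight` with a header
#' line and 0-based node indices. For a bare topology all link weights are
#' written as 1; for a matrix every non-zero entry (diagonal included) is
#' written.
#'
#' @param x A [tree_topology()] or a numeric square matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "tree_topology")) {
    df <- data.frame(source = seq_len(x$n_nodes) - 1L,
                     target = x$successor - 1L,
                     weight = 1)
  } else {
    stopifnot(is.matrix(x), nrow(x) == ncol(x))
    idx <- which(x != 0, arr.ind = TRUE)
    df <- data.frame(source = idx[, 1] - 1L, target = idx[, 2] - 1L,
                     weight = x[idx])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list TSV into a weight matrix
#'
#' @param path File written by [write_edge_list()] (or following its schema).
#' @param n_nodes Number of nodes; defaults to `max(index) + 1`.
#' @return Numeric `S x S` weight matrix.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("source", "target", "weight") %in% names(df)))
    stop("edge list must have columns source, target, weight", call. = FALSE)
  S <- if (is.null(n_nodes)) max(df$source, df$target) + 1L else as.integer(n_nodes)
  w <- matrix(0, S, S)
  w[cbind(df$source + 1L, df$target + 1L)] <- df$weight
  w
}
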