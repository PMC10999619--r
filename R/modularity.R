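#' Weighted Newman–Girvan modularity of a partition
#'
#' \eqn{Q = \frac{1}{2m} \sum_{ik} \left[A_{ik} - \frac{k_i k_k}{2m}\right]
#' \delta(c_i, c_k)} for a weighted undirected network with adjacency
#' \eqn{A}, strengths \eqn{k_i = \sum_k A_{ik}} and total edge weight
#' \eqn{m = \frac{1}{2}\sum_{ik} A_{ik}}. Putting every node in one module
#' gives \eqn{Q = 0}; \eqn{Q \in [-1/2, 1]}. Q is invariant under a global
#' rescaling of the edge weights.
#'
#' @param network an [build_network()] object, or a symmetric non-negative
#'   weight matrix with zero diagonal.
#' @param membership module assignment: vector of labels, one per node
#'   (named or in node order).
#' @return the modularity score Q.
#' @examples
#' W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
#' modularity_q(W, c(1, 1, 2, 2))  # 0.5
#' @export
modularity_q <- function(network, membership) {
  W <- network_weights(network)
  n <- nrow(W)
  mem <- align_membership(membership, rownames(W), n)
  m <- sum(W) / 2
  if (m <= 0) stop("modularity is undefined on an edgeless network",
                   call. = FALSE)
  d <- rowSums(W)
  within <- outer(mem, mem, "==")
  sum(W[within]) / (2 * m) - sum(tapply(d, mem, sum)^2) / (4 * m^2)
}

network_weights <- function(network) {
  if (inherits(network, "overlap_network")) return(network$weights)
  W <- as.matrix(network)
  if (nrow(W) != ncol(W) || any(abs(W - t(W)) > 1e-12))
    stop("weight matrix must be square and symmetric", call. = FALSE)
  diag(W) <- 0
  W
}

align_membership <- function(membership, nodes, n) {
  if (length(membership) != n)
    stop("membership must cover all ", n, " nodes", call. = FALSE)
  if (!is.null(names(membership)) && !is.null(nodes)) {
    if (!setequal(names(membership), nodes))
      stop("membership names do not match network nodes", call. = FALSE)
    membership <- membership[nodes]
  }
  as.integer(factor(membership))
}

# relabel modules 1, 2, ... in order of first appearance (node index order);
# makes every algorithm's output canonical and comparable
canonical_membership <- function(mem, nodes = NULL) {
  mem <- as.integer(factor(mem, levels = unique(mem)))
  if (!is.null(nodes)) names(mem) <- nodes
  mem
}

# Exhaustive maximum-modularity search: enumerates every set partition of the
# nodes as restricted-growth strings, depth-first in lexicographic order, and
# keeps the first partition attaining the maximal Q. Within-module weight and
# module strength sums are maintained incrementally while backtracking, so a
# leaf costs O(1). Bell(12) ~ 4.2e6 is the practical ceiling; larger inputs
# are refused upstream.
exhaustive_partition <- function(W) {
  n <- nrow(W)
  m <- sum(W) / 2
  d <- rowSums(W)
  best_q <- -Inf
  best <- rep(1L, n)
  mem <- integer(n)
  internal <- numeric(n)   # 2x within-module weight, per label
  strength <- numeric(n)   # sum of node strengths, per label

  recurse <- function(i, maxlab) {
    if (i > n) {
      q <- sum(internal) / (2 * m) - sum(strength^2) / (4 * m^2)
      if (q > best_q + 1e-12) {
        best_q <<- q
        best <<- mem
      }
      return(invisible(NULL))
    }
    prev <- seq_len(i - 1L)
    wrow <- W[i, prev]
    memprev <- mem[prev]
    for (lab in seq_len(maxlab + 1L)) {
      w_add <- if (i == 1L) 0 else 2 * sum(wrow[memprev == lab])
      internal[lab] <<- internal[lab] + w_add
      strength[lab] <<- strength[lab] + d[i]
      mem[i] <<- lab
      recurse(i + 1L, max(maxlab, lab))
      internal[lab] <<- internal[lab] - w_add
      strength[lab] <<- strength[lab] - d[i]
    }
  }
  recurse(1L, 0L)
  list(membership = best, Q = best_q)
}

# Greedy CNM-style agglomeration: start from singletons, repeatedly merge the
# pair of modules with the largest positive modularity gain
# dQ(a,b) = e_ab/m - d_a d_b / (2 m^2); ties broken toward the
# lexicographically smallest pair of smallest member node indices.
greedy_agglomerate <- function(W, mem = seq_len(nrow(W))) {
  m <- sum(W) / 2
  d <- rowSums(W)
  mem <- as.integer(factor(mem))
  repeat {
    labs <- sort(unique(mem))
    if (length(labs) < 2L) break
    # module-aggregated weights and strengths
    G <- rowsum(t(rowsum(W, mem)), mem)        # labs x labs, between-weights
    D <- as.vector(rowsum(d, mem))
    first_node <- vapply(labs, function(l) min(which(mem == l)), 1L)
    nl <- length(labs)
    dq <- G / (2 * m) - outer(D, D) / (4 * m^2)
    dq <- 2 * dq                                # gain counts both directions
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    best <- max(dq)
    if (best <= 1e-12) break
    cand <- which(dq >= best - 1e-12, arr.ind = TRUE)
    # order candidates by the smallest node index of each member module
    key <- cbind(pmin(first_node[cand[, 1]], first_node[cand[, 2]]),
                 pmax(first_node[cand[, 1]], first_node[cand[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    a <- labs[cand[pick, 1]]; b <- labs[cand[pick, 2]]
    mem[mem == b] <- a
    mem <- as.integer(factor(mem))
  }
  mem
}

# Local node-move refinement: sweep nodes in index order, moving each to the
# adjacent module with the largest strict modularity gain, until a full sweep
# makes no move. Deterministic; ties broken toward the smallest module label.
local_moves <- function(W, mem, max_sweeps = 100L) {
  m <- sum(W) / 2
  d <- rowSums(W)
  mem <- as.integer(factor(mem))
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(nrow(W))) {
      a <- mem[i]
      k_ic <- tapply(W[i, ], mem, sum)              # weight from i to modules
      labs <- as.integer(names(k_ic))
      D <- tapply(d, mem, sum)
      # candidates: modules adjacent to i (plus an empty module = split off)
      gain <- (k_ic - k_ic[as.character(a)]) / m -
        d[i] * (D - D[as.character(a)] + d[i] * (labs != a)) / (2 * m^2)
      gain[as.character(a)] <- 0
      # moving i out to a fresh singleton module
      split_gain <- -k_ic[[as.character(a)]] / m +
        d[i] * (D[[as.character(a)]] - d[i]) / (2 * m^2)
      best_lab <- labs[which.max(gain)]
      best_gain <- max(gain)
      if (split_gain > best_gain + 1e-12 && sum(mem == a) > 1L) {
        mem[i] <- max(mem) + 1L
        moved <- TRUE
      } else if (best_gain > 1e-12 && best_lab != a) {
        mem[i] <- best_lab
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(factor(mem))
}

#' Detect network modules by modularity maximization
#'
#' Partitions the nodes of a weighted niche-overlap network to maximize the
#' weighted Newman–Girvan modularity ([modularity_q()]). Three strategies:
#' \describe{
#'   \item{greedy}{CNM-style greedy agglomeration from singletons followed by
#'     a local node-move refinement pass (default).}
#'   \item{multilevel}{alternates local node moves and greedy agglomeration
#'     until neither improves Q.}
#'   \item{exhaustive}{enumerates every partition of the connected nodes —
#'     the exact optimum, refused beyond 12 connected nodes.}
#' }
#' All three are deterministic: ties are broken toward the lexicographically
#' smallest node pair (agglomeration) or smallest module label (node moves).
#' Isolated (degree-0) nodes are kept as singleton modules but excluded from
#' the reported module count `n_modules`.
#'
#' @param network an [build_network()] object or symmetric weight matrix.
#' @param method `"greedy"`, `"multilevel"` or `"exhaustive"`.
#' @return object of class `module_partition`: list with `membership`
#'   (named integer vector), `Q`, `n_modules`, `method`.
#' @export
detect_modules <- function(network,
                           method = c("greedy", "multilevel", "exhaustive")) {
  method <- match.arg(method)
  W <- network_weights(network)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  nodes <- rownames(W) %||% as.character(seq_len(n))
  deg <- rowSums(W)
  connected <- deg > 0

  if (!any(connected)) {
    mem <- canonical_membership(seq_len(n), nodes)
    return(structure(list(membership = mem, Q = NA_real_, n_modules = 0L,
                          method = method), class = "module_partition"))
  }

  Wc <- W[connected, connected, drop = FALSE]
  nc <- nrow(Wc)
  if (method == "exhaustive") {
    if (nc > 12L)
      stop("exhaustive search refused: ", nc, " connected nodes (limit 12); ",
           "use method = 'greedy' or 'multilevel'", call. = FALSE)
    memc <- exhaustive_partition(Wc)$membership
  } else if (method == "greedy") {
    memc <- local_moves(Wc, greedy_agglomerate(Wc))
  } else {
    memc <- seq_len(nc)
    q_prev <- -Inf
    repeat {
      memc <- local_moves(Wc, greedy_agglomerate(Wc, memc))
      q <- modularity_q(Wc, memc)
      if (q <= q_prev + 1e-12) break
      q_prev <- q
    }
  }

  mem <- integer(n)
  mem[connected] <- memc
  mem[!connected] <- max(memc) + seq_len(sum(!connected))
  mem <- canonical_membership(mem, nodes)
  structure(list(membership = mem,
                 Q = modularity_q(W, mem),
                 n_modules = length(unique(mem[connected])),
                 method = method),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition (", x$method, "): ", x$n_modules,
      " modules among connected nodes, Q = ", sprintf("%.4f", x$Q), "\n",
      sep = "")
  invisible(x)
}
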