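#' Community structure: modularity, Louvain detection, dependence pairs
#'
#' Directed trade networks are symmetrized for community analysis
#' (A' = A + t(A)), the treatment the usual Louvain toolchain applies to
#' directed graphs; a directed-modularity variant is out of scope.
#'
#' @name communities
NULL

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sym_adj <- function(net, weighted = TRUE, rescale = FALSE) {
  stopifnot(inherits(net, "trade_network"))
  a <- if (weighted) net$weights else {
    if (is.null(net$binary)) stop("communities: binarize the network first ",
                                  "or use weighted = TRUE", call. = FALSE)
    net$binary + 0
  }
  if (rescale) a <- a / 1e6  # USD -> millions; Q is scale-invariant
  a + t(a)
}

# modularity of a membership vector on a symmetric weighted adjacency
.q_of <- function(a, comm, resolution = 1) {
  m2 <- sum(a)  # 2m
  if (m2 <= 0) stop("modularity: empty graph (m = 0)", call. = FALSE)
  k <- rowSums(a)
  q <- 0
  for (c in unique(comm)) {
    idx <- which(comm == c)
    e_c <- sum(a[idx, idx, drop = FALSE])
    a_c <- sum(k[idx])
    q <- q + e_c / m2 - resolution * (a_c / m2)^2
  }
  q
}

#' Newman modularity of a partition
#'
#' Q = 1/(2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) on the
#' symmetrized adjacency; unweighted mode treats every edge weight as 1.
#'
#' @param net a `trade_network` (binarized if `weighted = FALSE`).
#' @param partition named vector or list mapping node -> community id, or an
#'   unnamed vector in node order.
#' @param weighted use USD weights (default) or the binary adjacency.
#' @param resolution resolution parameter gamma (1 = classic modularity).
#' @return the modularity Q, in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, partition, weighted = TRUE, resolution = 1) {
  a <- .sym_adj(net, weighted)
  comm <- .as_membership(partition, net$nodes)
  .q_of(a, comm, resolution)
}

.as_membership <- function(partition, nodes) {
  if (is.list(partition)) partition <- unlist(partition)
  if (!is.null(names(partition))) {
    miss <- setdiff(nodes, names(partition))
    if (length(miss) > 0L) {
      stop("partition does not cover nodes: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    partition <- partition[nodes]
  } else if (length(partition) != length(nodes)) {
    stop("partition length must equal node count", call. = FALSE)
  }
  as.integer(factor(partition))
}

# one Louvain level: local moves on symmetric adjacency a, seeded visit
# order, optional non-singleton starting assignment
.louvain_local <- function(a, resolution, order_idx, init = NULL) {
  n <- nrow(a)
  m2 <- sum(a)
  k <- rowSums(a)
  comm <- if (is.null(init)) seq_len(n) else as.integer(init)
  tot <- as.numeric(rowsum(k, factor(comm, levels = seq_len(n))))
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order_idx) {
      ci <- comm[i]
      nb <- which(a[i, ] > 0 & seq_len(n) != i)
      if (length(nb) == 0L) next
      # weight from i to each candidate community
      w_to <- tapply(a[i, nb], comm[nb], sum)
      cand <- as.integer(names(w_to))
      m <- m2 / 2
      tot_ci_less_i <- tot[ci] - k[i]
      w_i_ci <- if (ci %in% cand) w_to[[as.character(ci)]] else 0
      tot_excl <- tot[cand] - ifelse(cand == ci, k[i], 0)
      # gain of moving i from ci to c, relative to staying put:
      #   (k_{i,c} - k_{i,ci\i})/m - gamma * k_i (tot_c - tot_{ci\i})/(2 m^2)
      gain <- (as.numeric(w_to) - w_i_ci) / m -
        resolution * k[i] * (tot_excl - tot_ci_less_i) / (2 * m^2)
      # first-encountered candidate wins ties in the seeded scan order
      best <- which(gain > 1e-12)
      if (length(best) > 0L) {
        best <- best[which.max(gain[best])]
        cb <- cand[best]
        if (cb != ci) {
          tot[ci] <- tot[ci] - k[i]
          tot[cb] <- tot[cb] + k[i]
          comm[i] <- cb
          moved <- TRUE
          improved_any <- TRUE
        }
      }
    }
    if (!moved) break
  }
  # relabel to contiguous 1..k in numeric order (factor() would sort "10" < "2")
  list(comm = match(comm, sort(unique(comm))), improved = improved_any)
}

#' Louvain community detection
#'
#' Greedy two-phase modularity maximization: seeded local node moves that
#' only accept Q-improving relocations, then aggregation of communities into
#' super-nodes, repeated until no pass improves Q. Deterministic for a given
#' seed (the node visit order is the seeded shuffle).
#'
#' @param net a `trade_network` (binarized if `weighted = FALSE`).
#' @param weighted use USD weights (default) or binary adjacency.
#' @param seed integer seed controlling the visit order.
#' @param resolution resolution parameter gamma.
#' @param rescale divide weights by 1e6 before optimizing (numeric comfort;
#'   partitions and Q are scale-invariant).
#' @param restarts number of independent seeded runs (default 10); the best-Q partition
#'   wins (greedy local moves are order-sensitive, so a few deterministic
#'   restarts buy real quality on small graphs). Still fully reproducible
#'   from `seed`.
#' @return a `community_partition`: list with `assignment` (named node ->
#'   community id, ids 1..k), `q` (modularity recomputed on the input
#'   graph), `n_communities`, `sizes`, and `q_trace` (Q after each pass of
#'   the winning run, non-decreasing).
#' @export
louvain <- function(net, weighted = TRUE, seed = 1L, resolution = 1,
                    rescale = FALSE, restarts = 10L) {
  a <- .sym_adj(net, weighted, rescale = rescale)
  if (sum(a) <= 0) stop("louvain: empty graph", call. = FALSE)
  nodes <- net$nodes
  best <- NULL
  n0 <- nrow(a)
  for (r in seq_len(max(1L, restarts))) {
    sub_seed <- as.integer(seed) + (r - 1L) * 1009L
    # restart 1 is the classic singleton start; later restarts begin from a
    # seeded random coarse assignment, which lets the greedy moves reach
    # optima a singleton start cannot
    init <- if (r == 1L) NULL else {
      with_seed(sub_seed + 500000L,
                sample.int(max(2L, ceiling(n0 / 3)), n0, replace = TRUE))
    }
    run <- .louvain_run(a, resolution, sub_seed, init = init)
    if (is.null(best) || run$q > best$q + 1e-12) best <- run
  }
  comm <- match(best$node2comm, sort(unique(best$node2comm)))
  structure(list(assignment = stats::setNames(comm, nodes),
                 q = best$q,
                 n_communities = length(unique(comm)),
                 sizes = as.integer(table(comm)),
                 q_trace = best$trace,
                 weighted = weighted,
                 resolution = resolution,
                 seed = as.integer(seed)),
            class = "community_partition")
}

# one full two-phase run (local moves + aggregation until no improvement)
.louvain_run <- function(a, resolution, level_seed, init = NULL) {
  n0 <- nrow(a)
  node2comm <- seq_len(n0)  # membership on the original nodes
  trace <- numeric(0)
  level_a <- a

  repeat {
    nl <- nrow(level_a)
    order_idx <- with_seed(level_seed, sample.int(nl))
    res <- .louvain_local(level_a, resolution, order_idx, init = init)
    init <- NULL  # only the first level of a restart uses the custom start
    node2comm <- res$comm[node2comm]
    trace <- c(trace, .q_of(a, node2comm, resolution))
    if (!res$improved || length(unique(res$comm)) == nl) break
    # aggregate communities into super-nodes; row u of the aggregate is
    # community u because res$comm is contiguous 1..k
    g <- factor(res$comm, levels = seq_len(max(res$comm)))
    agg <- rowsum(level_a, g)
    agg <- t(rowsum(t(agg), g))
    level_a <- agg
    level_seed <- level_seed + 1L
  }

  list(node2comm = node2comm, q = .q_of(a, node2comm, resolution),
       trace = trace)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities (sizes %s), Q = %.4f\n",
              x$n_communities, paste(x$sizes, collapse = "/"), x$q))
  invisible(x)
}

#' Brute-force maximum-modularity partition (small graphs)
#'
#' Exhaustive search over all set partitions; exponential, intended as an
#' oracle for graphs of at most ~10 nodes.
#'
#' @param net a `trade_network`.
#' @param weighted use weights or binary adjacency.
#' @param resolution resolution parameter.
#' @return list `assignment`, `q`.
#' @export
brute_force_modularity <- function(net, weighted = TRUE, resolution = 1) {
  a <- .sym_adj(net, weighted)
  n <- nrow(a)
  if (n > 10L) stop("brute_force_modularity: n > 10 is unreasonable",
                    call. = FALSE)
  best_q <- -Inf
  best <- NULL
  # enumerate restricted-growth strings
  rec <- function(i, assign, maxc) {
    if (i > n) {
      q <- .q_of(a, assign, resolution)
      if (q > best_q) {
        best_q <<- q
        best <<- assign
      }
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) {
      assign[i] <- c
      rec(i + 1L, assign, max(maxc, c))
    }
  }
  rec(1L, integer(n), 0L)
  list(assignment = stats::setNames(best, net$nodes), q = best_q)
}

#' Absolute-dependence pairs
#'
#' An importer "absolutely depends" on a supplier when that supplier's share
#' of the importer's total imports reaches the threshold theta. With
#' theta > 0.5 at most one supplier can qualify per importer. The threshold
#' is a modelling choice (default 0.5) and is always reported with the
#' output.
#'
#' @param flows a `trade_flows` object.
#' @param year calendar year.
#' @param theta share threshold in (0, 1].
#' @return data frame `dependent`, `supplier`, `share`, ordered by
#'   dependent; attribute `theta`.
#' @export
dependence_pairs <- function(flows, year, theta = 0.5) {
  if (!is.numeric(theta) || theta <= 0 || theta > 1) {
    stop("dependence_pairs: theta must be in (0, 1]", call. = FALSE)
  }
  fy <- flows[flows$year == year & flows$value > 0, , drop = FALSE]
  out <- data.frame(dependent = character(0), supplier = character(0),
                    share = numeric(0), stringsAsFactors = FALSE)
  for (imp in sort(unique(fy$importer))) {
    sub <- fy[fy$importer == imp, , drop = FALSE]
    tot <- sum(sub$value)
    sh <- tapply(sub$value, sub$exporter, sum) / tot
    hit <- sh[sh >= theta]
    if (length(hit) > 0L) {
      out <- rbind(out, data.frame(dependent = imp,
                                   supplier = names(hit),
                                   share = as.numeric(hit),
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  structure(out, theta = theta)
}
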