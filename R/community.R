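#' Weighted-graph container for community detection
#'
#' @param a symmetric nonnegative adjacency/weight matrix (zero diagonal).
#' @return a `weighted_graph`: list with `a`, node strengths `k` (row sums)
#'   and total edge weight `m = sum(a)/2`.
#' @export
weighted_graph <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  if (any(a < 0)) stop("negative weight; cluster on the positive subgraph")
  diag(a) <- 0
  structure(list(a = a, k = rowSums(a), m = sum(a) / 2),
            class = "weighted_graph")
}

#' Positive subgraph of an estimated network
#'
#' Community detection targets comorbidity (positive) associations, and the
#' modularity null model is undefined for negative strengths, so negative
#' edges are dropped (and counted) before clustering.
#'
#' @param net an `ising_network` (or list with symmetric `w`).
#' @return a `weighted_graph` of the positive edges; attribute
#'   `"n_negative_dropped"` counts the discarded negative edges.
#' @export
positive_subgraph <- function(net) {
  w <- net$w
  n_neg <- sum(w[upper.tri(w)] < 0)
  a <- ifelse(w > 0, w, 0)
  g <- weighted_graph(a)
  attr(g, "n_negative_dropped") <- n_neg
  g
}

#' Modularity of a partition
#'
#' Exact evaluation of
#' `Q = 1/(2m) * sum_ij (A_ij - gamma * k_i * k_j / (2m)) * delta(c_i, c_j)`
#' with `m` the total edge weight, `k_i` the node strengths and `gamma` the
#' resolution parameter (usually 1). An edgeless graph has `Q = 0`.
#'
#' @param g a `weighted_graph` (or nonnegative symmetric matrix).
#' @param labels community label per node (any atomic type).
#' @param gamma_res resolution parameter (default 1).
#' @return numeric modularity.
#' @export
modularity_q <- function(g, labels, gamma_res = 1) {
  if (!inherits(g, "weighted_graph")) g <- weighted_graph(g)
  p <- nrow(g$a)
  if (length(labels) != p) stop("labels must cover all nodes")
  if (g$m == 0) return(0)
  same <- outer(labels, labels, "==")
  sum((g$a - gamma_res * outer(g$k, g$k) / (2 * g$m)) * same) / (2 * g$m)
}

## modularity change from merging communities u, v given the community-level
## weight fractions e (between) and a (incident): dQ = 2 * (e_uv - g a_u a_v)
dq_merge <- function(e_uv, a_u, a_v, gamma_res) {
  2 * (e_uv - gamma_res * a_u * a_v)
}

#' Fast-greedy modularity community detection
#'
#' Agglomerative modularity maximization: start from singleton communities
#' and repeatedly merge the pair with the largest modularity gain, ties
#' broken by the lexicographically lowest community-id pair so the result
#' is deterministic. The full merge history is recorded and the partition
#' is cut at the maximum modularity reached along the path (earliest
#' occurrence on ties, so zero-gain merges of isolated nodes are not taken
#' and isolated nodes end as singletons).
#'
#' @param g a `weighted_graph` (nonnegative weights; see
#'   [positive_subgraph()]).
#' @param gamma_res resolution parameter of the modularity null model
#'   (default 1).
#' @return a `community_partition`: list with `labels` (named integer
#'   community ids, consecutive from 1), `q` (modularity of the returned
#'   partition), `gamma_res`, `merges` (data frame of the merge history
#'   with columns `step, from, into, q_after`), and `q_path` (modularity
#'   after each merge, starting from the singleton partition).
#' @export
fast_greedy <- function(g, gamma_res = 1) {
  if (!inherits(g, "weighted_graph")) g <- weighted_graph(g)
  p <- nrow(g$a)
  nodes <- colnames(g$a) %||% paste0("V", seq_len(p))
  if (p == 0) stop("empty graph")
  two_m <- 2 * g$m

  if (g$m == 0) {
    labels <- setNames(seq_len(p), nodes)
    return(structure(list(labels = labels, q = 0, gamma_res = gamma_res,
                          merges = data.frame(step = integer(0),
                                              from = integer(0),
                                              into = integer(0),
                                              q_after = numeric(0)),
                          q_path = 0),
                     class = "community_partition"))
  }

  ## community-level state: e[u,v] = fraction of total weight between u and v
  ## (e[u,u] = within-u fraction), a[u] = k_u / 2m
  e <- unname(g$a) / two_m
  a <- unname(g$k) / two_m
  memb <- seq_len(p)          # current community id per node
  alive <- rep(TRUE, p)
  q <- -gamma_res * sum(a^2)  # singleton partition (diag(e) = 0 here)
  q_path <- q
  snapshots <- list(memb)
  merges <- data.frame(step = integer(0), from = integer(0),
                       into = integer(0), q_after = numeric(0))

  for (step in seq_len(p - 1)) {
    ids <- which(alive)
    best <- NULL
    for (ui in seq_along(ids)) {
      u <- ids[ui]
      for (vi in seq_along(ids)) {
        if (vi <= ui) next
        v <- ids[vi]
        dq <- dq_merge(e[u, v], a[u], a[v], gamma_res)
        if (is.null(best) || dq > best$dq + 1e-12) best <- list(u = u, v = v, dq = dq)
        ## ties: (u, v) pairs are scanned in lexicographic order, keep first
      }
    }
    u <- best$u; v <- best$v
    ## merge v into u
    e[u, ] <- e[u, ] + e[v, ]
    e[, u] <- e[, u] + e[, v]
    e[u, u] <- e[u, u]        # within-weight accumulates via the two adds
    e[v, ] <- 0; e[, v] <- 0
    a[u] <- a[u] + a[v]; a[v] <- 0
    alive[v] <- FALSE
    memb[memb == v] <- u
    q <- q + best$dq
    q_path <- c(q_path, q)
    snapshots[[length(snapshots) + 1L]] <- memb
    merges <- rbind(merges, data.frame(step = step, from = v, into = u,
                                       q_after = q))
  }

  cut <- which.max(q_path)    # earliest maximum on ties
  labels <- snapshots[[cut]]
  labels <- setNames(match(labels, unique(labels)), nodes)
  structure(list(labels = labels, q = q_path[cut], gamma_res = gamma_res,
                 merges = merges, q_path = q_path),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities, Q = %.4f (gamma = %s)\n",
              length(unique(x$labels)), x$q, format(x$gamma_res)))
  invisible(x)
}

#' Merge history as a Newick-like dendrogram string
#'
#' Serializes the full greedy agglomeration recorded by [fast_greedy()] as a
#' nested-parentheses string (no branch lengths), one leaf per node;
#' communities still separate at the end of the merge path appear as
#' children of the root.
#'
#' @param part a `community_partition`.
#' @return a single Newick-like string terminated by `;`.
#' @export
merge_newick <- function(part) {
  reps <- as.list(names(part$labels))
  for (k in seq_len(nrow(part$merges))) {
    u <- part$merges$into[k]; v <- part$merges$from[k]
    reps[[u]] <- sprintf("(%s,%s)", reps[[u]], reps[[v]])
    reps[[v]] <- NA_character_
  }
  alive <- !vapply(reps, function(r) identical(r, NA_character_), logical(1))
  roots <- unlist(reps[alive])
  if (length(roots) == 1) paste0(roots, ";") else {
    paste0("(", paste(roots, collapse = ","), ");")
  }
}

#' Write a community partition as TSV
#'
#' One `node TAB community_id` row per node; modularity and resolution in a
#' comment header.
#'
#' @param part a `community_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Q=%.10f gamma_res=%s", part$q,
                     format(part$gamma_res)), con)
  writeLines("node\tcommunity", con)
  writeLines(paste(names(part$labels), part$labels, sep = "\t"), con)
  invisible(path)
}
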