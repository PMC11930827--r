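# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, exhaustive enumeration, and
# textbook algorithms at tiny sizes.

rec <- function(patient_id, code, sex = "male", age = 65L) {
  data.frame(patient_id = patient_id, sex = factor(sex, c("male", "female")),
             age = as.integer(age), code = code, stringsAsFactors = FALSE)
}

## all-pairs shortest paths by textbook Dijkstra on distances 1/|w|
oracle_apsp <- function(w) {
  p <- nrow(w)
  d <- ifelse(w != 0, 1 / abs(w), Inf)
  diag(d) <- Inf
  out <- matrix(Inf, p, p)
  for (s in seq_len(p)) {
    dist <- rep(Inf, p); dist[s] <- 0
    done <- rep(FALSE, p)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      for (v in which(d[u, ] < Inf)) {
        if (dist[u] + d[u, v] < dist[v]) dist[v] <- dist[u] + d[u, v]
      }
    }
    out[s, ] <- dist
  }
  diag(out) <- 0
  out
}

## geodesic betweenness by exhaustive simple-path enumeration (p <= 7)
oracle_betweenness <- function(w) {
  p <- nrow(w)
  d <- ifelse(w != 0, 1 / abs(w), Inf)
  paths_between <- function(s, t) {
    res <- list()
    grow <- function(path, len) {
      u <- path[length(path)]
      if (u == t) { res[[length(res) + 1L]] <<- list(path = path, len = len); return() }
      for (v in which(is.finite(d[u, ]))) {
        if (!(v %in% path)) grow(c(path, v), len + d[u, v])
      }
    }
    grow(s, 0)
    res
  }
  btw <- rep(0, p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    geod <- ps[abs(lens - min(lens)) < 1e-12]
    for (g in geod) {
      mid <- setdiff(g$path, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(geod)
    }
  }
  btw
}

## all set partitions of n items as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) { out[[length(out) + 1L]] <<- labels; return() }
    m <- if (length(labels)) max(labels) else 0L
    for (l in seq_len(m + 1L)) grow(c(labels, l))
  }
  grow(integer(0))
  out
}

## independent modularity evaluation: literal double sum
oracle_modularity <- function(a, labels, gamma = 1) {
  m <- sum(a) / 2
  if (m == 0) return(0)
  k <- rowSums(a)
  q <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (labels[i] == labels[j]) q <- q + a[i, j] - gamma * k[i] * k[j] / (2 * m)
  }
  q / (2 * m)
}

## exhaustive-search optimal modularity partition (p <= 8)
oracle_best_partition <- function(a, gamma = 1) {
  parts <- all_partitions(nrow(a))
  qs <- vapply(parts, function(l) oracle_modularity(a, l, gamma), numeric(1))
  list(q = max(qs), labels = parts[[which.max(qs)]])
}

## exact Ising configuration distribution by direct enumeration
oracle_ising_exact <- function(w, b) {
  p <- length(b)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  un <- apply(states, 1, function(x) {
    s <- 0
    for (i in seq_len(p - 1)) for (j in (i + 1):p) s <- s + w[i, j] * x[i] * x[j]
    exp(s + sum(b * x))
  })
  cbind(states, prob = un / sum(un))
}

## proximal coordinate descent for l1-penalized logistic regression,
## glmnet objective: mean(log(1+e^eta) - y*eta) + lambda * ||beta||_1
cd_objective <- function(X, y, b0, beta, lambda) {
  eta <- as.numeric(b0 + X %*% beta)
  mean(log1p(exp(eta)) - y * eta) + lambda * sum(abs(beta))
}

cd_lasso_logistic <- function(X, y, lambda, max_iter = 200000, tol = 1e-13) {
  n <- nrow(X); p <- ncol(X)
  b0 <- 0; beta <- rep(0, p)
  soft <- function(z, t) sign(z) * max(abs(z) - t, 0)
  obj <- cd_objective(X, y, b0, beta, lambda)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(b0 + X %*% beta)
    pr <- 1 / (1 + exp(-eta))
    b0 <- b0 - mean(pr - y) / 0.25                # majorized Newton step
    for (j in seq_len(p)) {
      eta <- as.numeric(b0 + X %*% beta)
      pr <- 1 / (1 + exp(-eta))
      grad <- mean(X[, j] * (pr - y))
      L <- 0.25 * mean(X[, j]^2)
      if (L == 0) next
      beta[j] <- soft(beta[j] - grad / L, lambda / L)
    }
    new_obj <- cd_objective(X, y, b0, beta, lambda)
    if (abs(obj - new_obj) < tol) break
    obj <- new_obj
  }
  list(b0 = b0, beta = beta, obj = cd_objective(X, y, b0, beta, lambda))
}

## hand-computable comorbidity-rate table: P(other | index)
oracle_comorbidity_rate <- function(records, index, other) {
  pats <- function(cd) unique(records$patient_id[records$code == cd])
  length(intersect(pats(index), pats(other))) / length(pats(index))
}

edge_set <- function(w) which(upper.tri(w) & w != 0)

edge_f1 <- function(w_true, w_est) {
  t <- edge_set(w_true); e <- edge_set(w_est)
  tp <- length(intersect(t, e))
  if (tp == 0) return(0)
  2 * tp / (2 * tp + length(setdiff(e, t)) + length(setdiff(t, e)))
}
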