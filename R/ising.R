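#' Conditional activation probability under an Ising network
#'
#' Evaluates the model's defining conditional for node `i`:
#' `P(x_i = 1 | x_-i) = logistic(b_i + sum_{j != i} w_ij x_j)`.
#'
#' @param net an `ising_network` (or any list with symmetric `w`, vector
#'   `b`, and optional `labels`).
#' @param x binary vector with one entry per node (node `i`'s own entry is
#'   ignored; the diagonal of `w` is zero).
#' @param i node index or label.
#' @return probability in (0, 1).
#' @export
conditional_probability <- function(net, x, i) {
  w <- net$w; b <- net$b
  p <- length(b)
  if (is.character(i)) {
    i <- match(i, colnames(w))
    if (is.na(i)) stop("unknown node label")
  }
  if (i < 1 || i > p) stop("unknown node index")
  if (length(x) != p) stop("x must have one entry per node")
  if (!all(x %in% c(0, 1))) stop("x must be binary")
  unname(plogis(b[i] + sum(w[, i] * x) - w[i, i] * x[i]))
}

## glmnet-convention lambda_max for penalized logistic with intercept:
## smallest lambda at which every slope is zero.
lambda_max_logistic <- function(X, y) {
  n <- length(y)
  ybar <- mean(y)
  max(abs(crossprod(X, y - ybar))) / n
}

#' Build the l1 regularization path
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty that zeroes
#' every slope) down to `ratio * lambda_max`, glmnet-style.
#'
#' @param X predictor matrix, `y` binary response.
#' @param y binary response vector.
#' @param n_lambda path length (default 100).
#' @param ratio smallest/largest lambda ratio (default 0.01).
#' @return decreasing numeric vector of penalties.
#' @export
lambda_path <- function(X, y, n_lambda = 100L, ratio = 0.01) {
  lmax <- lambda_max_logistic(X, y)
  if (lmax <= 0) lmax <- 1e-3   # degenerate: uncorrelated or constant y
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Extended BIC for a fitted logistic model
#'
#' `EBIC = -2 * loglik + df * log(n) + 2 * gamma * df * log(p_cand)` where
#' `df` counts nonzero slopes (the unpenalized intercept is excluded) and
#' `p_cand` is the number of candidate predictors (`p - 1` in node-wise
#' Ising estimation). `gamma = 0` reduces EBIC to BIC.
#'
#' @param loglik log-likelihood (vectorized over models).
#' @param df number of nonzero slopes.
#' @param n sample size.
#' @param p_cand number of candidate predictors.
#' @param gamma EBIC sparsity hyperparameter (default 0.25).
#' @return numeric EBIC value(s).
#' @export
ebic <- function(loglik, df, n, p_cand, gamma = 0.25) {
  -2 * loglik + df * log(n) + 2 * gamma * df * log(p_cand)
}

#' Node-wise l1-regularized logistic fit with EBIC selection
#'
#' Fits column `i` of the binary matrix on all other columns with an l1
#' penalty on the slopes (intercept unpenalized, predictors not
#' standardized — 0/1 columns share a scale) over a regularization path,
#' computes the EBIC of every path point and selects the minimizer. This is
#' one node of the eLasso estimator. A constant column cannot be regressed;
#' it is returned with all-zero slopes, intercept at the empirical log-odds
#' (Haldane-corrected), and `degenerate = TRUE`.
#'
#' @param X `comorbidity_matrix` or plain 0/1 matrix.
#' @param i node index or column label.
#' @param gamma EBIC hyperparameter (default 0.25, the estimator's usual
#'   default).
#' @param lambda optional penalty path; default is [lambda_path()] on this
#'   node's regression.
#' @param n_lambda,lambda_ratio path parameters when `lambda` is `NULL`.
#' @return a `nodewise_fit`: list with `node`, `labels` (predictor labels),
#'   `lambda`, `beta` (predictors x path matrix of slopes), `intercept`
#'   (per path point), `loglik`, `df`, `ebic`, `selected` (path index
#'   minimizing EBIC), `coef` (selected slopes, named), `b` (selected
#'   intercept), `degenerate`.
#' @export
fit_node <- function(X, i, gamma = 0.25, lambda = NULL,
                     n_lambda = 100L, lambda_ratio = 0.01) {
  x <- if (inherits(X, "comorbidity_matrix")) X$x else as.matrix(X)
  p <- ncol(x)
  if (p < 2) stop("need at least two columns")
  if (is.character(i)) i <- match(i, colnames(x))
  y <- x[, i]
  preds <- x[, -i, drop = FALSE]
  labels <- colnames(x)[-i] %||% paste0("V", seq_len(p)[-i])
  n <- length(y)

  if (min(table(factor(y, levels = 0:1))) < 2) {
    ## constant or near-constant column: no estimable regression
    k <- sum(y)
    b0 <- qlogis((k + 0.5) / (n + 1))    # empirical log-odds limit
    return(structure(list(
      node = colnames(x)[i] %||% paste0("V", i), labels = labels,
      lambda = numeric(0), beta = matrix(0, length(labels), 0),
      intercept = numeric(0), loglik = numeric(0), df = integer(0),
      ebic = numeric(0), selected = NA_integer_,
      coef = setNames(rep(0, length(labels)), labels), b = b0,
      degenerate = TRUE), class = "nodewise_fit"))
  }

  if (all(apply(preds, 2, function(cc) length(unique(cc))) == 1L)) {
    ## every candidate predictor is constant: only the null model exists
    p1 <- mean(y)
    ll0 <- sum(y * log(p1) + (1 - y) * log(1 - p1))
    return(structure(list(
      node = colnames(x)[i] %||% paste0("V", i), labels = labels,
      lambda = NA_real_, beta = matrix(0, length(labels), 1,
                                       dimnames = list(labels, NULL)),
      intercept = qlogis(p1), loglik = ll0, df = 0L,
      ebic = ebic(ll0, 0L, n, p - 1, gamma), selected = 1L,
      coef = setNames(rep(0, length(labels)), labels), b = qlogis(p1),
      degenerate = FALSE), class = "nodewise_fit"))
  }

  if (is.null(lambda)) {
    lambda <- lambda_path(preds, y, n_lambda = n_lambda, ratio = lambda_ratio)
  }
  ## glmnet requires >= 2 predictor columns; pad with an all-zero dummy
  ## (coefficient identically 0) for the two-node case
  dummy <- ncol(preds) == 1L
  if (dummy) preds <- cbind(preds, 0L)
  ## glmnet warns about rare classes; rarity is handled by the degenerate
  ## branch above, so the warning is noise here
  fit <- suppressWarnings(
    glmnet::glmnet(preds, y, family = "binomial", lambda = lambda,
                   standardize = FALSE, intercept = TRUE,
                   thresh = 1e-10, maxit = 1e6))
  beta <- as.matrix(fit$beta)
  if (dummy) beta <- beta[-nrow(beta), , drop = FALSE]
  ## coefficients at the path boundary can come back as numerical dust
  ## (~1e-16); they are zero for support counting and symmetrization
  beta[abs(beta) < 1e-7] <- 0
  rownames(beta) <- labels
  intercept <- as.numeric(fit$a0)
  ## binary response: saturated loglik = 0, so loglik = -deviance / 2
  loglik <- -(1 - fit$dev.ratio) * fit$nulldev / 2
  df <- colSums(beta != 0)
  crit <- ebic(loglik, df, n, p_cand = p - 1, gamma = gamma)
  sel <- which.min(crit)
  structure(list(
    node = colnames(x)[i] %||% paste0("V", i), labels = labels,
    lambda = fit$lambda, beta = beta, intercept = intercept,
    loglik = loglik, df = df, ebic = crit, selected = sel,
    coef = setNames(beta[, sel], labels), b = intercept[sel],
    degenerate = FALSE), class = "nodewise_fit")
}

#' Symmetrize node-wise fits into an Ising network
#'
#' Each ordered pair of nodes has two regression coefficients
#' (`i` on `j` and `j` on `i`). Under the `AND` rule (default) the edge
#' weight is their mean when both are nonzero and 0 otherwise; under `OR`
#' the mean of the nonzero members when at least one is nonzero. Thresholds
#' are the selected intercepts. The result is exactly symmetric with a zero
#' diagonal.
#'
#' @param fits list of `nodewise_fit` objects, one per node, in column
#'   order.
#' @param rule `"AND"` or `"OR"`.
#' @param n sample size the fits used (stored for reporting).
#' @param gamma EBIC hyperparameter used (stored).
#' @return an `ising_network`: list with `w` (symmetric weight matrix, zero
#'   diagonal, labelled), `b` (named threshold vector), `n`, `gamma`,
#'   `rule`, `degenerate` (logical per node).
#' @export
symmetrize <- function(fits, rule = c("AND", "OR"), n = NA_integer_,
                       gamma = NA_real_) {
  rule <- match.arg(rule)
  p <- length(fits)
  labels <- vapply(fits, `[[`, character(1), "node")
  if (anyDuplicated(labels)) stop("node labels must be unique")
  raw <- matrix(0, p, p, dimnames = list(labels, labels))
  for (k in seq_len(p)) raw[k, fits[[k]]$labels] <- fits[[k]]$coef
  w <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- raw[i, j]; bb <- raw[j, i]
      wij <- if (a != 0 && bb != 0) {
        (a + bb) / 2
      } else if (rule == "OR" && (a != 0 || bb != 0)) {
        a + bb   # the single nonzero member
      } else 0
      w[i, j] <- w[j, i] <- wij
    }
  }
  structure(list(
    w = w, b = setNames(vapply(fits, `[[`, numeric(1), "b"), labels),
    labels = labels, n = n, gamma = gamma, rule = rule,
    degenerate = setNames(vapply(fits, `[[`, logical(1), "degenerate"),
                          labels)),
    class = "ising_network")
}

#' Estimate the comorbidity network by eLasso
#'
#' Runs [fit_node()] for every column of the binary matrix and symmetrizes
#' the selected coefficients into an Ising network: per-node l1-regularized
#' logistic regression over a log-spaced penalty path, EBIC model selection
#' and the AND (or OR) combination rule. A positive edge weight means the
#' two diseases co-occur more often than their remaining associations
#' explain; a negative weight, less often. Deterministic given the matrix
#' and hyperparameters; row order is irrelevant.
#'
#' @param X `comorbidity_matrix` or 0/1 matrix with at least two columns.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule symmetrization rule, `"AND"` (default) or `"OR"`.
#' @param n_lambda,lambda_ratio regularization-path specification
#'   (default 100 points down to 0.01 of `lambda_max`).
#' @param keep_fits keep the full per-node path objects in the result
#'   (`$fits`) for auditing (default `FALSE`).
#' @return an `ising_network`; see [symmetrize()].
#' @export
fit_ising <- function(X, gamma = 0.25, rule = c("AND", "OR"),
                      n_lambda = 100L, lambda_ratio = 0.01,
                      keep_fits = FALSE) {
  rule <- match.arg(rule)
  x <- if (inherits(X, "comorbidity_matrix")) X$x else as.matrix(X)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  fits <- lapply(seq_len(ncol(x)), function(i) {
    fit_node(x, i, gamma = gamma, n_lambda = n_lambda,
             lambda_ratio = lambda_ratio)
  })
  net <- symmetrize(fits, rule = rule, n = nrow(x), gamma = gamma)
  if (keep_fits) net$fits <- fits
  net
}

#' @export
print.ising_network <- function(x, ...) {
  ne <- sum(x$w[upper.tri(x$w)] != 0)
  cat(sprintf("Ising network: %d nodes, %d edges (%s rule, EBIC gamma=%s, n=%s)\n",
              length(x$b), ne, x$rule,
              format(x$gamma), format(x$n)))
  if (any(x$degenerate)) {
    cat("  degenerate (constant) nodes:",
        paste(names(which(x$degenerate)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the weighted edge list of a network
#'
#' @param net an `ising_network` (or list with symmetric `w`).
#' @param positive_only keep only positive-weight edges.
#' @return data frame `from, to, weight` (upper triangle, nonzero weights),
#'   ordered lexicographically.
#' @export
edge_list <- function(net, positive_only = FALSE) {
  w <- net$w
  labels <- colnames(w)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  out <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                    weight = w[idx], stringsAsFactors = FALSE)
  if (positive_only) out <- out[out$weight > 0, , drop = FALSE]
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}
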