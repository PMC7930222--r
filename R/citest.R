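#' Linear partial-correlation conditional-independence test
#'
#' Tests the hypothesis that `x` and `y` are independent given the
#' conditioning set `z` under a linear-Gaussian model: both variables are
#' regressed on `z` (with intercept) and the Pearson correlation of the
#' residuals is referred to a two-sided Student-t null with
#' `n - |z| - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @param z optional conditioning matrix (columns = conditions) or vector;
#'   `NULL` or zero columns gives the unconditional correlation test.
#' @return A `ci_test` result: list with `statistic` (partial correlation),
#'   `p_value`, `n_eff` and `cond_dim`.
#' @export
parcorr_test <- function(x, y, z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  Z <- cond_matrix(z, n)
  d <- ncol(Z)
  if (n < d + 3) stop("sample too small: need n >= |z| + 3 (n = ", n,
                      ", |z| = ", d, ")")
  D <- cbind(1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("singular regression design in conditioning set")
  rx <- qr.resid(qrD, x)
  ry <- qr.resid(qrD, y)
  denom <- sqrt(sum(rx^2) * sum(ry^2))
  if (denom < 1e-300) stop("degenerate residuals (constant input?)")
  r <- max(-1, min(1, sum(rx * ry) / denom))
  df <- n - d - 2
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  structure(list(statistic = r, p_value = p, n_eff = n, cond_dim = d),
            class = "ci_test")
}

cond_matrix <- function(z, n) {
  if (is.null(z)) return(matrix(numeric(0), n, 0))
  Z <- as.matrix(z)
  if (!ncol(Z)) return(matrix(numeric(0), n, 0))
  if (nrow(Z) != n) stop("conditioning set length does not match x/y")
  storage.mode(Z) <- "double"
  Z
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("<ci_test> statistic %.4f, p %.4g, n_eff %d, |Z| %d\n",
              x$statistic, x$p_value, x$n_eff, x$cond_dim))
  invisible(x)
}

#' Parameters for the k-NN conditional mutual information test
#'
#' @param k neighbours in the joint space (>= 1; a rule of thumb is
#'   5--15 for a few hundred to a few thousand samples).
#' @param n_permutations permutation-null size B (>= 19 for any useful
#'   significance resolution).
#' @param seed integer seed controlling the permutations and the tie-breaking
#'   jitter.
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 10, n_permutations = 200, seed = 42) {
  stopifnot(k >= 1, n_permutations >= 1)
  structure(list(k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "knn_config")
}

#' k-nearest-neighbour conditional mutual information estimate
#'
#' Model-free estimate of I(X; Y | Z) in nats by the k-NN entropy-estimator
#' construction: for each sample the maximum-norm distance `eps_i` to its
#' k-th neighbour in the joint space X (x) Y (x) Z is found, neighbours with
#' distance strictly smaller than `eps_i` are counted in the marginal
#' subspaces X (x) Z, Y (x) Z and Z, and the estimate is
#' `digamma(k) + mean(digamma(k_z + 1) - digamma(k_xz + 1) - digamma(k_yz + 1))`.
#' With an empty Z every point qualifies in the Z subspace (`k_z = n - 1`)
#' and the expression reduces to the standard k-NN mutual-information
#' estimator. Exact duplicate points would produce zero distances; a
#' deterministic, seeded jitter of relative scale 1e-10 breaks them.
#' Estimates are not clipped: small negative values occur under independence
#' and are reported as-is.
#'
#' @inheritParams parcorr_test
#' @param k neighbours in the joint space; must satisfy `k + 2 <= n`.
#' @param jitter_seed seed of the deterministic tie-breaking jitter.
#' @return CMI estimate in nats (scalar).
#' @export
cmi_knn <- function(x, y, z = NULL, k = 10, jitter_seed = 7L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  Z <- cond_matrix(z, n)
  if (k >= n - 1) stop("k (", k, ") must be smaller than n - 1 (n = ", n, ")")
  M <- cbind(x, y, Z)
  M <- jitter_ties(M, jitter_seed)
  dx <- abs(outer(M[, 1], M[, 1], "-"))
  dy <- abs(outer(M[, 2], M[, 2], "-"))
  dz <- matrix(0, n, n)
  if (ncol(Z)) {
    for (c in seq_len(ncol(Z))) {
      dz <- pmax(dz, abs(outer(M[, 2 + c], M[, 2 + c], "-")))
    }
  }
  dxz <- pmax(dx, dz)
  dyz <- pmax(dy, dz)
  dj <- pmax(dxz, dy)
  diag(dj) <- Inf
  eps <- vapply(seq_len(n),
                function(i) sort(dj[i, ], partial = k)[k], 0.0)
  kz  <- if (ncol(Z)) rowSums(dz  < eps) - 1L else rep(n - 1L, n)
  kxz <- rowSums(dxz < eps) - 1L
  kyz <- rowSums(dyz < eps) - 1L
  digamma(k) + mean(digamma(kz + 1) - digamma(kxz + 1) - digamma(kyz + 1))
}

# deterministic tiny jitter breaking exact duplicates, column-wise scaled
jitter_ties <- function(M, seed) {
  dup <- vapply(seq_len(ncol(M)), function(c) anyDuplicated(M[, c]) > 0, TRUE)
  if (!any(dup)) return(M)
  with_seed(seed, {
    for (c in which(dup)) {
      s <- stats::sd(M[, c])
      if (s == 0) s <- 1
      M[, c] <- M[, c] + stats::rnorm(nrow(M), sd = 1e-10 * s)
    }
  })
  M
}

#' Permutation test of conditional independence based on k-NN CMI
#'
#' Computes the CMI estimate of [cmi_knn()] and compares it with the null
#' distribution obtained by recomputing the estimate after random
#' permutations of the `x` samples (conditioning and `y` untouched). The
#' p-value is `(1 + #{permuted >= observed}) / (B + 1)`, so its resolution
#' is `1 / (B + 1)`.
#'
#' @inheritParams cmi_knn
#' @param config a [knn_config()] (k, permutation count B, seed).
#' @return A `ci_test` result (statistic = CMI in nats). If B is too small
#'   to resolve small p-values (B < 19) the result carries attribute
#'   `low_resolution = TRUE`.
#' @export
cmi_knn_test <- function(x, y, z = NULL, config = knn_config()) {
  stopifnot(inherits(config, "knn_config"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  Z <- cond_matrix(z, n)
  k <- config$k
  B <- config$n_permutations
  obs <- cmi_knn(x, y, Z, k = k, jitter_seed = config$seed)
  null <- with_seed(config$seed, {
    vapply(seq_len(B), function(b) {
      cmi_knn(x[sample.int(n)], y, Z, k = k, jitter_seed = config$seed)
    }, 0.0)
  })
  p <- (1 + sum(null >= obs)) / (B + 1)
  res <- structure(list(statistic = obs, p_value = p, n_eff = n,
                        cond_dim = ncol(Z)),
                   class = "ci_test")
  if (B < 19) attr(res, "low_resolution") <- TRUE
  res
}
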