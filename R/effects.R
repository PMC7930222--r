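#' Fit lag-specific path coefficients on the discovered graph
#'
#' For each target component, regresses the target on all of its discovered
#' parents jointly (one multiple linear regression per target over the common
#' alignment window), and places the coefficients in the array
#' `phi[target, source, lag + 1]`. Entries without a discovered link are
#' exactly zero, and the lag-0 slice is zero by construction (no
#' contemporaneous links). The joint regression — rather than pairwise fits —
#' is what gives the coefficients path-coefficient semantics. On standardized
#' data the coefficients are effects per standard deviation.
#'
#' @param series the [roi_ts()] the graph was discovered on.
#' @param graph a `ts_graph` from [run_pcmci()].
#' @return Object of class `path_coefficients`: list with `phi`
#'   (N x N x (tau_max + 1), dimnames lag `0..tau_max`), `tau_max`, `labels`.
#' @export
fit_path_coefficients <- function(series, graph) {
  stopifnot(inherits(series, "roi_ts"), inherits(graph, "ts_graph"))
  X <- series$values
  Tn <- nrow(X)
  n <- ncol(X)
  tau_max <- graph$tau_max
  phi <- array(0, dim = c(n, n, tau_max + 1L),
               dimnames = list(series$labels, series$labels, NULL))
  t_index <- (tau_max + 1L):Tn
  for (j in seq_len(n)) {
    pj <- graph$links[graph$links$target == j, , drop = FALSE]
    if (!nrow(pj)) next
    Z <- vapply(seq_len(nrow(pj)), function(m)
      lag_col(X, pj$source[m], pj$lag[m], t_index),
      numeric(length(t_index)))
    D <- cbind(1, Z)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      stop("collinear parent design for target '", series$labels[j],
           "' (parents: ",
           paste(sprintf("%s lag %d", series$labels[pj$source], pj$lag),
                 collapse = ", "), ")")
    }
    beta <- qr.coef(qrD, X[t_index, j])[-1]
    phi[cbind(j, pj$source, pj$lag + 1L)] <- beta
  }
  structure(list(phi = phi, tau_max = tau_max, labels = series$labels),
            class = "path_coefficients")
}

#' @export
print.path_coefficients <- function(x, ...) {
  cat(sprintf("<path_coefficients> N = %d, lags 1..%d, %d nonzero\n",
              dim(x$phi)[1], x$tau_max, sum(x$phi != 0)))
  invisible(x)
}

# accept a path_coefficients object or a bare [N, N, tau_max+1] array
phi_of <- function(phi) {
  if (inherits(phi, "path_coefficients")) phi$phi
  else if (is.array(phi) && length(dim(phi)) == 3) phi
  else stop("phi must be a path_coefficients object or an N x N x (tau_max+1) array")
}

#' Accumulate direct and indirect causal effects over lags
#'
#' Computes the causal-effect matrices `psi[, , tau + 1]`, where
#' `psi[j, i, tau + 1]` is the total effect of a one-standard-deviation
#' perturbation of component i on component j after `tau` steps, summed over
#' every directed path whose lags total `tau`. The accumulation is the
#' impulse-response recursion
#' `psi(0) = I`, `psi(tau) = sum_{s=1}^{tau} phi(s) %*% psi(tau - s)`,
#' which is equivalent to propagating a noiseless unit impulse through the
#' linear system.
#'
#' @param phi a `path_coefficients` object or bare coefficient array.
#' @param tau_max horizon; defaults to the phi array's lag range.
#' @return Object of class `ce_matrices`: list with `psi`
#'   (N x N x (tau_max + 1)), `tau_max`, `labels`.
#' @export
causal_effect_matrices <- function(phi, tau_max = NULL) {
  labels <- if (inherits(phi, "path_coefficients")) phi$labels else
    dimnames(phi_of(phi))[[1]]
  ph <- phi_of(phi)
  stopifnot(all(is.finite(ph)))
  n <- dim(ph)[1]
  p <- dim(ph)[3] - 1L
  if (is.null(tau_max)) tau_max <- p
  psi <- array(0, dim = c(n, n, tau_max + 1L))
  if (!is.null(labels)) dimnames(psi) <- list(labels, labels, NULL)
  psi[, , 1] <- diag(n)
  for (tau in seq_len(tau_max)) {
    acc <- matrix(0, n, n)
    for (s in seq_len(min(tau, p))) {
      acc <- acc + ph[, , s + 1L] %*% psi[, , tau - s + 1L]
    }
    psi[, , tau + 1L] <- acc
  }
  structure(list(psi = psi, tau_max = tau_max, labels = labels),
            class = "ce_matrices")
}

#' Mediated causal effect through one component, by path blocking
#'
#' Blocks every link whose target is component `k` (zeroing row `k` of every
#' coefficient matrix), recomputes the accumulated effects, and returns the
#' difference: `mce[j, i, tau + 1]` is the portion of the causal effect
#' `i -> j` at lag `tau` carried by paths passing through `k`. For a pair
#' whose every path runs through `k` the mediated effect equals the total
#' effect; for a pair with no path through `k` it is exactly zero.
#'
#' @param phi a `path_coefficients` object or bare array.
#' @param k mediator component index (1..N).
#' @param tau_max horizon (default: phi's lag range).
#' @return list with `mce` (N x N x (tau_max + 1) array), `psi`, the blocked
#'   `psi_blocked`, and `k`.
#' @export
mediated_causal_effect <- function(phi, k, tau_max = NULL) {
  ph <- phi_of(phi)
  n <- dim(ph)[1]
  if (k < 1 || k > n) stop("k must be in 1..", n)
  full <- causal_effect_matrices(phi, tau_max)
  ph_blocked <- ph
  ph_blocked[k, , ] <- 0
  blocked <- causal_effect_matrices(ph_blocked, tau_max %||% (dim(ph)[3] - 1L))
  list(mce = full$psi - blocked$psi, psi = full$psi,
       psi_blocked = blocked$psi, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# boolean reachability: exists[j, i, tau + 1] = some directed path i -> j
# with lags totalling tau (same recursion as psi, in the boolean semiring)
path_exists_array <- function(ph, tau_max) {
  n <- dim(ph)[1]
  p <- dim(ph)[3] - 1L
  A <- ph != 0
  E <- array(FALSE, dim = c(n, n, tau_max + 1L))
  E[, , 1] <- diag(n) > 0
  for (tau in seq_len(tau_max)) {
    acc <- matrix(FALSE, n, n)
    for (s in seq_len(min(tau, p))) {
      acc <- acc | ((A[, , s + 1L] %*% (E[, , tau - s + 1L] * 1)) > 0)
    }
    E[, , tau + 1L] <- acc
  }
  E
}

#' Aggregate causal-effect measures per component
#'
#' From the accumulated effect matrices, computes for every ordered pair the
#' maximum absolute effect over lags `1..tau_max` (`ce_max`), and per
#' component: the aggregated causal effect ACE (mean of `ce_max` over all
#' other targets — how strongly the component drives the rest of the
#' network), the aggregated causal susceptibility ACS (mean over all other
#' sources — how strongly it is driven), and the aggregated mediated causal
#' effect AMCE (mean, over the ordered pairs `(i, j)` with
#' `i != j, i != k, j != k` that have at least one causal path through `k`
#' within the horizon, of the maximum absolute mediated effect). Components
#' mediating no pair have AMCE 0 by convention.
#'
#' @param phi a `path_coefficients` object or bare array.
#' @param tau_max horizon (default: phi's lag range).
#' @return Object of class `aggregate_measures`: list with `ce_max`
#'   (N x N, row = target, column = source), `ace`, `acs`, `amce`,
#'   `c_k_cardinality` (named length-N vectors) and `tau_max`.
#' @export
aggregate_measures <- function(phi, tau_max = NULL) {
  ph <- phi_of(phi)
  labels <- dimnames(ph)[[1]] %||% sprintf("X%d", seq_len(dim(ph)[1]))
  n <- dim(ph)[1]
  if (n < 2) stop("aggregate measures need at least 2 components")
  ce <- causal_effect_matrices(phi, tau_max)
  tau_max <- ce$tau_max
  # max over lags 1..tau_max of |psi|; lag 0 (identity) excluded
  ce_max <- apply(abs(ce$psi[, , -1, drop = FALSE]), c(1, 2), max)
  diag_excl <- !diag(n)
  ace <- vapply(seq_len(n), function(i)
    mean(ce_max[diag_excl[, i], i]), 0.0)
  acs <- vapply(seq_len(n), function(j)
    mean(ce_max[j, diag_excl[j, ]]), 0.0)
  E <- path_exists_array(ph, tau_max)
  amce <- numeric(n)
  card <- integer(n)
  for (k in seq_len(n)) {
    # pair (i, j) mediated by k: path i -> k (lag tau1 >= 1) and k -> j
    # (lag tau2 >= 1) with tau1 + tau2 <= tau_max
    min_in <- rep(Inf, n); min_out <- rep(Inf, n)
    for (tau in seq_len(tau_max - 1L)) {
      min_in[E[k, , tau + 1L] & min_in > tau] <- tau
      min_out[E[, k, tau + 1L] & min_out > tau] <- tau
    }
    mk <- mediated_causal_effect(ph, k, tau_max)
    mce_max <- apply(abs(mk$mce[, , -1, drop = FALSE]), c(1, 2), max)
    vals <- numeric(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || i == k || j == k) next
      if (is.finite(min_in[i]) && is.finite(min_out[j]) &&
          min_in[i] + min_out[j] <= tau_max) {
        vals <- c(vals, mce_max[j, i])
      }
    }
    card[k] <- length(vals)
    amce[k] <- if (length(vals)) mean(vals) else 0
  }
  names(ace) <- names(acs) <- names(amce) <- names(card) <- labels
  dimnames(ce_max) <- list(labels, labels)
  structure(list(ce_max = ce_max, ace = ace, acs = acs, amce = amce,
                 c_k_cardinality = card, tau_max = tau_max, labels = labels),
            class = "aggregate_measures")
}

#' @export
as.data.frame.aggregate_measures <- function(x, ...) {
  data.frame(roi = x$labels, ace = unname(x$ace), acs = unname(x$acs),
             amce = unname(x$amce),
             n_mediated_pairs = unname(x$c_k_cardinality),
             stringsAsFactors = FALSE)
}

#' @export
print.aggregate_measures <- function(x, ...) {
  cat(sprintf("<aggregate_measures> N = %d, lags 1..%d\n",
              length(x$ace), x$tau_max))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Extract the mediation subgraph of one lagged pair
#'
#' Unrolls the discovered graph over time offsets `0..tau` and keeps exactly
#' the nodes and links lying on at least one directed path from component
#' `i` at time `t - tau` to component `j` at time `t` whose link lags sum to
#' `tau`. Intermediate nodes are annotated with their mediated causal effect
#' for the pair (total effect minus the effect with paths through that node
#' blocked). An empty result (no connecting path) is returned as such, not
#' as an error.
#'
#' @param phi a `path_coefficients` object or bare array.
#' @param i,j source and target component indices.
#' @param tau lag of the queried effect (1..tau_max).
#' @return Object of class `mediation_result`: list with `i`, `j`, `tau`,
#'   `ce` (the total effect), `nodes` (data frame `component`, `label`,
#'   `offset` — time offset back from the target — and `mce`), `edges`
#'   (data frame `from`, `from_offset`, `to`, `to_offset`, `lag`,
#'   `coefficient`), and `summary_edges` (lag-collapsed unique component
#'   pairs).
#' @export
mediation_graph <- function(phi, i, j, tau) {
  ph <- phi_of(phi)
  labels <- dimnames(ph)[[1]] %||% sprintf("X%d", seq_len(dim(ph)[1]))
  n <- dim(ph)[1]
  p <- dim(ph)[3] - 1L
  stopifnot(i >= 1, i <= n, j >= 1, j <= n, tau >= 1)
  # forward reach from (i, offset tau); fwd[v, o + 1]: path from source node
  # to component v at offset o (offsets count back from the target time)
  fwd <- matrix(FALSE, n, tau + 1L)
  fwd[i, tau + 1L] <- TRUE
  for (o in (tau - 1L):0) {
    for (s in seq_len(min(p, tau - o))) {
      fwd[, o + 1L] <- fwd[, o + 1L] | ((abs(ph[, , s + 1L]) %*%
                                           (fwd[, o + s + 1L] * 1)) > 0)
    }
  }
  bwd <- matrix(FALSE, n, tau + 1L)  # node reaches (j, offset 0)
  bwd[j, 1L] <- TRUE
  for (o in seq_len(tau)) {
    for (s in seq_len(min(p, o))) {
      bwd[, o + 1L] <- bwd[, o + 1L] | ((t(abs(ph[, , s + 1L])) %*%
                                           (bwd[, o - s + 1L] * 1)) > 0)
    }
  }
  on_path <- fwd & bwd
  ce <- causal_effect_matrices(ph, tau)$psi[j, i, tau + 1L]
  if (!any(on_path)) {
    return(structure(list(i = i, j = j, tau = tau, ce = 0,
                          nodes = data.frame(), edges = data.frame(),
                          summary_edges = data.frame(), labels = labels),
                     class = "mediation_result"))
  }
  idx <- which(on_path, arr.ind = TRUE)
  nodes <- data.frame(component = idx[, 1], label = labels[idx[, 1]],
                      offset = idx[, 2] - 1L, stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$offset, nodes$component), ]
  rownames(nodes) <- NULL
  # per-component MCE for the queried pair (NA on the endpoints themselves)
  nodes$mce <- NA_real_
  mid <- setdiff(unique(nodes$component), c(i, j))
  for (k in mid) {
    mk <- mediated_causal_effect(ph, k, tau)
    nodes$mce[nodes$component == k] <- mk$mce[j, i, tau + 1L]
  }
  edges <- NULL
  for (r in seq_len(nrow(nodes))) {
    a <- nodes$component[r]; oa <- nodes$offset[r]
    for (s in seq_len(min(p, oa))) {
      ob <- oa - s
      tgts <- which(ph[, a, s + 1L] != 0 & on_path[, ob + 1L])
      if (length(tgts)) {
        edges <- rbind(edges, data.frame(
          from = a, from_offset = oa, to = tgts, to_offset = ob, lag = s,
          coefficient = ph[tgts, a, s + 1L]))
      }
    }
  }
  rownames(edges) <- NULL
  se <- unique(edges[c("from", "to", "lag", "coefficient")])
  rownames(se) <- NULL
  structure(list(i = i, j = j, tau = tau, ce = ce, nodes = nodes,
                 edges = edges, summary_edges = se, labels = labels),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s at lag %d: CE = %.4f, %d node(s), %d link(s)\n",
              x$labels[x$i], x$labels[x$j], x$tau, x$ce,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Time-resolved igraph form of a mediation subgraph
#'
#' Nodes are `(component, time offset)` pairs named `label@t-offset`, with
#' vertex attribute `mce`; edges carry the path coefficient.
#'
#' @param med a [mediation_graph()] result.
#' @return an igraph graph (empty when no path connects the pair).
#' @export
mediation_igraph <- function(med) {
  stopifnot(inherits(med, "mediation_result"))
  if (!nrow(med$nodes)) return(igraph::make_empty_graph(directed = TRUE))
  vn <- sprintf("%s@t-%d", med$nodes$label, med$nodes$offset)
  g <- igraph::make_empty_graph(n = length(vn), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = vn)
  g <- igraph::set_vertex_attr(g, "component", value = med$nodes$label)
  g <- igraph::set_vertex_attr(g, "offset", value = med$nodes$offset)
  g <- igraph::set_vertex_attr(g, "mce", value = med$nodes$mce)
  key <- paste(med$nodes$component, med$nodes$offset)
  from <- match(paste(med$edges$from, med$edges$from_offset), key)
  to <- match(paste(med$edges$to, med$edges$to_offset), key)
  igraph::add_edges(g, rbind(from, to), lag = med$edges$lag,
                    coefficient = med$edges$coefficient)
}

#' Decomposed transfer entropy between two components
#'
#' Approximates the transfer entropy from component `i` to component `j` as
#' a sum over lags `tau = 1..tau_star` of conditional mutual information
#' terms `I(X_i at t - tau ; X_j at t | S)`, where each term's condition set
#' `S` is read off the discovered graph: the target's parents (minus the
#' tested link) plus the lagged source's own parents shifted by `tau`. The
#' graphical-model structure makes each condition set finite and excludes
#' irrelevant components, avoiding the curse of dimensionality of
#' conditioning on the full past. Terms are estimated with [cmi_knn()].
#'
#' @param series the [roi_ts()] the graph was discovered on.
#' @param graph a `ts_graph`.
#' @param i,j source and target component indices.
#' @param tau_star largest lag included in the sum (<= the graph's tau_max).
#' @param knn a [knn_config()] (only `k` and `seed` are used).
#' @param max_conds refuse condition sets larger than this (estimation in
#'   high-dimensional condition spaces is unreliable at small n).
#' @return list with `dte` (the sum, nats) and `terms` (per-lag data frame).
#' @export
decomposed_transfer_entropy <- function(series, graph, i, j, tau_star,
                                        knn = knn_config(), max_conds = 10) {
  stopifnot(inherits(series, "roi_ts"), inherits(graph, "ts_graph"))
  if (tau_star > graph$tau_max) stop("tau_star exceeds the graph's tau_max")
  X <- series$values
  Tn <- nrow(X)
  parents <- graph_parent_list(graph)
  terms <- data.frame(lag = seq_len(tau_star), cmi = NA_real_,
                      cond_dim = NA_integer_)
  for (tau in seq_len(tau_star)) {
    pj <- parents[[j]]
    pj <- pj[!(pj$source == i & pj$lag == tau), , drop = FALSE]
    pi_sh <- parents[[i]]
    conds <- rbind(
      if (nrow(pj)) pj[c("source", "lag")] else NULL,
      if (nrow(pi_sh)) data.frame(source = pi_sh$source,
                                  lag = pi_sh$lag + tau) else NULL)
    conds <- if (is.null(conds)) data.frame(source = integer(),
                                            lag = integer()) else unique(conds)
    if (nrow(conds) > max_conds) {
      stop("condition set of size ", nrow(conds), " at lag ", tau,
           " exceeds max_conds = ", max_conds,
           "; raise max_conds or simplify the graph")
    }
    max_back <- max(tau, if (nrow(conds)) max(conds$lag) else 0L)
    t_index <- (max_back + 1L):Tn
    Z <- if (nrow(conds)) {
      vapply(seq_len(nrow(conds)), function(m)
        lag_col(X, conds$source[m], conds$lag[m], t_index),
        numeric(length(t_index)))
    } else NULL
    terms$cmi[tau] <- cmi_knn(lag_col(X, i, tau, t_index), X[t_index, j], Z,
                              k = knn$k, jitter_seed = knn$seed)
    terms$cond_dim[tau] <- nrow(conds)
  }
  list(dte = sum(terms$cmi), terms = terms)
}

# significant links regrouped as per-target parent tables
graph_parent_list <- function(graph) {
  lapply(seq_len(graph$n), function(j) {
    d <- graph$links[graph$links$target == j, c("source", "lag", "statistic"),
                     drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
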