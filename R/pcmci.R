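#' Worst-case conditional-independence test counts of the two-stage search
#'
#' The parent pre-selection stage performs at most `N^3 * tau_max^2` tests
#' (for each of the N targets, up to `N * tau_max` candidates are each tested
#' against condition sets of iteratively increasing cardinality), and the
#' momentary-conditional-independence stage performs exactly `N^2 * tau_max`
#' tests (every ordered pair at every positive lag), so the search is
#' polynomial overall. Actual counters of a run (see [run_pcmci()]) must
#' never exceed these bounds.
#'
#' @param n_vars number of components N (>= 1).
#' @param tau_max maximum lag (>= 1).
#' @return list with `pc_worst_case`, `mci_count`, `total`.
#' @examples
#' count_ci_tests(14, 15)  # 617400 + 2940 = 620340
#' @export
count_ci_tests <- function(n_vars, tau_max) {
  stopifnot(n_vars >= 1, tau_max >= 1)
  pc <- n_vars^3 * tau_max^2
  mci <- n_vars^2 * tau_max
  list(pc_worst_case = pc, mci_count = mci, total = pc + mci)
}

# lagged copy of component `var` aligned to target times `t_index`
lag_col <- function(X, var, lag, t_index) X[t_index - lag, var]

ci_test_fun <- function(test, knn) {
  test <- match.arg(test, c("parcorr", "cmiknn"))
  if (test == "parcorr") {
    function(x, y, Z) parcorr_test(x, y, Z)
  } else {
    function(x, y, Z) cmi_knn_test(x, y, Z, config = knn)
  }
}

#' Parent pre-selection by iterative conditional-independence filtering
#'
#' First stage of the two-stage causal search. For each target component the
#' candidate set is every `(source, lag)` with lag in `1..tau_max`. Candidates
#' are first screened unconditionally, then repeatedly re-tested conditioned
#' on the `q` strongest remaining co-parents (one condition set per
#' cardinality `q = 1, 2, ...`), removing any candidate whose test exceeds
#' `pc_alpha`, until the condition cardinality exhausts the surviving set.
#' This keeps the number of tests polynomial while shrinking each target's
#' conditioning set to an (approximate) superset of its true parents.
#'
#' @param series a [roi_ts()], preferably [preprocess()]ed.
#' @param tau_max maximum lag searched.
#' @param test `"parcorr"` or `"cmiknn"`.
#' @param pc_alpha removal threshold of this screening stage; acts as a
#'   regularization parameter rather than a calibrated level.
#' @param max_conds cap on the conditioning cardinality (default unlimited).
#' @param knn a [knn_config()] used when `test = "cmiknn"`.
#' @param counter optional environment with field `n` incremented per test.
#' @return Object of class `parent_sets`: list (one per target) of data
#'   frames `source`, `lag`, `statistic`, ordered by decreasing
#'   `|statistic|`; attribute `n_tests`.
#' @export
pc1_parent_selection <- function(series, tau_max, test = "parcorr",
                                 pc_alpha = 0.01, max_conds = Inf,
                                 knn = knn_config(), counter = NULL) {
  stopifnot(inherits(series, "roi_ts"))
  if (tau_max < 1) stop("tau_max must be >= 1")
  X <- series$values
  Tn <- nrow(X)
  n <- ncol(X)
  if (Tn < 2 * (tau_max + 1)) {
    stop("series too short: need T >= ", 2 * (tau_max + 1),
         " time points for tau_max = ", tau_max)
  }
  if (is.null(counter)) counter <- new.env()
  if (is.null(counter$n)) counter$n <- 0L
  run_test <- ci_test_fun(test, knn)
  t_index <- (tau_max + 1L):Tn
  parents <- vector("list", n)
  for (j in seq_len(n)) {
    y <- X[t_index, j]
    cand <- expand.grid(source = seq_len(n), lag = seq_len(tau_max))
    cand$statistic <- NA_real_
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      res <- run_test(lag_col(X, cand$source[r], cand$lag[r], t_index), y, NULL)
      counter$n <- counter$n + 1L
      cand$statistic[r] <- res$statistic
      keep[r] <- res$p_value <= pc_alpha
    }
    cand <- cand[keep, , drop = FALSE]
    q <- 1L
    while (nrow(cand) > q && q <= max_conds) {
      ord <- order(-abs(cand$statistic), cand$source, cand$lag)
      cand <- cand[ord, , drop = FALSE]
      drop <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        others <- setdiff(seq_len(nrow(cand)), r)
        zi <- others[seq_len(q)]
        Z <- vapply(zi, function(m)
          lag_col(X, cand$source[m], cand$lag[m], t_index),
          numeric(length(t_index)))
        res <- run_test(lag_col(X, cand$source[r], cand$lag[r], t_index), y, Z)
        counter$n <- counter$n + 1L
        if (res$p_value > pc_alpha) {
          drop[r] <- TRUE
        } else if (abs(res$statistic) < abs(cand$statistic[r])) {
          cand$statistic[r] <- res$statistic  # rank by weakest evidence seen
        }
      }
      cand <- cand[!drop, , drop = FALSE]
      q <- q + 1L
    }
    ord <- order(-abs(cand$statistic), cand$source, cand$lag)
    parents[[j]] <- cand[ord, , drop = FALSE]
    rownames(parents[[j]]) <- NULL
  }
  structure(parents, names = series$labels, class = "parent_sets",
            n_tests = counter$n)
}

#' Momentary conditional independence tests over all pairs and lags
#'
#' Second stage of the search: for every ordered pair `(i, j)` and every lag
#' `tau` in `1..tau_max`, tests the lagged source against the target
#' conditioned on the target's selected parents (minus the tested link) and
#' the source's own parents shifted back by `tau`. Conditioning on both
#' parent sets removes dependence inherited from autocorrelation and common
#' drivers, which keeps false-positive rates of cross-links at the nominal
#' level. Because shifted source parents reach back up to `2 * tau_max`, all
#' tests share the common alignment window of length `T - 2 * tau_max`, so
#' every test has the same effective sample size.
#'
#' @inheritParams pc1_parent_selection
#' @param parents a `parent_sets` object from [pc1_parent_selection()].
#' @param alpha significance level used to flag links (all results kept).
#' @return Object of class `ts_graph` whose `all_results` data frame holds
#'   `source`, `target`, `lag`, `statistic`, `p_value` for every tested link
#'   and whose `links` data frame is the subset with `p_value <= alpha`.
#' @export
mci_link_test <- function(series, parents, tau_max, test = "parcorr",
                          alpha = 0.01, knn = knn_config(), counter = NULL) {
  stopifnot(inherits(series, "roi_ts"), inherits(parents, "parent_sets"))
  X <- series$values
  Tn <- nrow(X)
  n <- ncol(X)
  if (Tn <= 2 * tau_max + 3) {
    stop("series too short for MCI alignment: need T > ", 2 * tau_max + 3)
  }
  if (is.null(counter)) counter <- new.env()
  if (is.null(counter$n)) counter$n <- 0L
  run_test <- ci_test_fun(test, knn)
  t_index <- (2L * tau_max + 1L):Tn
  res <- expand.grid(source = seq_len(n), target = seq_len(n),
                     lag = seq_len(tau_max))
  res$statistic <- NA_real_
  res$p_value <- NA_real_
  for (r in seq_len(nrow(res))) {
    i <- res$source[r]; j <- res$target[r]; tau <- res$lag[r]
    pj <- parents[[j]]
    pj <- pj[!(pj$source == i & pj$lag == tau), , drop = FALSE]
    pi_sh <- parents[[i]]
    conds <- rbind(
      if (nrow(pj)) data.frame(source = pj$source, lag = pj$lag) else NULL,
      if (nrow(pi_sh)) data.frame(source = pi_sh$source,
                                  lag = pi_sh$lag + tau) else NULL)
    if (!is.null(conds) && nrow(conds)) {
      conds <- unique(conds)
      Z <- vapply(seq_len(nrow(conds)), function(m)
        lag_col(X, conds$source[m], conds$lag[m], t_index),
        numeric(length(t_index)))
    } else {
      Z <- NULL
    }
    out <- run_test(lag_col(X, i, tau, t_index), X[t_index, j], Z)
    counter$n <- counter$n + 1L
    res$statistic[r] <- out$statistic
    res$p_value[r] <- out$p_value
  }
  new_ts_graph(res, n = n, tau_max = tau_max, alpha = alpha,
               labels = series$labels,
               n_eff = length(t_index), n_tests_mci = counter$n)
}

new_ts_graph <- function(all_results, n, tau_max, alpha, labels, n_eff,
                         n_tests_pc = NA_integer_, n_tests_mci = NA_integer_) {
  links <- all_results[all_results$p_value <= alpha, , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links, all_results = all_results, n = n,
                 tau_max = tau_max, alpha = alpha, labels = labels,
                 n_eff = n_eff,
                 n_tests = list(pc = n_tests_pc, mci = n_tests_mci)),
            class = "ts_graph")
}

#' @export
print.ts_graph <- function(x, ...) {
  cat(sprintf("<ts_graph> N = %d, tau_max = %d, alpha = %g: %d link(s) (%d auto, %d cross)\n",
              x$n, x$tau_max, x$alpha, nrow(x$links),
              sum(x$links$source == x$links$target),
              sum(x$links$source != x$links$target)))
  invisible(x)
}

#' Two-stage lag-specific causal discovery
#'
#' Runs parent pre-selection ([pc1_parent_selection()]) followed by the
#' momentary conditional independence tests ([mci_link_test()]) and returns
#' the time-series graph whose links `(source, lag, target)`, all with lag
#' `>= 1`, have MCI p-values at or below `alpha`. Defaults (`tau_max = 15`,
#' `alpha = 0.01`, partial-correlation test) match the intended task-fMRI
#' application at a 2.8 s sampling interval.
#'
#' @inheritParams pc1_parent_selection
#' @param alpha significance level retaining links after the MCI stage; acts
#'   as a model-selection regularizer.
#' @param pc_alpha screening threshold of the first stage (defaults to
#'   `alpha`).
#' @return A `ts_graph` (see [mci_link_test()]) with parent sets, test
#'   counters and the worst-case bound attached.
#' @export
run_pcmci <- function(series, tau_max = 15, alpha = 0.01, test = "parcorr",
                      pc_alpha = alpha, max_conds = Inf, knn = knn_config()) {
  pc_counter <- new.env(); pc_counter$n <- 0L
  parents <- pc1_parent_selection(series, tau_max = tau_max, test = test,
                                  pc_alpha = pc_alpha, max_conds = max_conds,
                                  knn = knn, counter = pc_counter)
  mci_counter <- new.env(); mci_counter$n <- 0L
  graph <- mci_link_test(series, parents, tau_max = tau_max, test = test,
                         alpha = alpha, knn = knn, counter = mci_counter)
  graph$n_tests <- list(pc = pc_counter$n, mci = mci_counter$n,
                        total = pc_counter$n + mci_counter$n)
  graph$bound <- count_ci_tests(series_n(series), tau_max)
  stopifnot(graph$n_tests$total <= graph$bound$total)
  graph$parents <- parents
  graph
}

series_n <- function(series) ncol(series$values)

#' Export a time-series graph as a labelled edge list
#'
#' @param x a `ts_graph`.
#' @param ... unused.
#' @param all if `TRUE`, include non-significant results too.
#' @return data frame `source_label`, `target_label`, `lag`, `statistic`,
#'   `p_value`.
#' @export
as.data.frame.ts_graph <- function(x, ..., all = FALSE) {
  d <- if (all) x$all_results else x$links
  data.frame(source_label = x$labels[d$source],
             target_label = x$labels[d$target],
             lag = d$lag, statistic = d$statistic, p_value = d$p_value,
             stringsAsFactors = FALSE)
}

#' Convert the significant links to an igraph summary or time-resolved graph
#'
#' The summary form collapses lags: one node per component, one edge per
#' `(source, target)` pair annotated with its minimum-p lag. The
#' time-resolved form has one node per (component, lag offset).
#'
#' @param graph a `ts_graph`.
#' @param form `"summary"` or `"time_resolved"`.
#' @return an igraph graph.
#' @export
ts_graph_igraph <- function(graph, form = c("summary", "time_resolved")) {
  form <- match.arg(form)
  lk <- graph$links
  if (form == "summary") {
    g <- igraph::make_empty_graph(n = graph$n, directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = graph$labels)
    if (nrow(lk)) {
      key <- paste(lk$source, lk$target)
      best <- do.call(rbind, lapply(split(lk, key), function(d)
        d[which.min(d$p_value), ]))
      g <- igraph::add_edges(g, rbind(best$source, best$target),
                             lag = best$lag, statistic = best$statistic,
                             p_value = best$p_value)
    }
    g
  } else {
    offs <- 0:graph$tau_max
    vn <- as.vector(outer(graph$labels, offs,
                          function(l, o) sprintf("%s@t-%d", l, o)))
    g <- igraph::make_empty_graph(n = length(vn), directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = vn)
    if (nrow(lk)) {
      from <- (lk$lag) * graph$n + lk$source          # node at offset lag
      to <- lk$target                                  # offset 0
      g <- igraph::add_edges(g, rbind(from, to), lag = lk$lag,
                             statistic = lk$statistic, p_value = lk$p_value)
    }
    g
  }
}
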