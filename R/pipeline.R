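#' Analysis configuration with study defaults
#'
#' Collects every tunable of the pipeline in one flat object. The defaults
#' reproduce the intended task-fMRI setting: maximum lag 15 samples,
#' significance level 0.01, linear partial-correlation test, standardized
#' series. All randomness (permutation nulls, tie-breaking jitter) funnels
#' through the single `seed`.
#'
#' @param input character vector of per-component file paths, one table
#'   path, or a [roi_ts()] object directly.
#' @param labels optional component labels.
#' @param sampling_interval sampling interval in seconds (default 2.8, the
#'   repetition time of the intended application).
#' @param tau_max maximum lag of the causal search (default 15).
#' @param alpha link significance level (default 0.01).
#' @param pc_alpha screening threshold of the parent pre-selection stage
#'   (defaults to `alpha`).
#' @param ci_test `"parcorr"` or `"cmiknn"`.
#' @param knn a [knn_config()] for the CMI test.
#' @param standardize,detrend preprocessing toggles (see [preprocess()]).
#' @param max_conds conditioning-cardinality cap of the screening stage.
#' @param seed integer master seed.
#' @param screen also compute the lagged-dependence screening table.
#' @param mediation `"auto"` (the pair and lag with the largest absolute
#'   causal effect), a data frame with columns `i`, `j`, `tau`, or `NULL`
#'   for none.
#' @param dte optional data frame `i`, `j`, `tau_star` of transfer-entropy
#'   decompositions to compute.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, labels = NULL, sampling_interval = 2.8,
                            tau_max = 15, alpha = 0.01, pc_alpha = alpha,
                            ci_test = c("parcorr", "cmiknn"),
                            knn = NULL, standardize = TRUE, detrend = FALSE,
                            max_conds = Inf, seed = 1L, screen = FALSE,
                            mediation = "auto", dte = NULL) {
  ci_test <- match.arg(ci_test)
  if (is.null(knn)) knn <- knn_config(seed = seed)
  structure(list(input = input, labels = labels,
                 sampling_interval = sampling_interval,
                 tau_max = as.integer(tau_max), alpha = alpha,
                 pc_alpha = pc_alpha, ci_test = ci_test, knn = knn,
                 standardize = standardize, detrend = detrend,
                 max_conds = max_conds, seed = as.integer(seed),
                 screen = screen, mediation = mediation, dte = dte),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Read, preprocess, optionally screen lagged dependencies, discover the
#' lag-specific causal graph, fit path coefficients, accumulate causal
#' effects, compute aggregate and mediation measures, and (optionally)
#' decompose transfer entropy for requested pairs. Each stage's failure is
#' reported with the stage name. The result is fully determined by the
#' configuration, the inputs and the seed.
#'
#' @param config an [analysis_config()].
#' @return Object of class `causalts_results`: list with `series` (the
#'   preprocessed input), `lagdep` (or `NULL`), `graph`, `phi`, `psi`,
#'   `aggregates`, `mediation` (list of [mediation_graph()] results),
#'   `dte` (list), and `meta` (seed, settings, effective sample size,
#'   CI-test counters and their worst-case bound, stage timings).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  series <- stage("read", {
    if (inherits(config$input, "roi_ts")) config$input
    else read_roi_timeseries(config$input, labels = config$labels,
                             sampling_interval = config$sampling_interval)
  })
  series <- stage("preprocess",
                  preprocess(series, standardize = config$standardize,
                             detrend = config$detrend))
  lagdep <- if (isTRUE(config$screen)) {
    stage("screen", lagged_dependence(series, config$tau_max))
  } else NULL
  graph <- stage("discover",
                 run_pcmci(series, tau_max = config$tau_max,
                           alpha = config$alpha, test = config$ci_test,
                           pc_alpha = config$pc_alpha,
                           max_conds = config$max_conds, knn = config$knn))
  phi <- stage("path_coefficients", fit_path_coefficients(series, graph))
  psi <- stage("causal_effects", causal_effect_matrices(phi))
  aggregates <- stage("aggregates", aggregate_measures(phi))
  mediation <- stage("mediation", {
    req <- config$mediation
    if (is.character(req) && identical(req, "auto")) {
      cm <- aggregates$ce_max
      diag(cm) <- -Inf                       # pairs only, no self loops
      pos <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      j <- pos[["row"]]; i <- pos[["col"]]
      tau <- which.max(abs(psi$psi[j, i, -1]))
      req <- data.frame(i = i, j = j, tau = tau)
    }
    if (is.null(req) || !nrow(req)) list()
    else lapply(seq_len(nrow(req)), function(r)
      mediation_graph(phi, req$i[r], req$j[r], req$tau[r]))
  })
  dte <- stage("dte", {
    if (is.null(config$dte) || !nrow(config$dte)) list()
    else lapply(seq_len(nrow(config$dte)), function(r)
      decomposed_transfer_entropy(series, graph, config$dte$i[r],
                                  config$dte$j[r], config$dte$tau_star[r],
                                  knn = config$knn))
  })
  meta <- list(seed = config$seed, tau_max = config$tau_max,
               alpha = config$alpha, pc_alpha = config$pc_alpha,
               ci_test = config$ci_test,
               standardize = config$standardize, detrend = config$detrend,
               n_components = ncol(series$values),
               n_timepoints = nrow(series$values),
               sampling_interval = series$sampling_interval,
               n_eff = graph$n_eff, n_ci_tests = graph$n_tests,
               ci_test_bound = graph$bound,
               n_links = nrow(graph$links),
               timings = as.list(timings),
               package_version = as.character(utils::packageVersion("causalts")))
  structure(list(series = series, lagdep = lagdep, graph = graph, phi = phi,
                 psi = psi, aggregates = aggregates, mediation = mediation,
                 dte = dte, meta = meta),
            class = "causalts_results")
}

#' @export
print.causalts_results <- function(x, ...) {
  cat(sprintf("<causalts_results> N = %d, T = %d, tau_max = %d, alpha = %g\n",
              x$meta$n_components, x$meta$n_timepoints, x$meta$tau_max,
              x$meta$alpha))
  print(x$graph)
  invisible(x)
}

#' Export a results bundle as plain-text artifacts
#'
#' Writes, into `directory`: `links.tsv` (significant labelled links),
#' `ci_results.tsv` (all tested links), `ce_long.tsv` (the full
#' source x target x lag causal-effect table), `aggregates.tsv` (per-node
#' ACE/ACS/AMCE), one GraphML file per mediation result
#' (`mediation_<src>_<tgt>_lag<tau>.graphml`), `dte.tsv` when transfer
#' entropy was requested, `lagged_dependence.tsv` when screening was on, and
#' `metadata.json`. Files already written are removed again if a later
#' export step fails.
#'
#' @param bundle a [run_pipeline()] result.
#' @param directory output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
export_report <- function(bundle, directory) {
  stopifnot(inherits(bundle, "causalts_results"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create directory ", directory)
  }
  written <- character(0)
  emit <- function(name, writer) {
    f <- file.path(directory, name)
    tryCatch(writer(f), error = function(e) {
      unlink(written)
      stop("export of ", name, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    written <<- c(written, f)
  }
  tsv <- function(d) function(f) utils::write.table(
    d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("links.tsv", tsv(as.data.frame(bundle$graph)))
  emit("ci_results.tsv", tsv(as.data.frame(bundle$graph, all = TRUE)))
  labels <- bundle$graph$labels
  psi <- bundle$psi$psi
  tm <- bundle$psi$tau_max
  ce_long <- expand.grid(target = labels, source = labels, lag = seq_len(tm),
                         stringsAsFactors = FALSE)
  ce_long$ce <- as.vector(psi[, , -1])
  emit("ce_long.tsv", tsv(ce_long[c("source", "target", "lag", "ce")]))
  emit("aggregates.tsv", tsv(as.data.frame(bundle$aggregates)))
  for (med in bundle$mediation) {
    if (!nrow(med$nodes)) next
    name <- sprintf("mediation_%s_%s_lag%d.graphml",
                    med$labels[med$i], med$labels[med$j], med$tau)
    emit(name, function(f)
      igraph::write_graph(mediation_igraph(med), f, format = "graphml"))
  }
  if (length(bundle$dte)) {
    d <- do.call(rbind, lapply(bundle$dte, function(x) {
      data.frame(lag = x$terms$lag, cmi = x$terms$cmi,
                 cond_dim = x$terms$cond_dim, dte_total = x$dte)
    }))
    emit("dte.tsv", tsv(d))
  }
  if (!is.null(bundle$lagdep)) {
    emit("lagged_dependence.tsv", tsv(as.data.frame(bundle$lagdep)))
  }
  emit("metadata.json", function(f)
    jsonlite::write_json(bundle$meta, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  invisible(written)
}
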