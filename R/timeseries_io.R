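#' Read ROI time series from single-column files or a delimited table
#'
#' Accepts either (a) a vector of paths, one single-column whitespace text
#' file per component — the layout written by ROI-mean extraction tools such
#' as fslmeants and by [write_fixture()] — or (b) a single path to a
#' delimited table with rows = time points and columns = components. The
#' table dialect (tab, comma or whitespace; with or without a header row) is
#' sniffed and can be overridden.
#'
#' @param paths character vector of file paths (multi-file mode) or one path
#'   (table mode is used when the file has more than one column).
#' @param labels optional component labels; defaults to file base names
#'   (multi-file mode) or table column names.
#' @param sampling_interval sampling interval in seconds.
#' @param delimiter optional explicit field separator for table mode.
#' @return A [roi_ts()] with columns in the order given.
#' @export
read_roi_timeseries <- function(paths, labels = NULL, sampling_interval = 1,
                                delimiter = NULL) {
  paths <- as.character(paths)
  if (!length(paths)) stop("no input paths given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input file(s) not found: ",
                            paste(missing, collapse = ", "))
  if (length(paths) == 1 && n_fields(paths, delimiter) > 1) {
    return(read_roi_table(paths, labels, sampling_interval, delimiter))
  }
  cols <- lapply(paths, read_numeric_column)
  lens <- vapply(cols, length, 1L)
  if (length(unique(lens)) > 1) {
    stop("time series length mismatch: ",
         paste(sprintf("%s (%d)", basename(paths), lens), collapse = ", "))
  }
  if (is.null(labels)) labels <- sub("\\.[^.]*$", "", basename(paths))
  roi_ts(do.call(cbind, cols), labels = labels,
         sampling_interval = sampling_interval)
}

read_numeric_column <- function(path) {
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt)]
  vals <- suppressWarnings(as.numeric(txt))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric token '%s' at line %d of %s",
                 txt[bad], bad, path))
  }
  vals
}

n_fields <- function(path, delimiter = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (is.null(delimiter)) "[\t, ]+" else delimiter
  length(strsplit(trimws(first), sep)[[1]])
}

read_roi_table <- function(path, labels, sampling_interval, delimiter) {
  first <- strsplit(trimws(readLines(path, n = 1L, warn = FALSE)),
                    if (is.null(delimiter)) "[\t, ]+" else delimiter)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  dt <- if (is.null(delimiter)) {
    data.table::fread(path, header = has_header, data.table = FALSE)
  } else {
    data.table::fread(path, header = has_header, sep = delimiter,
                      data.table = FALSE)
  }
  if (!all(vapply(dt, is.numeric, TRUE))) {
    bad <- names(dt)[!vapply(dt, is.numeric, TRUE)][1]
    stop("non-numeric column '", bad, "' in ", path)
  }
  if (is.null(labels)) {
    labels <- if (has_header) names(dt) else sprintf("X%d", seq_along(dt))
  }
  roi_ts(as.matrix(dt), labels = labels, sampling_interval = sampling_interval)
}

#' Pre-condition a series for causal analysis
#'
#' Optionally removes a per-component linear trend, then optionally
#' standardizes each component to mean 0 and unit variance. Standardization
#' puts all downstream path coefficients and causal effects on the
#' per-standard-deviation scale, making them comparable across components.
#'
#' @param series a [roi_ts()].
#' @param standardize center and scale each component (default `TRUE`).
#' @param detrend remove the least-squares linear trend first (default
#'   `FALSE`).
#' @return A [roi_ts()] of the same shape.
#' @export
preprocess <- function(series, standardize = TRUE, detrend = FALSE) {
  stopifnot(inherits(series, "roi_ts"))
  X <- series$values
  if (detrend) {
    tt <- seq_len(nrow(X))
    X <- apply(X, 2, function(col) stats::lm.fit(cbind(1, tt), col)$residuals)
  }
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    zero <- sds < 1e-12
    if (any(zero)) {
      stop("zero-variance component(s): ",
           paste(series$labels[zero], collapse = ", "))
    }
    X <- scale(X, center = TRUE, scale = sds)
    attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  }
  roi_ts(X, labels = series$labels,
         sampling_interval = series$sampling_interval)
}

#' Lagged unconditional dependencies between all component pairs
#'
#' Computes `dep[i, j, tau] = |dependence(X_i at t - tau, X_j at t)|` for
#' `tau = 1..tau_max`, the screening quantity used to choose the maximum lag
#' of the causal analysis: one looks for the lag beyond which all pairwise
#' dependencies have decayed.
#'
#' @param series a [roi_ts()].
#' @param tau_max largest lag screened (>= 1).
#' @param measure `"correlation"` (absolute Pearson correlation, in `[0,1]`,
#'   cheap; the default) or `"mutual_information"` (k-NN estimate, nats,
#'   sensitive to nonlinear dependence).
#' @param k neighbours for the mutual-information measure.
#' @return Object of class `lagged_dependence`: list with `dep`
#'   (N x N x tau_max array, source x target x lag), `measure`, `labels`.
#' @export
lagged_dependence <- function(series, tau_max,
                              measure = c("correlation", "mutual_information"),
                              k = 10) {
  stopifnot(inherits(series, "roi_ts"))
  measure <- match.arg(measure)
  if (tau_max < 1) stop("tau_max must be >= 1")
  X <- series$values
  Tn <- nrow(X)
  n <- ncol(X)
  if (Tn <= tau_max + 2) stop("need T > tau_max + 2 time points")
  dep <- array(NA_real_, dim = c(n, n, tau_max),
               dimnames = list(series$labels, series$labels, 1:tau_max))
  for (tau in seq_len(tau_max)) {
    now <- (tau + 1):Tn
    for (i in seq_len(n)) {
      past <- X[now - tau, i]
      for (j in seq_len(n)) {
        dep[i, j, tau] <- if (measure == "correlation") {
          abs(stats::cor(past, X[now, j]))
        } else {
          cmi_knn(past, X[now, j], k = k)
        }
      }
    }
  }
  structure(list(dep = dep, measure = measure, labels = series$labels),
            class = "lagged_dependence")
}

#' @export
print.lagged_dependence <- function(x, ...) {
  cat(sprintf("<lagged_dependence> %d components, lags 1..%d, measure %s\n",
              dim(x$dep)[1], dim(x$dep)[3], x$measure))
  invisible(x)
}

#' Export lagged dependencies as a long table
#'
#' @param x a `lagged_dependence` object.
#' @param ... unused.
#' @return data frame with columns `source`, `target`, `lag`, `value`.
#' @export
as.data.frame.lagged_dependence <- function(x, ...) {
  d <- dim(x$dep)
  g <- expand.grid(source = x$labels, target = x$labels, lag = seq_len(d[3]),
                   stringsAsFactors = FALSE)
  g$value <- as.vector(x$dep)
  g
}

#' Suggest a maximum analysis lag from the dependence decay
#'
#' Returns the smallest lag `tau` such that the largest dependence over all
#' component pairs at every lag `>= tau` lies below `threshold` — i.e. the
#' horizon beyond which lagged dependence has decayed. If the dependencies
#' never decay below the threshold within the screened horizon, the horizon
#' itself is returned with attribute `below_threshold = FALSE` and a warning.
#'
#' @param lagdep a [lagged_dependence()] result.
#' @param threshold decay threshold on the dependence scale (default 0.2 on
#'   the absolute-correlation scale).
#' @return Integer lag with attribute `below_threshold`.
#' @export
suggest_tau_max <- function(lagdep, threshold = 0.2) {
  stopifnot(inherits(lagdep, "lagged_dependence"))
  horizon <- dim(lagdep$dep)[3]
  peak <- apply(lagdep$dep, 3, max)
  tail_max <- rev(cummax(rev(peak)))   # max over lags >= tau
  ok <- which(tail_max < threshold)
  if (length(ok)) {
    structure(as.integer(ok[1]), below_threshold = TRUE)
  } else {
    warning("lagged dependencies never decay below ", threshold,
            " within the screened horizon of ", horizon, " lags")
    structure(as.integer(horizon), below_threshold = FALSE)
  }
}
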