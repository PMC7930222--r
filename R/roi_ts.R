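#' Multivariate ROI time series
#'
#' Container for an observed multivariate process: a numeric matrix with one
#' row per time point and one column per labelled component (e.g. the mean
#' BOLD signal of a region of interest), together with the sampling interval
#' in seconds.
#'
#' @param values numeric matrix, T time points x N components; all finite.
#' @param labels character vector of N unique component labels.
#' @param sampling_interval sampling interval in seconds (scalar > 0).
#'
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(values, labels = NULL, sampling_interval = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- sprintf("X%d", seq_len(ncol(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("number of labels (", length(labels), ") does not match number of columns (",
         ncol(values), ")")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate component labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop("non-finite values in component '", labels[bad[1, 2]],
         "' at time point ", bad[1, 1],
         " (missing values are rejected, not imputed)")
  }
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1 ||
      sampling_interval <= 0) {
    stop("sampling_interval must be a positive scalar (seconds)")
  }
  colnames(values) <- labels
  structure(list(values = values, labels = labels,
                 sampling_interval = as.numeric(sampling_interval)),
            class = "roi_ts")
}

#' @export
as.matrix.roi_ts <- function(x, ...) x$values

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d time points x %d components, sampling interval %g s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  cat("components:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# run expr with a temporary RNG state seeded by `seed`; global state restored
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
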