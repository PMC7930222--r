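#' Specify a lagged linear stochastic process with known causal structure
#'
#' Builds a ground-truth vector-autoregressive model in which every directed
#' influence is a lag-specific link `source -> target` at lag `lag >= 1` with
#' a fixed coefficient. Contemporaneous (lag-0) links are excluded by
#' assumption: at the sampling resolutions this package targets, same-sample
#' dependence cannot be oriented and the causal Markov condition requires all
#' influences to take at least one time step.
#'
#' The implied linear system must be stable: the spectral radius of the
#' companion-form transition matrix must be strictly below 1, otherwise the
#' process has no stationary distribution and the model is rejected.
#'
#' @param n_vars number of components N.
#' @param links data frame (or list coercible to one) with columns `source`,
#'   `target` (component indices in 1..N), `lag` (integer >= 1) and
#'   `coefficient` (real, interpreted per standard deviation of the driving
#'   component). `NULL` or zero rows gives a pure-noise model.
#' @param noise_sd innovation standard deviation(s); scalar or length N.
#' @param labels N unique component labels; defaults to X1..XN.
#' @param max_lag optional explicit model order; defaults to the largest lag
#'   among the links (1 for an empty link set).
#'
#' @return An object of class `var_model` with fields `n_vars`, `max_lag`,
#'   `links`, `noise_sd`, `labels` and the verified `spectral_radius`.
#' @examples
#' m <- make_var_model(3, data.frame(source = 1, target = 2, lag = 2,
#'                                   coefficient = 0.5))
#' m$spectral_radius
#' @export
make_var_model <- function(n_vars, links = NULL, noise_sd = 1, labels = NULL,
                           max_lag = NULL) {
  if (!is.numeric(n_vars) || length(n_vars) != 1 || n_vars < 1 ||
      n_vars != round(n_vars)) {
    stop("n_vars must be a positive integer")
  }
  n_vars <- as.integer(n_vars)
  if (is.null(links) || (is.data.frame(links) && nrow(links) == 0)) {
    links <- data.frame(source = integer(), target = integer(),
                        lag = integer(), coefficient = numeric())
  }
  links <- as.data.frame(links)
  need <- c("source", "target", "lag", "coefficient")
  if (!all(need %in% names(links))) {
    stop("links must have columns ", paste(need, collapse = ", "))
  }
  links <- links[need]
  if (nrow(links)) {
    if (any(links$lag < 1 | links$lag != round(links$lag))) {
      stop("all link lags must be integers >= 1 (no contemporaneous links)")
    }
    if (any(links$source < 1 | links$source > n_vars |
            links$target < 1 | links$target > n_vars)) {
      stop("link source/target indices must be in 1..", n_vars)
    }
    key <- paste(links$source, links$target, links$lag)
    if (anyDuplicated(key)) {
      stop("duplicate link specification for (source, target, lag): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    links$source <- as.integer(links$source)
    links$target <- as.integer(links$target)
    links$lag <- as.integer(links$lag)
  }
  if (is.null(max_lag)) max_lag <- if (nrow(links)) max(links$lag) else 1L
  max_lag <- as.integer(max_lag)
  if (nrow(links) && max_lag < max(links$lag)) {
    stop("max_lag smaller than the largest link lag")
  }
  noise_sd <- rep_len(as.numeric(noise_sd), n_vars)
  if (any(!is.finite(noise_sd) | noise_sd <= 0)) {
    stop("noise_sd must be positive for every component")
  }
  if (is.null(labels)) labels <- sprintf("X%d", seq_len(n_vars))
  labels <- as.character(labels)
  if (length(labels) != n_vars) stop("need exactly ", n_vars, " labels")
  if (anyDuplicated(labels)) stop("labels must be unique")

  model <- structure(list(n_vars = n_vars, max_lag = max_lag, links = links,
                          noise_sd = noise_sd, labels = labels),
                     class = "var_model")
  rho <- companion_spectral_radius(model)
  if (rho >= 1) {
    stop(sprintf(paste0("unstable coefficient set: companion spectral radius ",
                        "%.4f >= 1; the process has no stationary solution"), rho))
  }
  model$spectral_radius <- rho
  model
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> N = %d, order %d, %d link(s), spectral radius %.3f\n",
              x$n_vars, x$max_lag, nrow(x$links), x$spectral_radius))
  invisible(x)
}

# lag-indexed coefficient array phi[target, source, lag + 1]; lag 0 slice is 0
phi_array <- function(model) {
  phi <- array(0, dim = c(model$n_vars, model$n_vars, model$max_lag + 1L),
               dimnames = list(model$labels, model$labels, NULL))
  if (nrow(model$links)) {
    phi[cbind(model$links$target, model$links$source, model$links$lag + 1L)] <-
      model$links$coefficient
  }
  phi
}

companion_spectral_radius <- function(model) {
  n <- model$n_vars
  p <- model$max_lag
  phi <- phi_array(model)
  A <- matrix(0, n * p, n * p)
  for (s in seq_len(p)) A[1:n, ((s - 1) * n + 1):(s * n)] <- phi[, , s + 1L]
  if (p > 1) {
    idx <- seq_len(n * (p - 1))
    A[cbind(n + idx, idx)] <- 1
  }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Simulate a realization of a lagged linear stochastic process
#'
#' Draws i.i.d. Gaussian innovations and propagates them through the model's
#' lag-specific links. An initial burn-in segment (default ten model orders)
#' is simulated from zero initial conditions and discarded so the retained
#' segment is approximately a draw from the stationary distribution.
#'
#' @param model a `var_model` from [make_var_model()].
#' @param n_samples number of retained time points T (>= 1).
#' @param burn_in discarded initial time points; must be >= the model order.
#' @param seed integer seed for reproducibility (`NULL` leaves the RNG alone).
#' @param sampling_interval sampling interval attached to the output, seconds.
#' @param link_transform optional function applied to the driving (lagged)
#'   value before multiplication by the coefficient, e.g. `function(u) u^2`
#'   to make a link nonlinear. Default `NULL` keeps every link linear. The
#'   stability guarantee only covers the linear case.
#'
#' @return A [roi_ts()] with `n_samples` rows and the model's labels.
#' @export
simulate_process <- function(model, n_samples, burn_in = 10L * model$max_lag,
                             seed = NULL, sampling_interval = 1,
                             link_transform = NULL) {
  stopifnot(inherits(model, "var_model"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (burn_in < model$max_lag) {
    stop("burn_in must be at least the model order (", model$max_lag, ")")
  }
  total <- as.integer(burn_in + n_samples)
  n <- model$n_vars
  sim <- function() {
    X <- matrix(rnorm(total * n), total, n) *
      matrix(model$noise_sd, total, n, byrow = TRUE)
    lk <- model$links
    if (nrow(lk)) {
      f <- if (is.null(link_transform)) identity else match.fun(link_transform)
      src <- lk$source; tgt <- lk$target; lag <- lk$lag; cf <- lk$coefficient
      for (t in seq_len(total)) {
        for (r in seq_along(cf)) {
          if (lag[r] < t) {
            X[t, tgt[r]] <- X[t, tgt[r]] + cf[r] * f(X[t - lag[r], src[r]])
          }
        }
      }
    }
    X
  }
  X <- if (is.null(seed)) sim() else with_seed(seed, sim())
  roi_ts(X[(burn_in + 1L):total, , drop = FALSE], labels = model$labels,
         sampling_interval = sampling_interval)
}

#' Smooth and decimate a simulated series
#'
#' Emulates, in a deliberately simple way, the temporal blurring and coarse
#' sampling of an indirect measurement such as BOLD: each column is convolved
#' (causally) with a finite nonnegative kernel, then decimated to the
#' requested output interval, which must be an integer multiple of the input
#' sampling interval. The first `length(kernel) - 1` smoothed points, which
#' mix in unobserved pre-series values, are dropped before decimation.
#'
#' @param series a [roi_ts()].
#' @param kernel finite nonnegative numeric vector; default a short symmetric
#'   smoothing kernel. A unit impulse (`1`) leaves values unchanged.
#' @param out_interval output sampling interval in seconds; default keeps the
#'   input interval (decimation factor 1).
#'
#' @return A [roi_ts()] at the new sampling interval.
#' @export
apply_hrf_downsample <- function(series, kernel = c(0.25, 0.5, 0.25),
                                 out_interval = series$sampling_interval) {
  stopifnot(inherits(series, "roi_ts"))
  kernel <- as.numeric(kernel)
  if (!length(kernel) || any(!is.finite(kernel)) || any(kernel < 0)) {
    stop("kernel must be a finite nonnegative numeric vector")
  }
  fac <- out_interval / series$sampling_interval
  if (abs(fac - round(fac)) > 1e-8 || fac < 1) {
    stop(sprintf(paste0("out_interval (%g s) must be an integer multiple of ",
                        "the input sampling interval (%g s)"),
                 out_interval, series$sampling_interval))
  }
  fac <- as.integer(round(fac))
  X <- series$values
  m <- length(kernel)
  Y <- apply(X, 2, function(col) stats::filter(col, kernel, sides = 1))
  Y <- Y[m:nrow(X), , drop = FALSE]             # drop rows with partial support
  Y <- Y[seq(1, nrow(Y), by = fac), , drop = FALSE]
  roi_ts(Y, labels = series$labels, sampling_interval = out_interval)
}

#' The 14-region motor-task ROI table
#'
#' Labelled regions of interest for a motor-task effective-connectivity
#' model: bilateral anterior and posterior primary motor cortex (BA4),
#' premotor cortex (BA6), visual cortex V1 (BA17) and V2 (BA18), thalamus,
#' cerebellum and frontal lobe, with the atlas each mask derives from.
#'
#' @return data frame with columns `index`, `area`, `abbreviation`, `atlas`.
#' @export
motor_roi_table <- function() {
  data.frame(
    index = 1:14,
    area = c("Left thalamus", "Right thalamus",
             "Left premotor cortex Brodmann area 6",
             "Right premotor cortex Brodmann area 6",
             "Left anterior primary motor cortex Brodmann area 4",
             "Right anterior primary motor cortex Brodmann area 4",
             "Left posterior primary motor cortex Brodmann area 4",
             "Right posterior primary motor cortex Brodmann area 4",
             "Left visual cortex V1 Brodmann area 17",
             "Right visual cortex V1 Brodmann area 17",
             "Left visual cortex V2 Brodmann area 18",
             "Right visual cortex V2 Brodmann area 18",
             "Cerebellum", "Frontal lobe"),
    abbreviation = c("ThalamusL", "ThalamusR", "PcBA6L", "PcBA6R",
                     "PmcBA4aL", "PmcBA4aR", "PmcBA4pL", "PmcBA4pR",
                     "V1BA17L", "V1BA17R", "V1BA18L", "V1BA18R",
                     "Cereb", "FL"),
    atlas = c("MNI structural", "MNI structural",
              rep("Juelich histological", 10),
              "Harvard-Oxford cortical structural",
              "Harvard-Oxford cortical structural"),
    stringsAsFactors = FALSE
  )
}

#' A 14-region synthetic ground-truth model
#'
#' A stable lagged linear process over the [motor_roi_table()] regions whose
#' sparse cross-links sketch a visual-to-motor cascade: right V2 drives other
#' visual areas and, directly at a long lag and indirectly through premotor
#' and motor cortex, the left anterior motor cortex; premotor cortex feeds
#' the thalamus, which sends a weak negative link back to visual cortex.
#' Every component carries a lag-1 autolink. Used as the packaged desk-scale
#' fixture for end-to-end runs (T = 280 samples at 2.8 s is the intended
#' regime).
#'
#' @param autocoef lag-1 autolink coefficient shared by all components.
#' @return A `var_model` with `max_lag = 15`.
#' @export
example_motor_model <- function(autocoef = 0.35) {
  rois <- motor_roi_table()
  auto <- data.frame(source = 1:14, target = 1:14, lag = 1L,
                     coefficient = autocoef)
  cross <- data.frame(
    source      = c(12L, 12L, 12L, 6L, 12L, 5L, 4L, 1L, 13L, 14L, 8L),
    target      = c(11L,  9L,  6L, 5L,  5L, 4L, 1L, 11L, 5L,  4L,  4L),
    lag         = c( 1L,  2L,  3L, 2L, 15L, 2L, 2L, 1L,  4L,  3L,  1L),
    coefficient = c(0.30, 0.30, 0.30, 0.30, 0.25, 0.30, 0.30, -0.25,
                    0.25, 0.25, 0.25)
  )
  make_var_model(14, rbind(auto, cross), noise_sd = 1,
                 labels = rois$abbreviation, max_lag = 15L)
}

#' Write a simulated series and its ground truth as a plain-text fixture
#'
#' Lays out the directory the reading side expects: one single-column text
#' file per component (the format produced by ROI-mean extraction tools such
#' as fslmeants), a label table, the true link list, and the model
#' specification as a flat YAML file, so the fixture round-trips through
#' [read_roi_timeseries()] and carries its own ground truth.
#'
#' @param series a [roi_ts()] simulated from `model`.
#' @param model the generating `var_model`.
#' @param directory output directory (created if needed).
#' @param digits significant digits written (round-trip precision).
#' @return Invisibly, the character vector of files written.
#' @export
write_fixture <- function(series, model, directory, digits = 10) {
  stopifnot(inherits(series, "roi_ts"), inherits(model, "var_model"))
  if (!identical(series$labels, model$labels)) {
    stop("series and model labels disagree")
  }
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create directory ", directory)
  }
  fmt <- paste0("%.", digits, "g")
  files <- character(0)
  for (j in seq_along(series$labels)) {
    f <- file.path(directory, paste0(series$labels[j], ".txt"))
    writeLines(sprintf(fmt, series$values[, j]), f)
    files <- c(files, f)
  }
  lab <- file.path(directory, "labels.tsv")
  utils::write.table(
    data.frame(index = seq_along(model$labels), abbreviation = model$labels,
               atlas = "synthetic"),
    lab, sep = "\t", quote = FALSE, row.names = FALSE)
  tru <- file.path(directory, "truth_links.tsv")
  utils::write.table(model$links, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mod <- file.path(directory, "model.yml")
  yaml::write_yaml(list(n_vars = model$n_vars, max_lag = model$max_lag,
                        noise_sd = model$noise_sd, labels = model$labels,
                        sampling_interval = series$sampling_interval,
                        links = lapply(seq_len(nrow(model$links)), function(r)
                          as.list(model$links[r, ]))),
                   mod)
  invisible(c(files, lab, tru, mod))
}

#' Read back the model specification written by [write_fixture()]
#'
#' @param path path to a `model.yml` file.
#' @return A `var_model`.
#' @export
read_fixture_model <- function(path) {
  y <- yaml::read_yaml(path)
  links <- if (length(y$links)) {
    do.call(rbind, lapply(y$links, as.data.frame))
  } else NULL
  make_var_model(y$n_vars, links, noise_sd = unlist(y$noise_sd),
                 labels = unlist(y$labels), max_lag = y$max_lag)
}
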