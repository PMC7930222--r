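# Independent oracles and model fixtures shared across test files.

# Noiseless unit-impulse propagation, written as an explicit time-domain
# state update with scalar loops: deliberately independent of the matrix
# recursion it cross-checks. psi[j, i, tau + 1] = response of component j,
# tau steps after a unit impulse on component i.
impulse_response_oracle <- function(phi, tau_max) {
  n <- dim(phi)[1]
  p <- dim(phi)[3] - 1L
  psi <- array(0, dim = c(n, n, tau_max + 1L))
  for (i in seq_len(n)) {
    hist <- matrix(0, tau_max + 1L, n)
    hist[1, i] <- 1
    for (t in seq_len(tau_max)) {
      xt <- numeric(n)
      for (s in seq_len(min(p, t))) {
        for (jj in seq_len(n)) {
          for (m in seq_len(n)) {
            xt[jj] <- xt[jj] + phi[jj, m, s + 1L] * hist[t - s + 1L, m]
          }
        }
      }
      hist[t + 1L, ] <- xt
    }
    psi[, i, ] <- t(hist)
  }
  psi
}

# Random sparse link set kept stable by coefficient shrinkage.
random_stable_model <- function(n_vars, max_lag, n_cross = 4, seed = 1) {
  set.seed(seed)
  n_cross <- min(n_cross, n_vars * (n_vars - 1) * max_lag)
  links <- data.frame(source = seq_len(n_vars), target = seq_len(n_vars),
                      lag = 1L, coefficient = runif(n_vars, 0.2, 0.5))
  for (r in seq_len(n_cross)) {
    repeat {
      cand <- c(sample(n_vars, 2), sample(max_lag, 1))
      if (!any(links$source == cand[1] & links$target == cand[2] &
               links$lag == cand[3])) break
    }
    links <- rbind(links, data.frame(source = cand[1], target = cand[2],
                                     lag = cand[3],
                                     coefficient = runif(1, -0.7, 0.7)))
  }
  repeat {
    m <- tryCatch(make_var_model(n_vars, links, max_lag = max_lag),
                  error = function(e) NULL)
    if (!is.null(m) && m$spectral_radius < 0.95) return(m)
    links$coefficient <- links$coefficient * 0.8
  }
}

# chain 1 -> 2 -> 3 at lag 1 each (0.5, 0.4); total 1 -> 3 effect 0.2 at lag 2
chain_phi <- function() {
  phi <- array(0, dim = c(3, 3, 3))
  phi[2, 1, 2] <- 0.5
  phi[3, 2, 2] <- 0.4
  phi
}

# diamond 1 -> {2, 3} -> 4: branch products 0.20 (via 2) and 0.12 (via 3)
diamond_phi <- function() {
  phi <- array(0, dim = c(4, 4, 2))
  phi[2, 1, 2] <- 0.5
  phi[4, 2, 2] <- 0.4
  phi[3, 1, 2] <- 0.4
  phi[4, 3, 2] <- 0.3
  phi
}

ar1_model <- function(a, n_vars = 1) {
  make_var_model(n_vars, data.frame(source = seq_len(n_vars),
                                    target = seq_len(n_vars),
                                    lag = 1L, coefficient = a))
}

# correlated standard-normal pair with population correlation rho
gaussian_pair <- function(n, rho) {
  x <- rnorm(n)
  list(x = x, y = rho * x + sqrt(1 - rho^2) * rnorm(n))
}
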