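# Independent brute-force Cox partial likelihood (direct summation over
# risk sets), used as an oracle for the package's Newton-Raphson engine.
# Deliberately naive and independent of the compiled code path.
naive_cox_loglik <- function(beta, time, status, X, ties = "efron") {
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(status == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    s0 <- sum(r[R])
    s0d <- sum(r[D])
    ll <- ll + sum(eta[D])
    for (k in seq_len(d) - 1) {
      f <- if (ties == "efron") k / d else 0
      ll <- ll - log(s0 - f * s0d)
    }
  }
  ll
}

naive_cox_fit <- function(time, status, X, ties = "efron") {
  opt <- stats::optim(rep(0, ncol(X)),
                      function(b) -naive_cox_loglik(b, time, status, X, ties),
                      method = "BFGS", control = list(reltol = 1e-14))
  list(coef = opt$par, loglik = -opt$value)
}

# small worked survival dataset with tied event times
toy6 <- function() {
  data.frame(time = c(1, 1, 2, 2, 3, 4),
             event = c(1, 0, 1, 1, 0, 1),
             x = c(1, 0, 1, 0, 1, 0))
}

# planted-outlier variant of a simulated study: one line moved > 3 SD out
# on antagonism with uniformly early extinction of all its lineages
plant_outlier <- function(seed = 11, line = "L01") {
  d <- simulate_study(sim_config(seed = seed))
  ax <- d$axes
  i <- ax$line_id == line
  ax$antagonism[i] <- mean(ax$antagonism[!i]) + 3.5 * sd(ax$antagonism[!i])
  rc <- merge(d$records, ax, by = "line_id")
  set.seed(seed + 1)
  k <- rc$line_id == line
  rc$time[k] <- runif(sum(k), 0.05, 0.6)
  rc$event[k] <- TRUE
  rc
}
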