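#' Mixed-effects Cox proportional-hazards model with Gaussian frailty
#'
#' Fits a Cox proportional-hazards model in which, optionally, a shared
#' Gaussian random intercept (a log-normal frailty) acts on the log-hazard
#' of every observation belonging to the same group — here, every inbred
#' lineage derived from the same isofemale line. The hazard for
#' observation \eqn{i} in group \eqn{g} is
#' \deqn{h_i(t) = h_0(t)\,\exp(x_i'\beta + b_g), \qquad b_g \sim N(0, \sigma^2).}
#'
#' Estimation follows the penalized partial-likelihood approach: for a
#' given \eqn{\sigma^2} the fixed coefficients and group effects jointly
#' maximize the partial log-likelihood penalized by
#' \eqn{b'b/(2\sigma^2)} (inner Newton-Raphson); \eqn{\sigma^2} itself
#' maximizes the Laplace-approximate integrated partial likelihood
#' (outer Brent search on \code{interval}). Tied event times use the
#' Efron approximation by default; Breslow is available because discrete
#' generation-scale data produce heavy ties.
#'
#' With \code{random = NULL} the function fits a standard fixed-effects
#' Cox model with the same engine, and with \code{sigma2 = 0} the
#' frailty is switched off, so the fit reduces exactly to the standard
#' model.
#'
#' @param formula model formula with a [survival::Surv()] right-censored
#'   response, e.g. `Surv(time, event) ~ antagonism + concordance`.
#' @param data data frame containing the variables.
#' @param random random-intercept specification of the form
#'   `~ 1 | line_id`, or `NULL` for a fixed-effects fit.
#' @param ties approximation for tied event times.
#' @param sigma2 if `NULL` (default) the frailty variance is estimated;
#'   a non-negative number fixes it (0 gives the fixed-effects fit).
#' @param interval search interval for the frailty variance.
#' @param control list from [coxfr_control()].
#' @return An object of class `"coxfr"` with components
#'   `coefficients`, `se`, `var` (covariance of the fixed effects from
#'   the inverse penalized information), `loglik` (named vector: `null`,
#'   `partial`, `integrated`), `frailty` (list: `group`, `variance`,
#'   `ranef`, `estimated`, `boundary`), `linear.predictors`, `n`,
#'   `nevent`, `iter`. Methods: `print`, `summary`, `coef`, `vcov`,
#'   `logLik`, `ranef`, `fixef`, `anova`, `predict`, `residuals`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' dat <- simulate_study(cfg)
#' fit <- coxfr(Surv(time, event) ~ antagonism + concordance,
#'              data = dat$records_cov, random = ~ 1 | line_id)
#' summary(fit)
#' @export
coxfr <- function(formula, data, random = NULL,
                  ties = c("efron", "breslow"), sigma2 = NULL,
                  interval = c(1e-6, 10), control = coxfr_control()) {
  cl <- match.call()
  efron <- match.arg(ties) == "efron"

  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv") || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv object")
  time <- y[, "time"]
  status <- as.integer(y[, "status"])
  n <- length(time)
  if (sum(status) < 1L) stop("no events in the data; nothing to fit")

  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  int <- match("(Intercept)", colnames(X), nomatch = 0L)
  if (int > 0L) X <- X[, -int, drop = FALSE]
  p <- ncol(X)
  if (p > 0L) {
    if (!all(is.finite(X))) stop("covariates must be finite")
    qrX <- qr(X)
    if (qrX$rank < p) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
      stop("singular information: collinear covariate(s) ",
           paste(bad, collapse = ", "))
    }
  }

  g <- NULL
  if (!is.null(random)) {
    gexpr <- parse_random(random)[[3L]]
    g <- factor(eval(gexpr, data, environment(formula)))
    if (anyNA(g)) stop("missing values in the grouping variable")
    if (length(g) != n) stop("grouping variable length does not match the data")
  }

  ll_null <- cox_derivs(time, status, matrix(0, n, 0), numeric(n),
                        efron, FALSE)$loglik

  if (is.null(g) || (!is.null(sigma2) && sigma2 == 0)) {
    # fixed-effects fit (engine without penalty)
    fit <- cox_penalized_nr(time, status, X, pen = rep(0, p),
                            efron = efron, control = control)
    V <- if (p > 0L) solve(fit$hess) else matrix(0, 0, 0)
    frailty <- if (is.null(g)) NULL else {
      list(group = deparse(parse_random(random)[[3]]),
           variance = 0,
           ranef = stats::setNames(rep(0, nlevels(g)), levels(g)),
           estimated = FALSE, boundary = FALSE)
    }
    lp <- if (p > 0L) drop(X %*% fit$theta) else rep(0, n)
    out <- list(coefficients = stats::setNames(fit$theta, colnames(X)),
                se = stats::setNames(sqrt(diag(V)), colnames(X)),
                var = V,
                loglik = c(null = ll_null, partial = fit$loglik,
                           integrated = fit$loglik),
                df = p,
                frailty = frailty,
                linear.predictors = lp,
                n = n, nevent = sum(status), iter = fit$iter,
                ties = if (efron) "efron" else "breslow",
                time = time, status = status, X = X, group = g,
                terms = mt, call = cl, formula = formula)
    class(out) <- "coxfr"
    return(out)
  }

  q <- nlevels(g)
  Z <- stats::model.matrix(~ 0 + g)
  colnames(Z) <- levels(g)
  W <- cbind(X, Z)
  pidx <- p + seq_len(q)

  inner <- function(s2, theta0) {
    cox_penalized_nr(time, status, W,
                     pen = c(rep(0, p), rep(1 / s2, q)),
                     theta = theta0, efron = efron, control = control)
  }
  laplace <- function(fit, s2) {
    b <- fit$theta[pidx]
    Kbb <- fit$hess[pidx, pidx, drop = FALSE]
    ld <- determinant(diag(q) + s2 * Kbb, logarithm = TRUE)$modulus
    fit$loglik - sum(b^2) / (2 * s2) - 0.5 * as.numeric(ld)
  }

  boundary <- FALSE
  if (!is.null(sigma2)) {
    s2hat <- sigma2
    fit <- inner(s2hat, NULL)
    ill <- laplace(fit, s2hat)
    estimated <- FALSE
  } else {
    env <- new.env()
    env$theta <- numeric(ncol(W))
    obj <- function(s2) {
      f <- inner(s2, env$theta)
      env$theta <- f$theta
      -laplace(f, s2)
    }
    opt <- stats::optimize(obj, interval, tol = control$outer.tol)
    s2hat <- opt$minimum
    fit <- inner(s2hat, env$theta)
    ill <- laplace(fit, s2hat)
    estimated <- TRUE
    # fixed-effects limit: sigma^2 -> 0 gives the standard Cox log-likelihood
    fit0 <- cox_penalized_nr(time, status, X, pen = rep(0, p),
                             efron = efron, control = control)
    if (ill <= fit0$loglik + 1e-7 || s2hat <= 5 * interval[1]) {
      boundary <- TRUE
      warning("frailty variance estimate at the lower boundary; returning 0")
      s2hat <- 0
      ill <- fit0$loglik
      V0 <- if (p > 0L) solve(fit0$hess) else matrix(0, 0, 0)
      out <- list(coefficients = stats::setNames(fit0$theta, colnames(X)),
                  se = stats::setNames(sqrt(diag(V0)), colnames(X)),
                  var = V0,
                  loglik = c(null = ll_null, partial = fit0$loglik,
                             integrated = ill),
                  df = p + 1L,
                  frailty = list(group = deparse(parse_random(random)[[3]]),
                                 variance = 0,
                                 ranef = stats::setNames(rep(0, q), levels(g)),
                                 estimated = TRUE, boundary = TRUE),
                  linear.predictors = if (p > 0L) drop(X %*% fit0$theta) else rep(0, n),
                  n = n, nevent = sum(status), iter = fit0$iter,
                  ties = if (efron) "efron" else "breslow",
                  time = time, status = status, X = X, group = g,
                  terms = mt, call = cl, formula = formula)
      class(out) <- "coxfr"
      return(out)
    }
  }

  Hp <- fit$hess
  diag(Hp) <- diag(Hp) + c(rep(0, p), rep(1 / s2hat, q))
  Vfull <- solve(Hp)
  V <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
  beta <- fit$theta[seq_len(p)]
  b <- fit$theta[pidx]
  out <- list(coefficients = stats::setNames(beta, colnames(X)),
              se = stats::setNames(sqrt(diag(V)), colnames(X)),
              var = V,
              loglik = c(null = ll_null, partial = fit$loglik,
                         integrated = ill),
              df = p + as.integer(estimated),
              frailty = list(group = deparse(parse_random(random)[[3]]),
                             variance = s2hat,
                             ranef = stats::setNames(b, levels(g)),
                             estimated = estimated, boundary = boundary),
              linear.predictors = drop(W %*% fit$theta),
              n = n, nevent = sum(status), iter = fit$iter,
              ties = if (efron) "efron" else "breslow",
              time = time, status = status, X = X, group = g,
              terms = mt, call = cl, formula = formula)
  class(out) <- "coxfr"
  out
}

#' Control parameters for [coxfr()]
#'
#' @param inner.tol convergence tolerance on the change in penalized
#'   partial log-likelihood between Newton-Raphson iterations.
#' @param outer.tol tolerance of the Brent search over the frailty
#'   variance.
#' @param maxit maximum inner iterations.
#' @export
coxfr_control <- function(inner.tol = 1e-9, outer.tol = 5e-5, maxit = 50L) {
  list(inner.tol = inner.tol, outer.tol = outer.tol, maxit = maxit)
}

# parse ~ 1 | group, returning the call so callers can pull out the
# group expression (element 3)
parse_random <- function(random) {
  if (!inherits(random, "formula") || length(random) != 2L)
    stop("random must be a one-sided formula of the form ~ 1 | group")
  rhs <- random[[2L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop("random must have the form ~ 1 | group")
  if (!identical(rhs[[2L]], 1) && !identical(rhs[[2L]], 1L))
    stop("only a random intercept (~ 1 | group) is supported")
  rhs
}

# Penalized Newton-Raphson for the Cox partial likelihood.
# pen: vector of ridge precisions (0 for fixed effects, 1/sigma^2 for
# the group effects). Monotone step-halving; convergence on the change
# in penalized log-likelihood.
cox_penalized_nr <- function(time, status, W, pen, theta = NULL,
                             efron = TRUE, control = coxfr_control()) {
  p <- ncol(W)
  if (p == 0L) {
    ll <- cox_derivs(time, status, W, numeric(length(time)), efron, FALSE)$loglik
    return(list(theta = numeric(0), loglik = ll, pll = ll,
                grad = numeric(0), hess = matrix(0, 0, 0),
                iter = 0L, converged = TRUE))
  }
  if (is.null(theta)) theta <- numeric(p)
  theta <- drop(theta)
  derivs <- function(th) {
    d <- cox_derivs(time, status, W, drop(W %*% th), efron, TRUE)
    d$grad <- drop(d$grad)
    d
  }
  d <- derivs(theta)
  pll <- d$loglik - 0.5 * sum(pen * theta^2)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(control$maxit)) {
    iter <- it
    gr <- d$grad - pen * theta
    H <- d$hess
    diag(H) <- diag(H) + pen
    step <- tryCatch(drop(solve(H, gr)), error = function(e)
      stop("singular information matrix; check for collinear covariates"))
    new_theta <- theta + step
    halve <- 0L
    repeat {
      eta <- drop(W %*% new_theta)
      ll_new <- cox_derivs(time, status, W, eta, efron, FALSE)$loglik
      pll_new <- ll_new - 0.5 * sum(pen * new_theta^2)
      if (pll_new >= pll - 1e-12 || halve >= 25L) break
      halve <- halve + 1L
      new_theta <- theta + (new_theta - theta) / 2
    }
    done <- abs(pll_new - pll) < control$inner.tol
    theta <- new_theta
    pll <- pll_new
    d <- derivs(theta)
    if (done) { converged <- TRUE; break }
  }
  list(theta = theta, loglik = d$loglik, pll = pll,
       grad = d$grad, hess = d$hess, iter = iter, converged = converged)
}
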