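#' @importFrom lme4 ranef
#' @export
lme4::ranef

#' @importFrom lme4 fixef
#' @export
lme4::fixef

#' @export
print.coxfr <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Cox proportional-hazards fit",
      if (!is.null(x$frailty)) "with Gaussian frailty", "\n")
  cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  if (length(x$coefficients)) {
    print(signif(coef_table(x), digits))
  } else {
    cat("No fixed covariates (null model)\n")
  }
  if (!is.null(x$frailty)) {
    cat("\nRandom effect (", x$frailty$group, ") variance: ",
        format(x$frailty$variance, digits = digits),
        if (isTRUE(x$frailty$boundary)) " (boundary)", "\n", sep = "")
  }
  cat("\nn = ", x$n, ", events = ", x$nevent,
      ", integrated log-likelihood = ",
      format(x$loglik[["integrated"]], digits = digits + 2L), "\n", sep = "")
  invisible(x)
}

coef_table <- function(x) {
  z <- x$coefficients / x$se
  cbind(Coef = x$coefficients, `s.e.` = x$se, z = z,
        P = 2 * stats::pnorm(-abs(z)))
}

#' Summary of a mixed-effects Cox fit
#'
#' @param object a [coxfr()] fit.
#' @param ... unused.
#' @return a `summary.coxfr` object holding the coefficient table
#'   (Coef., s.e., z, two-sided normal P), the frailty variance and
#'   fit statistics.
#' @export
summary.coxfr <- function(object, ...) {
  out <- list(call = object$call,
              coefficients = coef_table(object),
              frailty = object$frailty,
              loglik = object$loglik,
              AIC = AIC(object),
              n = object$n, nevent = object$nevent,
              ties = object$ties)
  class(out) <- "summary.coxfr"
  out
}

#' @export
print.summary.coxfr <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Mixed-effects Cox regression (", x$ties, " ties)\n", sep = "")
  cat("Call: ", paste(deparse(x$call), collapse = "\n"), "\n\n", sep = "")
  cat("Fixed effects:\n")
  if (nrow(x$coefficients)) stats::printCoefmat(
    x$coefficients, digits = digits, P.values = TRUE, has.Pvalue = TRUE,
    cs.ind = 1:2, tst.ind = 3)
  else cat("  (none)\n")
  if (!is.null(x$frailty)) {
    cat("\nRandom effects:\n  ", x$frailty$group, " variance: ",
        format(x$frailty$variance, digits = digits),
        if (isTRUE(x$frailty$boundary)) "  (lower boundary)", "\n", sep = "")
  }
  cat("\nn = ", x$n, ", events = ", x$nevent, "\n", sep = "")
  cat("Integrated log-likelihood = ",
      format(x$loglik[["integrated"]], digits = digits + 2L),
      ", null = ", format(x$loglik[["null"]], digits = digits + 2L),
      ", AIC = ", format(x$AIC, digits = digits + 2L), "\n", sep = "")
  invisible(x)
}

#' @export
coef.coxfr <- function(object, ...) object$coefficients

#' @export
vcov.coxfr <- function(object, ...) object$var

#' @export
fixef.coxfr <- function(object, ...) object$coefficients

#' Per-group random intercepts of a frailty fit
#'
#' For a null model (no fixed covariates) these are the per-line
#' extinction-risk scores: each line's predicted deviation, on the
#' log-hazard scale, from the population baseline.
#'
#' @param object a [coxfr()] fit with a `random` term.
#' @param ... unused.
#' @return named numeric vector of predicted group effects (mean
#'   approximately zero).
#' @export
ranef.coxfr <- function(object, ...) {
  if (is.null(object$frailty)) stop("fit has no random effect")
  object$frailty$ranef
}

#' @export
logLik.coxfr <- function(object, ...) {
  structure(object$loglik[["integrated"]], df = object$df,
            nobs = object$n, class = "logLik")
}

#' @export
nobs.coxfr <- function(object, ...) object$n

#' @export
predict.coxfr <- function(object, newdata = NULL,
                          type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    lp <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
    X <- stats::model.matrix(tt, mf)
    int <- match("(Intercept)", colnames(X), nomatch = 0L)
    if (int > 0L) X <- X[, -int, drop = FALSE]
    lp <- drop(X %*% object$coefficients)
  }
  if (type == "risk") exp(lp) else lp
}

#' @export
residuals.coxfr <- function(object, type = c("martingale", "deviance"), ...) {
  type <- match.arg(type)
  m <- object$status - breslow_cumhaz(object) * exp(object$linear.predictors)
  if (type == "martingale") return(m)
  d <- object$status
  dev <- sign(m) * sqrt(pmax(0, -2 * (m + d * log(pmax(d - m, 1e-300)))))
  dev
}

# Breslow estimate of the baseline cumulative hazard, evaluated at each
# observation's own time.
breslow_cumhaz <- function(object) {
  time <- object$time; status <- object$status
  r <- exp(object$linear.predictors)
  et <- sort(unique(time[status == 1]))
  d <- vapply(et, function(t) sum(status == 1 & time == t), numeric(1))
  s0 <- vapply(et, function(t) sum(r[time >= t]), numeric(1))
  h <- cumsum(d / s0)
  idx <- findInterval(time, et)
  ifelse(idx == 0, 0, h[pmax(idx, 1L)])
}

#' Likelihood-ratio test between nested Cox fits
#'
#' Compares two [coxfr()] fits on the same records by
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{nested})} with degrees of
#' freedom equal to the parameter-count difference, using the
#' integrated log-likelihood for frailty fits. Used here to decide
#' whether an antagonism-by-concordance (or male-by-female) interaction
#' term earns its place.
#'
#' @param nested,full [coxfr()] fits; the fixed covariates of `nested`
#'   must be a subset of those of `full`.
#' @return list with `statistic`, `df`, `p.value`, class `"coxfr_lrt"`.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "coxfr"), inherits(full, "coxfr"))
  if (nested$n != full$n || nested$nevent != full$nevent)
    stop("models were fitted to different record sets")
  if (!all(names(nested$coefficients) %in% names(full$coefficients)))
    stop("models are not nested: ",
         paste(setdiff(names(nested$coefficients), names(full$coefficients)),
               collapse = ", "), " not in the full model")
  if (full$df < nested$df)
    stop("models are not nested: full model has fewer parameters")
  chi <- max(0, 2 * (full$loglik[["integrated"]] - nested$loglik[["integrated"]]))
  df <- full$df - nested$df
  p <- if (df == 0L) {
    if (chi <= 1e-8) 1 else 0
  } else stats::pchisq(chi, df, lower.tail = FALSE)
  structure(list(statistic = chi, df = df, p.value = p),
            class = "coxfr_lrt")
}

#' @export
print.coxfr_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi-square = %.4g, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
anova.coxfr <- function(object, ..., test = "LRT") {
  fits <- c(list(object), list(...))
  fits <- Filter(function(f) inherits(f, "coxfr"), fits)
  if (length(fits) < 2L) stop("supply at least two coxfr fits to compare")
  res <- data.frame(df = vapply(fits, function(f) f$df, numeric(1)),
                    logLik = vapply(fits, function(f) f$loglik[["integrated"]],
                                    numeric(1)),
                    Chisq = NA_real_, `Pr(>Chisq)` = NA_real_,
                    check.names = FALSE)
  for (i in 2:length(fits)) {
    lt <- lrt(fits[[i - 1L]], fits[[i]])
    res$Chisq[i] <- lt$statistic
    res$`Pr(>Chisq)`[i] <- lt$p.value
  }
  structure(res, heading = "Analysis of deviance (likelihood-ratio tests)",
            class = c("anova", "data.frame"))
}

#' AIC difference between a fitted and a null model
#'
#' `AIC = -2 * integrated log-likelihood + 2 * k`, where `k` counts the
#' fixed coefficients plus one for an estimated frailty variance. The
#' returned difference `AIC(null) - AIC(fit)` is positive when the
#' fitted model is the better one.
#'
#' @param fit,null [coxfr()] fits on the same records.
#' @return the AIC difference (numeric scalar).
#' @export
delta_aic <- function(fit, null) {
  stopifnot(inherits(fit, "coxfr"), inherits(null, "coxfr"))
  if (fit$n != null$n || fit$nevent != null$nevent)
    stop("models were fitted to different record sets")
  AIC(null) - AIC(fit)
}

#' Per-line extinction-risk scores from a null frailty model
#'
#' Fits an intercept-only Cox model with a Gaussian per-line random
#' effect and returns each line's predicted random intercept on the
#' log-hazard scale: positive values mark lines whose lineages went
#' extinct faster than average.
#'
#' @param records data frame of lineage records with columns `time` and
#'   `event` and the grouping column named by `group`.
#' @param group name of the line-identifier column.
#' @param ... passed to [coxfr()].
#' @return named numeric vector of per-line scores (mean ~ 0).
#' @export
line_extinction_risk <- function(records, group = "line_id", ...) {
  f <- stats::as.formula("Surv(time, event) ~ 1")
  r <- stats::as.formula(paste("~ 1 |", group))
  fit <- coxfr(f, records, random = r, ...)
  ranef(fit)
}
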