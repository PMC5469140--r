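#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates every stage end-to-end on data from
#' [simulate_study()]: derived fitness axes; mixed-effects Cox fits of
#' extinction risk in both parameterizations (antagonism/concordance
#' and female/male standardized fitness), each with an
#' interaction-term likelihood-ratio test; the AIC difference against
#' the null (frailty-only) model; the leave-one-out influence screen
#' with a refit excluding the most influential line (derived variables
#' recalculated in its absence); per-line extinction-risk scores and
#' the extreme-line selection; the fecundity-only extinction forecast
#' and the first-generation projection against the observed extinction
#' proportion; and follow-up zero-rate tests and linear mixed models
#' for female fecundity and male fertility assays. Stages are logged
#' to `stderr`; any stage failure aborts with the stage name.
#'
#' @param config a [sim_config()].
#' @param out_dir if non-`NULL`, write `report.json` and the CSV
#'   tables there.
#' @param forecast_replicates Monte-Carlo replicates for the fecundity
#'   forecast.
#' @return object of class `"inbrex_report"`; all elements except
#'   `fits` are plain data and regenerate bit-identically from the same
#'   configuration.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         forecast_replicates = 200L) {
  stage <- function(name, expr) {
    message("[pipeline] ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- stage("simulate", simulate_study(config))
  rc <- sim$records_cov

  f_ac <- Surv(time, event) ~ antagonism + concordance
  f_mf <- Surv(time, event) ~ female_std + male_std
  fits <- stage("survival-fits", {
    m_ac <- coxfr(f_ac, rc, random = ~ 1 | line_id)
    m_mf <- coxfr(f_mf, rc, random = ~ 1 | line_id)
    m_ac_int <- coxfr(Surv(time, event) ~ antagonism * concordance, rc,
                      random = ~ 1 | line_id)
    m_mf_int <- coxfr(Surv(time, event) ~ female_std * male_std, rc,
                      random = ~ 1 | line_id)
    m_null <- coxfr(Surv(time, event) ~ 1, rc, random = ~ 1 | line_id)
    list(ac = m_ac, mf = m_mf, ac_int = m_ac_int, mf_int = m_mf_int,
         null = m_null)
  })

  lrt_ac <- lrt(fits$ac, fits$ac_int)
  lrt_mf <- lrt(fits$mf, fits$mf_int)
  daic <- delta_aic(fits$ac, fits$null)

  screen <- stage("influence-screen",
                  dfbeta_screen(f_ac, rc, group = "line_id"))
  excl <- flagged_lines(screen)
  refit <- NULL
  if (length(excl)) {
    refit <- stage("outlier-exclusion-refit", {
      keep_lf <- sim$line_fitness[!sim$line_fitness$line_id %in% excl[1L], ]
      axes2 <- fitness_axes(keep_lf)  # derived variables recalculated
      rc2 <- merge(sim$records[!sim$records$line_id %in% excl[1L], ],
                   axes2, by = "line_id", sort = FALSE)
      coxfr(f_ac, rc2, random = ~ 1 | line_id)
    })
  }

  risk <- stage("extinction-risk", ranef(fits$null))
  sel <- stage("extreme-lines", {
    a <- stats::setNames(sim$axes$antagonism, sim$axes$line_id)
    select_extreme_lines(a, risk)
  })

  fc <- stage("forecasts", {
    sim_fc <- forecast_fecundity_extinction(
      sim$fecundity, generations = config$max_generations,
      lineages_per_line = config$lineages_per_line,
      replicates = forecast_replicates, seed = config$seed + 17L)
    proj <- project_first_generation(sim$first_gen,
                                     generations = config$max_generations)
    list(fecundity = sim_fc, projection = proj,
         observed = mean(sim$records$event))
  })

  followup <- stage("follow-up", {
    selected <- data.frame(
      line_id = c(sel$top, sel$bottom),
      category = rep(c("male_benefit", "female_benefit"),
                     c(length(sel$top), length(sel$bottom))))
    fem <- simulate_followup_assays(selected, config, "female")
    mal <- simulate_followup_assays(selected, config, "male")
    list(
      fecundity_zeros = test_zero_rates(fem),
      fertility_zeros = test_zero_rates(mal),
      fecundity_lmm = fit_offspring_lmm(fem),
      fertility_lmm = fit_offspring_lmm(mal))
  })

  coef_block <- function(fit) {
    tb <- as.data.frame(coef_table(fit))
    tb <- cbind(term = rownames(tb), tb)
    rownames(tb) <- NULL
    tb
  }
  lmm_block <- function(l)
    list(statistic = l$statistic, df = l$df, p.value = l$p.value,
         effect = unname(l$effect), n_used = l$n_used, n_zero = l$n_zero)

  report <- list(
    version = as.character(utils::packageVersion("inbrex")),
    seed = config$seed,
    config = unclass(config),
    axes = sim$axes,
    antagonism_concordance = list(
      coefficients = coef_block(fits$ac),
      frailty_variance = fits$ac$frailty$variance,
      interaction_lrt = unclass(lrt_ac)),
    female_male = list(
      coefficients = coef_block(fits$mf),
      frailty_variance = fits$mf$frailty$variance,
      interaction_lrt = unclass(lrt_mf)),
    delta_aic_vs_null = daic,
    influence = list(
      flagged_records = sum(screen$flagged),
      flagged_lines = as.character(excl),
      excluded_refit = if (!is.null(refit)) coef_block(refit)),
    extinction_risk = risk,
    extreme_lines = sel[c("top", "bottom")],
    forecasts = list(
      observed_extinction = fc$observed,
      fecundity_forecast = fc$fecundity$proportion,
      first_generation_projection = fc$projection$proportion,
      projection_mode = fc$projection$method),
    followup = list(
      fecundity_zeros = followup$fecundity_zeros[
        c("statistic", "df", "p.value")],
      fertility_zeros = followup$fertility_zeros[
        c("statistic", "df", "p.value")],
      fecundity_lmm = lmm_block(followup$fecundity_lmm),
      fertility_lmm = lmm_block(followup$fertility_lmm)),
    fits = fits)
  class(report) <- "inbrex_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_payload(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(sim$axes, file.path(out_dir, "axes.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(report$antagonism_concordance$coefficients,
                     file.path(out_dir, "coefficients_antagonism.csv"),
                     row.names = FALSE)
    utils::write.csv(report$female_male$coefficients,
                     file.path(out_dir, "coefficients_sex_fitness.csv"),
                     row.names = FALSE)
  }
  report
}

# serializable part of the report (model objects removed)
report_payload <- function(report) {
  p <- unclass(report)
  p$fits <- NULL
  p
}

#' @export
print.inbrex_report <- function(x, digits = 3, ...) {
  cat("Lineage-extinction pipeline report (package version ",
      x$version, ", seed ", x$seed, ")\n\n", sep = "")
  cat("Antagonism/concordance model:\n")
  print(x$antagonism_concordance$coefficients, digits = digits)
  cat("  frailty variance: ",
      format(x$antagonism_concordance$frailty_variance, digits = digits),
      "\n  interaction LRT: chi-square = ",
      format(x$antagonism_concordance$interaction_lrt$statistic,
             digits = digits),
      ", P = ",
      format(x$antagonism_concordance$interaction_lrt$p.value,
             digits = digits), "\n\n", sep = "")
  cat("Female/male fitness model:\n")
  print(x$female_male$coefficients, digits = digits)
  cat("  frailty variance: ",
      format(x$female_male$frailty_variance, digits = digits),
      "\n\n", sep = "")
  cat("Delta AIC (null - fitted): ",
      format(x$delta_aic_vs_null, digits = digits), "\n", sep = "")
  cat("Influence screen: ", x$influence$flagged_records,
      " flagged records; flagged line(s): ",
      if (length(x$influence$flagged_lines))
        paste(x$influence$flagged_lines, collapse = ", ") else "none",
      "\n\n", sep = "")
  cat("Extinction: observed ",
      format(100 * x$forecasts$observed_extinction, digits = digits),
      "% | fecundity-only forecast ",
      format(100 * x$forecasts$fecundity_forecast, digits = digits),
      "% | first-generation projection ",
      format(100 * x$forecasts$first_generation_projection,
             digits = digits), "%\n", sep = "")
  cat("Follow-up category tests (chi-square, P): fecundity ",
      format(x$followup$fecundity_lmm$statistic, digits = digits), ", ",
      format(x$followup$fecundity_lmm$p.value, digits = digits),
      "; fertility ",
      format(x$followup$fertility_lmm$statistic, digits = digits), ", ",
      format(x$followup$fertility_lmm$p.value, digits = digits),
      "\n", sep = "")
  invisible(x)
}
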