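#' Compare the rate of zero-offspring assays between categories
#'
#' Pearson chi-square test (1 df, no continuity correction) of the
#' 2 x 2 table of zero versus non-zero offspring counts against assay
#' category (male-benefit vs female-benefit). A non-significant result
#' licenses dropping the zeros before the linear mixed model of the
#' non-zero counts.
#'
#' @param records data frame with columns `category` (two levels) and
#'   `offspring` (non-negative counts).
#' @return list with `statistic`, `df`, `p.value`, `table`.
#' @examples
#' r <- data.frame(category = rep(c("mb", "fb"), each = 100),
#'                 offspring = c(rep(0, 10), rep(5, 90),
#'                               rep(0, 20), rep(6, 80)))
#' test_zero_rates(r)$statistic  # 3.9216
#' @export
test_zero_rates <- function(records) {
  stopifnot(all(c("category", "offspring") %in% names(records)))
  cat_f <- factor(records$category)
  if (nlevels(cat_f) != 2L)
    stop("exactly two categories are required")
  tab <- table(zero = factor(records$offspring == 0,
                             levels = c(FALSE, TRUE)),
               category = cat_f)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("untestable table: a zero margin (a category has no records, ",
         "or no variation in zero/non-zero)")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, table = tab)
}

#' Linear mixed model for non-zero offspring counts
#'
#' After excluding zero counts (tested separately with
#' [test_zero_rates()]), fits a Gaussian linear mixed model of
#' lifetime offspring production with fixed effects for category
#' (male-benefit vs female-benefit) and base-population cohort, and
#' random intercepts for isofemale line, lineage nested within line,
#' and assay date. The category effect is tested by a likelihood-ratio
#' test between maximum-likelihood fits with and without the category
#' term (1 df chi-square). Singular random-effect components (variance
#' estimated at zero) are dropped with a warning and the model refitted.
#'
#' @param records data frame with columns `offspring`, `category`,
#'   `base_cohort`, `line_id`, `lineage_id`, `assay_date`.
#' @param drop_zeros exclude zero counts first (the default pipeline
#'   rule).
#' @return list with `statistic`, `df`, `p.value` for the category
#'   term, `varcomp` (random-effect variances of the full model),
#'   `effect` (estimated category contrast), `n_used`, `n_zero`,
#'   `dropped` (names of any dropped random terms), `model` (the full
#'   `lmerMod` fit).
#' @export
fit_offspring_lmm <- function(records, drop_zeros = TRUE) {
  need <- c("offspring", "category", "base_cohort", "line_id",
            "lineage_id", "assay_date")
  stopifnot(all(need %in% names(records)))
  if (length(unique(records$category)) < 2L)
    stop("need at least two category levels")
  n_zero <- sum(records$offspring == 0)
  if (drop_zeros) records <- records[records$offspring > 0, , drop = FALSE]
  records$category <- factor(records$category)
  records$base_cohort <- factor(records$base_cohort)
  records$line_id <- factor(records$line_id)
  records$lineage_id <- factor(paste(records$line_id, records$lineage_id,
                                     sep = ":"))
  records$assay_date <- factor(records$assay_date)

  re_terms <- c("(1 | line_id)", "(1 | lineage_id)", "(1 | assay_date)")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_pair <- function(re) {
    fml_full <- stats::as.formula(paste(
      "offspring ~ category + base_cohort +", paste(re, collapse = " + ")))
    fml_null <- stats::as.formula(paste(
      "offspring ~ base_cohort +", paste(re, collapse = " + ")))
    full <- suppressMessages(lme4::lmer(fml_full, records, REML = FALSE,
                                        control = ctrl))
    null <- suppressMessages(lme4::lmer(fml_null, records, REML = FALSE,
                                        control = ctrl))
    list(full = full, null = null)
  }
  dropped <- character(0)
  re <- re_terms
  fits <- fit_pair(re)
  while (lme4::isSingular(fits$full, tol = 1e-5) && length(re) > 1L) {
    vc <- as.data.frame(lme4::VarCorr(fits$full))
    vc <- vc[vc$grp != "Residual", ]
    worst <- vc$grp[which.min(vc$vcov)]
    idx <- grep(worst, re, fixed = TRUE)
    if (!length(idx)) break
    dropped <- c(dropped, worst)
    re <- re[-idx[1L]]
    fits <- fit_pair(re)
  }
  if (length(dropped))
    warning("singular random-effect structure; dropped: ",
            paste(dropped, collapse = ", "))
  lr <- stats::anova(fits$null, fits$full)
  chi <- lr$Chisq[2L]
  df <- lr$Df[2L]
  vc <- as.data.frame(lme4::VarCorr(fits$full))[, c("grp", "vcov")]
  eff <- lme4::fixef(fits$full)
  eff <- eff[grep("^category", names(eff))]
  list(statistic = chi, df = df,
       p.value = stats::pchisq(chi, df, lower.tail = FALSE),
       varcomp = vc, effect = eff,
       n_used = nrow(records), n_zero = n_zero,
       dropped = dropped, model = fits$full)
}

#' Select extreme lines along the antagonism-by-extinction-risk axis
#'
#' Standardizes the per-line antagonism score and extinction-risk score
#' (the random intercepts of a null frailty model), extracts the first
#' principal component of the two (eigenvector of their 2 x 2
#' correlation matrix), orients it so that positive scores align with
#' antagonism, and returns the `n_extreme` most positive
#' (male-benefit/high-extinction) and most negative
#' (female-benefit/low-extinction) lines.
#'
#' @param antagonism named numeric vector of per-line antagonism
#'   scores (names are line ids).
#' @param extinction_risk named numeric vector of per-line
#'   extinction-risk scores, same lines.
#' @param n_extreme number of lines to take from each end.
#' @return list with `scores` (named PC1 score per line, sorted
#'   decreasing), `top` (male-benefit/high-extinction line ids),
#'   `bottom` (female-benefit/low-extinction line ids), `loadings`.
#' @export
select_extreme_lines <- function(antagonism, extinction_risk,
                                 n_extreme = 3L) {
  ids <- names(antagonism)
  if (is.null(ids) || is.null(names(extinction_risk)))
    stop("both score vectors must be named by line id")
  extinction_risk <- extinction_risk[ids]
  if (anyNA(extinction_risk))
    stop("extinction_risk is missing for some lines")
  n <- length(ids)
  if (n < 2L * n_extreme)
    stop("need at least ", 2L * n_extreme, " lines")
  std <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  a <- std(antagonism); r <- std(extinction_risk)
  if (all(r == 0) || all(a == 0)) {
    # degenerate axis: ranking reduces to the non-degenerate score
    scores <- if (all(r == 0)) a else r
    load <- c(antagonism = as.numeric(all(r == 0)),
              extinction_risk = as.numeric(all(a == 0)))
  } else {
    C <- stats::cor(cbind(a, r))
    ev <- eigen(C, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    if (v[1L] < 0) v <- -v  # positive PC1 = more antagonistic
    scores <- drop(cbind(a, r) %*% v)
    load <- stats::setNames(v, c("antagonism", "extinction_risk"))
  }
  names(scores) <- ids
  ord <- order(scores, decreasing = TRUE)
  list(scores = scores[ord],
       top = ids[ord[seq_len(n_extreme)]],
       bottom = rev(ids[ord[(n - n_extreme + 1L):n]]),
       loadings = load)
}
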