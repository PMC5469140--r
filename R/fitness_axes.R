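#' Standardize log-transformed fitness means
#'
#' Natural-log-transforms per-line mean fitness and standardizes to
#' sample mean 0 and sample variance 1 (n - 1 denominator). Applied
#' within each sex separately, this puts male and female line-mean
#' fitness on a common unitless scale before the axis rotation.
#'
#' @param x strictly positive numeric vector of per-line mean lifetime
#'   offspring counts (one sex).
#' @return numeric vector of standardized log fitness.
#' @examples
#' standardize_log_fitness(c(exp(1), exp(2)))  # -0.7071, 0.7071
#' @export
standardize_log_fitness <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("need a numeric vector of at least 2 lines")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("fitness means must be strictly positive (log transform)")
  lx <- log(x)
  s <- stats::sd(lx)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: zero variance in fitness means")
  (lx - mean(lx)) / s
}

#' Rotate standardized fitness onto antagonism/concordance axes
#'
#' A 45-degree clockwise rotation of the (male, female) standardized
#' fitness plane:
#' \deqn{antagonism = (m - f)/\sqrt{2}, \qquad concordance = (m + f)/\sqrt{2}.}
#' The antagonism axis runs from female-benefit/male-detriment lines
#' (negative) to male-benefit/female-detriment lines (positive); the
#' concordance axis runs from generally low-fitness to generally
#' high-fitness lines. The orthonormal scaling makes the map an
#' isometry, so `antagonism^2 + concordance^2 = m^2 + f^2` per line and
#' `inverse = TRUE` recovers the inputs exactly.
#'
#' @param male_std,female_std standardized log fitness per line (or,
#'   with `inverse = TRUE`, antagonism and concordance scores).
#' @param inverse apply the inverse rotation.
#' @return data frame with columns `antagonism` and `concordance` (or
#'   `male_std`, `female_std` for the inverse).
#' @examples
#' rotate_axes(1, -1)  # antagonism sqrt(2), concordance 0
#' @export
rotate_axes <- function(male_std, female_std, inverse = FALSE) {
  if (inverse) {
    a <- male_std; co <- female_std
    return(data.frame(male_std = (co + a) / sqrt(2),
                      female_std = (co - a) / sqrt(2)))
  }
  data.frame(antagonism = (male_std - female_std) / sqrt(2),
             concordance = (male_std + female_std) / sqrt(2))
}

#' Derive antagonism/concordance axes from raw line fitness
#'
#' Takes per-line raw mean fitness for each sex, log-transforms and
#' variance-standardizes within sex, and rotates onto the antagonism
#' and concordance axes. By default the derived axes are *not*
#' re-standardized after rotation (their variances are `1 - r` and
#' `1 + r` for intersexual correlation `r`), which keeps coefficients
#' in the two model parameterizations related by the exact inverse
#' rotation; set `restandardize = TRUE` to force unit variance on the
#' derived axes as well.
#'
#' @param data data frame with one row per line.
#' @param male,female names of the raw fitness columns.
#' @param restandardize re-standardize the derived axes to variance 1.
#' @return `data` with columns `male_std`, `female_std`, `antagonism`,
#'   `concordance` appended.
#' @examples
#' d <- data.frame(line_id = 1:5,
#'                 male_fitness = c(30, 42, 55, 38, 61),
#'                 female_fitness = c(70, 52, 45, 66, 48))
#' fitness_axes(d)
#' @export
fitness_axes <- function(data, male = "male_fitness",
                         female = "female_fitness",
                         restandardize = FALSE) {
  for (cn in c(male, female))
    if (!cn %in% names(data)) stop("column '", cn, "' not found")
  if (nrow(data) < 3L) stop("need at least 3 lines")
  data$male_std <- standardize_log_fitness(data[[male]])
  data$female_std <- standardize_log_fitness(data[[female]])
  rot <- rotate_axes(data$male_std, data$female_std)
  if (restandardize) {
    rot$antagonism <- rot$antagonism / stats::sd(rot$antagonism)
    rot$concordance <- rot$concordance / stats::sd(rot$concordance)
  }
  data$antagonism <- rot$antagonism
  data$concordance <- rot$concordance
  data
}
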