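#' Demographic extinction forecast from female fecundity alone
#'
#' Monte-Carlo forecast of the lineage extinction expected from
#' demographic stochasticity in female fecundity and offspring sex,
#' *without* any effect of inbreeding. Each simulated lineage is
#' propagated by a single mating pair: each generation one female's
#' lifetime offspring count is drawn (resampled with replacement from
#' the line's fecundity samples, or from a negative-binomial when a
#' parametric summary is supplied), each offspring is assigned a sex
#' independently with probability `sex_ratio`, and the lineage survives
#' the generation only if at least one offspring of each sex emerged
#' (which requires at least two offspring). For a degenerate count `n`
#' every generation, the closed-form extinction probability is
#' `1 - (1 - 2^(1-n))^G`.
#'
#' @param fecundity data frame of per-line samples with columns
#'   `line_id` and `offspring`, or a parametric table with columns
#'   `line_id`, `mean`, `dispersion` (negative-binomial size).
#' @param generations number of generations of single-pair matings.
#' @param lineages_per_line lineages founded per line.
#' @param replicates Monte-Carlo replicates of the whole experiment.
#' @param sex_ratio probability an offspring is female.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return object of class `"extinction_forecast"`: `per_line` (matrix
#'   of cumulative extinction proportions, lines x generations),
#'   `overall` (lineage-weighted cumulative proportion by generation),
#'   `proportion` (overall proportion at the final generation),
#'   `n_replicates`, `seed`, `method`.
#' @examples
#' fec <- data.frame(line_id = "A", offspring = 2)  # always exactly 2
#' f <- forecast_fecundity_extinction(fec, replicates = 2000, seed = 1)
#' f$proportion   # close to 1 - 0.5^10
#' @export
forecast_fecundity_extinction <- function(fecundity, generations = 10,
                                          lineages_per_line = 20,
                                          replicates = 500,
                                          sex_ratio = 0.5, seed = NULL) {
  stopifnot(generations >= 1, replicates >= 1, lineages_per_line >= 1)
  if (!is.null(seed)) set.seed(seed)
  parametric <- all(c("mean", "dispersion") %in% names(fecundity))
  if (!parametric && !all(c("line_id", "offspring") %in% names(fecundity)))
    stop("fecundity needs columns line_id+offspring or line_id+mean+dispersion")
  if (!parametric && any(fecundity$offspring < 0))
    stop("offspring counts must be non-negative")
  lines <- unique(as.character(fecundity$line_id))
  if (length(lines) == 0L) stop("no fecundity data: line_id is empty")
  N <- lineages_per_line * replicates
  per_line <- matrix(0, length(lines), generations,
                     dimnames = list(lines, paste0("G", seq_len(generations))))
  for (li in seq_along(lines)) {
    if (parametric) {
      row <- fecundity[fecundity$line_id == lines[li], , drop = FALSE][1L, ]
      draw <- function(m) stats::rnbinom(m, mu = row$mean, size = row$dispersion)
    } else {
      samp <- fecundity$offspring[fecundity$line_id == lines[li]]
      if (length(samp) == 0L)
        stop("no fecundity samples for line ", lines[li])
      draw <- function(m) samp[sample.int(length(samp), m, replace = TRUE)]
    }
    alive <- rep(TRUE, N)
    ext_gen <- rep(NA_integer_, N)
    for (gen in seq_len(generations)) {
      m <- sum(alive)
      if (m == 0L) break
      n_off <- draw(m)
      females <- stats::rbinom(m, n_off, sex_ratio)
      survive <- n_off >= 2 & females >= 1 & females <= n_off - 1
      died <- which(alive)[!survive]
      ext_gen[died] <- gen
      alive[died] <- FALSE
    }
    for (gen in seq_len(generations))
      per_line[li, gen] <- mean(!is.na(ext_gen) & ext_gen <= gen)
  }
  overall <- colMeans(per_line)
  structure(list(per_line = per_line, overall = overall,
                 proportion = overall[[generations]],
                 generations = generations,
                 n_replicates = replicates, seed = seed,
                 method = "fecundity-simulation"),
            class = "extinction_forecast")
}

#' Project extinction forward from first-generation rates
#'
#' Uses each line's observed first-generation extinction rate
#' \eqn{\hat p_1} — before inbreeding has had any appreciable effect —
#' to project the proportion of lineages expected to be extinct after
#' `G` generations of single-pair (but not full-sib) matings.
#' `mode = "geometric"` compounds the per-generation rate,
#' \eqn{1 - (1 - \hat p_1)^G}; `mode = "linear"` accumulates it
#' additively, \eqn{\min(1, G\,\hat p_1)}. The geometric projection is
#' never larger than the linear one.
#'
#' @param first_gen data frame with columns `line_id`, `extinct`,
#'   `total`: lineages extinct in generation 1 and lineages started.
#' @param generations projection horizon `G`.
#' @param mode compounding convention.
#' @return object of class `"extinction_forecast"` with `per_line`
#'   (matrix lines x generations), `overall` (total-lineage-weighted),
#'   and `proportion` at generation `G`.
#' @examples
#' pg <- project_first_generation(
#'   data.frame(line_id = "A", extinct = 2, total = 20))
#' pg$proportion  # 1 - 0.9^10 = 0.6513
#' @export
project_first_generation <- function(first_gen, generations = 10,
                                     mode = c("geometric", "linear")) {
  mode <- match.arg(mode)
  stopifnot(all(c("line_id", "extinct", "total") %in% names(first_gen)),
            generations >= 1)
  if (any(first_gen$total <= 0)) stop("total lineages must be positive")
  if (any(first_gen$extinct > first_gen$total) || any(first_gen$extinct < 0))
    stop("extinct count must lie in [0, total]")
  p1 <- first_gen$extinct / first_gen$total
  gens <- seq_len(generations)
  per_line <- if (mode == "geometric")
    outer(p1, gens, function(p, g) 1 - (1 - p)^g)
  else
    outer(p1, gens, function(p, g) pmin(1, g * p))
  dimnames(per_line) <- list(as.character(first_gen$line_id),
                             paste0("G", gens))
  w <- first_gen$total / sum(first_gen$total)
  overall <- colSums(per_line * w)
  structure(list(per_line = per_line, overall = overall,
                 proportion = overall[[generations]],
                 generations = generations,
                 n_replicates = NA_integer_, seed = NULL,
                 method = paste0("first-generation-", mode)),
            class = "extinction_forecast")
}

#' @export
print.extinction_forecast <- function(x, digits = 4, ...) {
  cat("Extinction forecast (", x$method, ")\n", sep = "")
  cat("Lines: ", nrow(x$per_line), ", horizon: ", x$generations,
      " generations\n", sep = "")
  cat("Expected overall extinction at G = ", x$generations, ": ",
      format(100 * x$proportion, digits = digits), "%\n", sep = "")
  invisible(x)
}
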