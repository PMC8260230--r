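#' Geometric-series model of progenitor growth under partial ingression
#'
#' Constructs a population model for a self-renewing progenitor pool in which,
#' at every division, a fraction `f_ingress` of daughter cells leaves the
#' population (ingresses into the mesodermal layer). The resident population
#' then follows the geometric series \eqn{U_n = q^n U_0} with doubling
#' parameter \eqn{q = 2 (1 - f_{ingress})}.
#'
#' @param U0 initial population size (cells), at least 1.
#' @param f_ingress fraction of daughter cells ingressing per division,
#'   in \[0, 1\].
#' @return An object of class `"population_model"`: a list with components
#'   `U0`, `f_ingress` and `q`.
#' @examples
#' m <- population_model(U0 = 50, f_ingress = 0.35)
#' m$q  # 1.3
#' @export
population_model <- function(U0, f_ingress) {
  if (!is.numeric(U0) || length(U0) != 1L || U0 < 1)
    stop("'U0' must be a single number >= 1")
  q <- doubling_parameter(f_ingress)
  structure(list(U0 = as.numeric(U0), f_ingress = as.numeric(f_ingress), q = q),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Geometric-series population model\n")
  cat(sprintf("  U0 = %g cells, f_ingress = %g, q = 2(1 - f) = %g\n",
              x$U0, x$f_ingress, x$q))
  invisible(x)
}

#' Doubling parameter of the non-ingressed population
#'
#' Each division turns one mother into two daughters, of which a fraction
#' `f_ingress` leaves the pool, so the per-division multiplier of the resident
#' population is \eqn{q = 2 (1 - f_{ingress})}.
#'
#' @param f_ingress ingression fraction per division, in \[0, 1\].
#' @return The doubling parameter q, in \[0, 2\].
#' @examples
#' doubling_parameter(0.35)  # 1.3
#' doubling_parameter(0.5)   # 1: steady state
#' @export
doubling_parameter <- function(f_ingress) {
  if (!is.numeric(f_ingress) || length(f_ingress) != 1L ||
      is.na(f_ingress) || f_ingress < 0 || f_ingress > 1)
    stop("'f_ingress' must be a single value in [0, 1]")
  2 * (1 - f_ingress)
}

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Project the population forward
#'
#' Evaluates \eqn{U_n = q^n U_0} after `n` division rounds.
#'
#' @param model a [population_model()].
#' @param n number of divisions (non-negative integer; vectorized).
#' @return A data.frame with columns `n`, `cells` (real-valued) and
#'   `cells_rounded` (nearest integer, half away from zero).
#' @examples
#' m <- population_model(50, 0.35)
#' project_population(m, 9:10)$cells_rounded  # 530, 689
#' @export
project_population <- function(model, n) {
  stopifnot(inherits(model, "population_model"))
  if (any(n < 0) || any(n != floor(n)))
    stop("'n' must be a non-negative integer")
  cells <- model$q^n * model$U0
  data.frame(n = as.integer(n), cells = cells,
             cells_rounded = round_half_away(cells))
}

#' Bracketing division counts needed to reach a target population
#'
#' Returns the pair `(n_low, n_high)` where `n_high` is the smallest division
#' count with \eqn{U_n \ge} `target` and `n_low = n_high - 1`. A growing
#' population crosses the target between these two division rounds, so both
#' are reported rather than choosing one. If `U0` already meets the target,
#' `(0, 0)` is returned.
#'
#' @param model a [population_model()] with q > 1 (growing population).
#' @param target target population size (cells), at least `U0`.
#' @return Integer vector `c(n_low, n_high)`.
#' @examples
#' divisions_to_reach(population_model(50, 0.35), 550)  # c(9, 10)
#' @export
divisions_to_reach <- function(model, target) {
  stopifnot(inherits(model, "population_model"))
  if (target <= model$U0) return(c(n_low = 0L, n_high = 0L))
  if (model$q <= 1)
    stop("population is not growing (q <= 1): target unreachable")
  n_high <- ceiling(log(target / model$U0) / log(model$q))
  # guard against floating-point edge: ensure minimality and sufficiency
  while (model$q^(n_high - 1) * model$U0 >= target) n_high <- n_high - 1L
  while (model$q^n_high * model$U0 < target) n_high <- n_high + 1L
  c(n_low = as.integer(n_high - 1L), n_high = as.integer(n_high))
}

#' Average cell-cycle time implied by a division count
#'
#' @param total_time total duration of the expansion (hours).
#' @param n number of divisions within that window (>= 1).
#' @return Hours per division, `total_time / n`.
#' @examples
#' cycle_time(40, 10)  # 4 hours
#' @export
cycle_time <- function(total_time, n) {
  if (any(n < 1)) stop("'n' must be >= 1")
  total_time / n
}

#' Fit the growth model to observed counts
#'
#' Recovers the doubling parameter q (and hence the ingression fraction
#' f = 1 - q/2) from a series of population counts by ordinary least squares
#' of log(count) on the division index `time / assumed_cycle_time`.
#' Uncertainty is assessed by a case-resampling bootstrap over count rows.
#'
#' @param counts data.frame with columns `time_h` (hours) and `cells`
#'   (positive counts); at least 3 rows.
#' @param assumed_cycle_time assumed hours per division, used to convert
#'   time to a division index.
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return A list with `q`, `f_ingress`, `ci_q`, `ci_f` (percentile
#'   intervals), and the underlying `fit` (an `lm`).
#' @examples
#' m <- population_model(50, 0.35)
#' u <- project_population(m, 0:10)
#' counts <- data.frame(time_h = 4 * u$n, cells = u$cells)
#' fit_growth(counts, assumed_cycle_time = 4)$q  # 1.3
#' @export
fit_growth <- function(counts, assumed_cycle_time, n_boot = 1000,
                       conf = 0.95, seed = 1L) {
  stopifnot(is.data.frame(counts), all(c("time_h", "cells") %in% names(counts)))
  if (nrow(counts) < 3) stop("need at least 3 counts")
  if (any(counts$cells <= 0)) stop("counts must be positive")
  n_idx <- counts$time_h / assumed_cycle_time
  fit <- stats::lm(log(cells) ~ n_idx, data = transform(counts, n_idx = n_idx))
  q_hat <- exp(stats::coef(fit)[["n_idx"]])
  boot_q <- numeric(n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    i <- sample.int(nrow(counts), replace = TRUE)
    if (length(unique(n_idx[i])) < 2) { boot_q[b] <- NA_real_; next }
    bf <- stats::lm(log(counts$cells[i]) ~ n_idx[i])
    boot_q[b] <- exp(stats::coef(bf)[[2L]])
  }
  alpha <- (1 - conf) / 2
  ci_q <- stats::quantile(boot_q, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
  list(q = q_hat, f_ingress = 1 - q_hat / 2,
       ci_q = ci_q, ci_f = rev(1 - ci_q / 2), fit = fit)
}

#' Stochastic counterpart of the geometric growth model
#'
#' Simulates the population as a branching process: at every generation each
#' cell divides into two daughters, and each daughter independently ingresses
#' (leaves the pool) with probability `f_ingress`. The expected count after n
#' generations equals the deterministic projection \eqn{q^n U_0}.
#'
#' @param model a [population_model()].
#' @param n_generations number of generations to simulate.
#' @param seed integer seed.
#' @return Integer vector of length `n_generations + 1` with the population
#'   size at generations 0..n (generation 0 is `U0`). Extinction yields
#'   trailing zeros.
#' @examples
#' stochastic_growth_sim(population_model(1, 0), 10, seed = 1)[11]  # 1024
#' @export
stochastic_growth_sim <- function(model, n_generations, seed = 1L) {
  stopifnot(inherits(model, "population_model"), n_generations >= 0)
  set.seed(seed)
  counts <- integer(n_generations + 1L)
  counts[1L] <- as.integer(round(model$U0))
  p_stay <- 1 - model$f_ingress
  for (g in seq_len(n_generations)) {
    prev <- counts[g]
    counts[g + 1L] <- if (prev == 0L) 0L else
      stats::rbinom(1L, size = 2L * prev, prob = p_stay)
  }
  counts
}
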