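#' Build a table of soak observations
#'
#' Validates and assembles per-crystal records — crystal length (um), soak
#' time (s), refined occupancy (fraction) — into the data.frame consumed by
#' [fit_soak_model()]. Refined occupancies are expected on the fractional
#' scale and within the refinement clamp bounds [0.01, 0.99]; a column that
#' looks like percentages is rejected rather than silently rescaled.
#'
#' @param crystal_length Numeric vector, um, > 0.
#' @param soak_time Numeric vector, s, >= 0.
#' @param occupancy Numeric vector of refined occupancies in [0.01, 0.99].
#' @param system_label Single string naming the protein + ligand system.
#' @return A data.frame of class \code{soak_observations} with columns
#'   \code{crystal_length}, \code{soak_time}, \code{occupancy}.
#' @export
soak_observations <- function(crystal_length, soak_time, occupancy,
                              system_label = "unspecified") {
  n <- length(crystal_length)
  stopifnot(length(soak_time) == n, length(occupancy) == n)
  check_conditions(crystal_length, soak_time)
  if (any(!is.finite(occupancy)))
    stop("occupancies must be finite")
  if (any(occupancy > 1))
    stop("occupancies above 1 found: column must be fractions, not percent")
  if (any(occupancy < 0.01 - 1e-12) || any(occupancy > 0.99 + 1e-12))
    stop("occupancies must lie within the clamp bounds [0.01, 0.99]")
  out <- data.frame(crystal_length = as.numeric(crystal_length),
                    soak_time = as.numeric(soak_time),
                    occupancy = as.numeric(occupancy))
  attr(out, "system_label") <- system_label
  class(out) <- c("soak_observations", "data.frame")
  out
}

sum_sq_loss <- function(par, L, t, occ) {
  pred <- par[1] * t / (t + L * par[2])
  sum((occ - pred)^2)
}

#' Fit the soak-occupancy model by least squares
#'
#' Estimates \eqn{(O_{max}, \tau)} by minimising the unweighted sum of squared
#' residuals between refined and model occupancies, with bounds
#' \eqn{O_{max} \in (0, 1]}, \eqn{\tau > 0}. A bounded quasi-Newton search
#' (\code{optim}, L-BFGS-B) is started from a coarse grid of parameter pairs
#' and the best local optimum is kept, so results do not depend on a single
#' starting guess.
#'
#' @param observations A [soak_observations] table (or any data.frame with
#'   columns \code{crystal_length}, \code{soak_time}, \code{occupancy}) with
#'   at least 3 rows.
#' @return An object of class \code{soak_fit}: list with elements
#'   \code{params} ([soak_params]), \code{n_obs}, \code{r_squared} (variance
#'   explained about the identity line), \code{mean_abs_residual},
#'   \code{residuals} (refined minus calculated), \code{fitted}, and
#'   \code{loss} (residual sum of squares).
#' @examples
#' obs <- generate_observations(soak_preset("lysozyme_nag"), seed = 1)
#' fit <- fit_soak_model(obs)
#' fit$params
#' @export
fit_soak_model <- function(observations) {
  L <- observations$crystal_length
  t <- observations$soak_time
  occ <- observations$occupancy
  n <- length(occ)
  if (n < 3L) stop("need at least 3 observations to fit two parameters")
  check_conditions(L, t)
  if (length(unique(t)) < 2L || all(t == 0))
    stop("unidentifiable model: need at least two distinct soak times, one > 0")
  if (stats::var(occ) == 0 && length(unique(t[t > 0])) > 1L)
    stop("unidentifiable model: occupancies are constant across soak times")

  starts <- expand.grid(o_max = c(0.5, 0.7, 0.9, 1.0),
                        tau = c(0.1, 0.3, 1.0, 3.0))
  lower <- c(1e-6, 1e-8)
  upper <- c(1, 1e6)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(par = as.numeric(starts[i, ]), fn = sum_sq_loss,
                   L = L, t = t, occ = occ,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 10, pgtol = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimisation failed from every start")

  # profile polish: for fixed tau the optimal O_max is closed-form, so a 1-D
  # refinement over tau sharpens the multi-start optimum to machine precision
  omax_given_tau <- function(tau) {
    f <- t / (t + L * tau)
    min(max(sum(occ * f) / sum(f^2), 1e-6), 1)
  }
  profile_loss <- function(tau) sum_sq_loss(c(omax_given_tau(tau), tau),
                                            L, t, occ)
  tau0 <- best$par[2]
  opt <- stats::optimize(profile_loss, interval = c(tau0 / 2, tau0 * 2),
                         tol = 1e-10)
  par <- c(omax_given_tau(opt$minimum), opt$minimum)
  if (opt$objective > best$value) par <- best$par

  params <- soak_params(o_max = par[1], tau = par[2])
  fitted <- occupancy_calc(L, t, params)
  resid <- occ - fitted
  out <- list(params = params,
              n_obs = n,
              r_squared = r_squared_unity_slope(occ, fitted),
              mean_abs_residual = mean(abs(resid)),
              residuals = resid,
              fitted = fitted,
              loss = sum((occ - fitted)^2))
  class(out) <- "soak_fit"
  out
}

#' @export
print.soak_fit <- function(x, ...) {
  cat(sprintf(
    "Soak model fit (n = %d): O_max = %.3f, tau = %.3f s/um\n  R^2 = %.1f%%, mean |residual| = %.2f%%\n",
    x$n_obs, x$params$o_max, x$params$tau,
    100 * x$r_squared, 100 * x$mean_abs_residual))
  invisible(x)
}

#' Exhaustive grid-search fit of the soak model
#'
#' Brute-force reference optimiser: evaluates the residual sum of squares on
#' a regular \eqn{(O_{max}, \tau)} grid and returns the grid point with the
#' smallest loss (lowest \code{tau} wins exact ties). Intended as an
#' independent check of [fit_soak_model()] on small tables, not for routine
#' use.
#'
#' For fixed \eqn{\tau} the loss is quadratic in \eqn{O_{max}}, so the grid is
#' scanned one \eqn{\tau} at a time with the \eqn{O_{max}} axis vectorised;
#' every grid point is still evaluated exactly.
#'
#' @param observations Observation table as for [fit_soak_model()].
#' @param o_max_grid,tau_grid Numeric grids to scan.
#' @return List with \code{o_max}, \code{tau}, \code{loss}.
#' @export
grid_fit_soak_model <- function(observations,
                                o_max_grid = seq(0.01, 1.00, by = 0.001),
                                tau_grid = seq(0.01, 3.00, by = 0.001)) {
  L <- observations$crystal_length
  t <- observations$soak_time
  occ <- observations$occupancy
  sum_occ2 <- sum(occ^2)
  best_loss <- Inf
  best_omax <- NA_real_
  best_tau <- NA_real_
  for (tau in tau_grid) {
    f <- t / (t + L * tau)
    # loss(o) = sum(occ^2) - 2 o sum(occ f) + o^2 sum(f^2), vectorised over o
    a <- sum(f^2)
    b <- sum(occ * f)
    losses <- sum_occ2 - 2 * o_max_grid * b + o_max_grid^2 * a
    j <- which.min(losses)
    if (losses[j] < best_loss) {  # strict: ties keep the earlier (lower) tau
      best_loss <- losses[j]
      best_omax <- o_max_grid[j]
      best_tau <- tau
    }
  }
  list(o_max = best_omax, tau = best_tau, loss = best_loss)
}

#' Coefficient of determination about the identity line
#'
#' The model fixes a unity-slope relationship between refined and calculated
#' occupancies, so goodness of fit is reported as the variance in the refined
#' values explained by the identity line:
#' \deqn{R^2 = 1 - \sum (O_{ref} - O_{calc})^2 / \sum (O_{ref} - \bar O_{ref})^2.}
#' No slope or intercept is re-fitted; the statistic can be negative when the
#' model does worse than the mean.
#'
#' @param o_refine,o_calc Equal-length numeric vectors of refined and
#'   calculated occupancies.
#' @return R-squared as a fraction (possibly negative).
#' @export
r_squared_unity_slope <- function(o_refine, o_calc) {
  if (length(o_refine) != length(o_calc) || length(o_refine) == 0L)
    stop("`o_refine` and `o_calc` must be non-empty and of equal length")
  ss_tot <- sum((o_refine - mean(o_refine))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: `o_refine` has zero variance")
  1 - sum((o_refine - o_calc)^2) / ss_tot
}

#' Mean absolute residual between refined and calculated occupancies
#'
#' @inheritParams r_squared_unity_slope
#' @return Mean of \eqn{|O_{ref} - O_{calc}|}, a fraction.
#' @export
mean_abs_residual <- function(o_refine, o_calc) {
  if (length(o_refine) != length(o_calc) || length(o_refine) == 0L)
    stop("`o_refine` and `o_calc` must be non-empty and of equal length")
  mean(abs(o_refine - o_calc))
}

#' Population standard deviation
#'
#' Divide-by-n convention, \eqn{\sigma = (\sum (x - \bar x)^2 / n)^{1/2}} —
#' the spread of the values at hand, not an estimate for a larger population
#' (which would divide by n - 1 as \code{stats::sd} does).
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
population_sd <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty")
  sqrt(mean((x - mean(x))^2))
}

#' Residual-versus-size polynomial diagnostic
#'
#' If the occupancy model captured the size dependence completely, residuals
#' plotted against crystal length would be shapeless noise. This diagnostic
#' fits a least-squares polynomial of the residuals on crystal length and
#' reports its coefficients and R-squared; a diagnostic R-squared near zero
#' is consistent with no unmodelled size effect, while a clearly positive
#' value hints at higher-order terms.
#'
#' @param fit A [fit_soak_model()] result.
#' @param observations The observation table the fit was computed from.
#' @param degree Polynomial degree (default 3; must be < number of rows).
#' @return List with \code{coefficients} (intercept first) and
#'   \code{r_squared}; the all-zero-residual case is reported as R-squared 0.
#' @export
residual_size_diagnostic <- function(fit, observations, degree = 3L) {
  stopifnot(inherits(fit, "soak_fit"))
  resid <- fit$residuals
  L <- observations$crystal_length
  if (length(resid) != length(L))
    stop("fit and observations are not aligned")
  if (degree < 1L || degree >= length(resid))
    stop("`degree` must be >= 1 and < the number of observations")
  pfit <- stats::lm(resid ~ stats::poly(L, degree = degree, raw = TRUE))
  ss_tot <- sum((resid - mean(resid))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(pfit)^2) / ss_tot
  coefs <- unname(stats::coef(pfit))
  coefs[is.na(coefs)] <- 0
  list(coefficients = coefs, r_squared = r2)
}

#' Group observations into crystal-size bins
#'
#' Partitions observations into half-open size classes \eqn{[lower, upper)}
#' defined by strictly increasing edges (the presentation convention for
#' size-resolved soak curves). Observations at or beyond the last edge are
#' collected into a flagged overflow bin so the binning is always a
#' partition.
#'
#' @param observations Observation table.
#' @param edges Strictly increasing numeric vector of bin edges in um.
#' @return A list of bins; each bin is a list with \code{lower}, \code{upper},
#'   \code{n}, \code{mean_size} (NA when empty), \code{overflow} flag, and
#'   \code{observations} (the member rows).
#' @export
bin_by_size <- function(observations, edges) {
  if (any(diff(edges) <= 0)) stop("`edges` must be strictly increasing")
  L <- observations$crystal_length
  k <- length(edges) - 1L
  bins <- vector("list", k + 1L)
  for (i in seq_len(k)) {
    member <- L >= edges[i] & L < edges[i + 1L]
    bins[[i]] <- list(lower = edges[i], upper = edges[i + 1L],
                      n = sum(member),
                      mean_size = if (any(member)) mean(L[member]) else NA_real_,
                      overflow = FALSE,
                      observations = observations[member, , drop = FALSE])
  }
  member <- L >= edges[k + 1L] | L < edges[1L]
  bins[[k + 1L]] <- list(lower = edges[k + 1L], upper = Inf,
                         n = sum(member),
                         mean_size = if (any(member)) mean(L[member]) else NA_real_,
                         overflow = TRUE,
                         observations = observations[member, , drop = FALSE])
  bins
}
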