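#' Soak-model parameters
#'
#' Bundles the two parameters of the hyperbolic soak-occupancy model for one
#' protein--ligand system: the limit occupancy after an infinitely long soak
#' (\code{o_max}) and the rate constant \code{tau} (seconds per micrometre)
#' that links crystal size to the half-occupancy soak time via
#' \eqn{t_{1/2} = L\tau}.
#'
#' @param o_max Limit occupancy at infinite soak time, a fraction in (0, 1].
#' @param tau Rate constant in s/um, strictly positive.
#' @return An object of class \code{soak_params}.
#' @examples
#' lys <- soak_params(o_max = 0.903, tau = 0.794)
#' occupancy_calc(crystal_length = 310, soak_time = 750, params = lys)
#' @export
soak_params <- function(o_max, tau) {
  stopifnot(is.numeric(o_max), length(o_max) == 1L, is.finite(o_max),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (o_max <= 0 || o_max > 1)
    stop("`o_max` must be a fraction in (0, 1], got ", o_max)
  if (tau <= 0)
    stop("`tau` must be positive (s/um), got ", tau)
  structure(list(o_max = o_max, tau = tau), class = "soak_params")
}

#' @export
print.soak_params <- function(x, ...) {
  cat(sprintf("Soak model parameters: O_max = %.4g, tau = %.4g s/um\n",
              x$o_max, x$tau))
  invisible(x)
}

check_conditions <- function(crystal_length, soak_time) {
  stopifnot(is.numeric(crystal_length), is.numeric(soak_time))
  if (any(!is.finite(crystal_length)) || any(crystal_length <= 0))
    stop("`crystal_length` must be positive and finite (um)")
  if (any(!is.finite(soak_time)) || any(soak_time < 0))
    stop("`soak_time` must be non-negative and finite (s)")
  invisible(TRUE)
}

#' Occupancy predicted from crystal size and soak time
#'
#' Hyperbolic saturation model for the occupancy reached by a ligand soaking
#' into a crystal of length \code{L} (um) after time \code{t} (s):
#' \deqn{O(L, t) = O_{max} \cdot t / (t + L\tau).}
#' The model encodes a half-time proportional to crystal size,
#' \eqn{t_{1/2} = L\tau}: occupancy is 0 at \eqn{t = 0}, reaches half of
#' \eqn{O_{max}} at \eqn{t = L\tau}, and approaches \eqn{O_{max}}
#' asymptotically.
#'
#' @param crystal_length Crystal length in micrometres (> 0). Vectorised.
#' @param soak_time Soak time in seconds (>= 0). Vectorised.
#' @param params A [soak_params] object.
#' @return Occupancy fraction(s) in \eqn{[0, O_{max})}.
#' @seealso [half_occupancy_time()], [required_soak_time()]
#' @examples
#' occupancy_calc(310, 750, soak_params(0.903, 0.794))  # ~0.68
#' @export
occupancy_calc <- function(crystal_length, soak_time, params) {
  stopifnot(inherits(params, "soak_params"))
  check_conditions(crystal_length, soak_time)
  params$o_max * soak_time / (soak_time + crystal_length * params$tau)
}

#' Intra-crystalline dissociation constant from the limit occupancy
#'
#' Rearranges the fraction saturation equation
#' \eqn{O_{max} = C / (K_d + C)} to deduce the dissociation constant from the
#' limiting occupancy observed at ligand concentration \code{ligand_conc}:
#' \eqn{K_d = C (1 - O_{max}) / O_{max}}.
#'
#' @param o_max Limiting occupancy, a fraction strictly inside (0, 1).
#' @param ligand_conc Soaking ligand concentration in mM (> 0).
#' @return Dissociation constant in mM.
#' @examples
#' kd_from_omax(0.903, 50)   # ~5.4 mM
#' kd_from_omax(0.930, 100)  # ~7.5 mM
#' @export
kd_from_omax <- function(o_max, ligand_conc) {
  stopifnot(is.numeric(o_max), is.numeric(ligand_conc))
  if (any(o_max <= 0) || any(o_max >= 1))
    stop("`o_max` must lie strictly in (0, 1) for the saturation equation")
  if (any(ligand_conc <= 0))
    stop("`ligand_conc` must be positive (mM)")
  ligand_conc * (1 - o_max) / o_max
}

#' Limiting occupancy from a dissociation constant
#'
#' Forward direction of the fraction saturation equation,
#' \eqn{O_{max} = C / (K_d + C)}. Exact inverse of [kd_from_omax()].
#'
#' @param kd Dissociation constant in mM (> 0).
#' @param ligand_conc Ligand concentration in mM (> 0).
#' @return Occupancy fraction in (0, 1).
#' @export
omax_from_kd <- function(kd, ligand_conc) {
  stopifnot(is.numeric(kd), is.numeric(ligand_conc))
  if (any(kd <= 0) || any(ligand_conc <= 0))
    stop("`kd` and `ligand_conc` must be positive (mM)")
  ligand_conc / (kd + ligand_conc)
}

#' Soak time to reach half the limiting occupancy
#'
#' The model's central empirical relation: the time to half-saturation is
#' proportional to crystal length, \eqn{t_{1/2} = L\tau}.
#'
#' @inheritParams occupancy_calc
#' @return Half-occupancy time in seconds.
#' @export
half_occupancy_time <- function(crystal_length, params) {
  stopifnot(inherits(params, "soak_params"))
  if (any(!is.finite(crystal_length)) || any(crystal_length <= 0))
    stop("`crystal_length` must be positive (um)")
  crystal_length * params$tau
}

#' Soak time required to reach a target occupancy
#'
#' Algebraic inversion of the occupancy model for soak-experiment planning:
#' \eqn{t = L\tau \cdot O / (O_{max} - O)}. Only targets strictly below
#' \eqn{O_{max}} are reachable.
#'
#' @param target_occ Desired occupancy fraction, \eqn{0 \le O < O_{max}}.
#' @inheritParams occupancy_calc
#' @return Required soak time in seconds.
#' @examples
#' required_soak_time(0.80, 100, soak_params(0.903, 0.794))
#' @export
required_soak_time <- function(target_occ, crystal_length, params) {
  stopifnot(inherits(params, "soak_params"), is.numeric(target_occ))
  if (any(!is.finite(crystal_length)) || any(crystal_length <= 0))
    stop("`crystal_length` must be positive (um)")
  if (any(target_occ < 0))
    stop("`target_occ` must be non-negative")
  if (any(target_occ >= params$o_max))
    stop(sprintf(
      "target occupancy %.3g is unreachable: the model saturates at O_max = %.3g",
      max(target_occ), params$o_max))
  crystal_length * params$tau * target_occ / (params$o_max - target_occ)
}
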