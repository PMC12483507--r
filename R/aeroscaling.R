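#' Aerodynamic model parameters
#'
#' Parameter container for the quasi-steady hovering force model: air density
#' `rho` (kg m^-3), gravitational acceleration `g` (m s^-2), the
#' angle-of-attack-specific force coefficient `C_F_alpha` (dimensionless, the
#' slope of the force coefficient with `sin(alpha)`), and the number of wings
#' contributing to weight support.
#'
#' @param rho air density, kg m^-3.
#' @param g gravitational acceleration, m s^-2.
#' @param C_F_alpha angle-of-attack-specific force coefficient (> 0). The
#'   default 1.8 is typical of fruit-fly-scale revolving-wing measurements;
#'   see [calibrate_cfalpha()] to set it from a dataset.
#' @param n_wings number of wings whose force supports body weight.
#' @return list of class `aero_params`.
#' @export
aero_params <- function(rho = 1.225, g = 9.81, C_F_alpha = 1.8, n_wings = 2) {
  if (rho <= 0 || C_F_alpha <= 0 || g <= 0 || n_wings < 1)
    stop("invalid aerodynamic parameters")
  structure(list(rho = rho, g = g, C_F_alpha = C_F_alpha,
                 n_wings = n_wings), class = "aero_params")
}

#' Quasi-steady wingbeat-average aerodynamic force
#'
#' Wingbeat-average vertical force of a flapping wing in hover:
#' `F = 1/2 rho S2 omega_bar^2 sin(alpha_bar) C_F_alpha` per wing, where `S2`
#' is the wing's second-moment-of-area and `omega_bar` the wingbeat-average
#' angular speed. The decomposed form substitutes `S2 = R^3 c_bar S2_star`
#' and `omega_bar = 2 f A_phi` (`A_phi` in radians), separating wing size,
#' wing shape, and kinematics; both factorizations are algebraically
#' identical and [quasi_steady_force_decomposed()] evaluates the second.
#'
#' @param S2 second-moment-of-area, m^4 (> 0).
#' @param omega_bar wingbeat-average angular speed, rad s^-1 (>= 0).
#' @param alpha_bar mean mid-stroke angle-of-attack, rad, in (0, pi).
#' @param params an [aero_params()] object.
#' @return list: `F_per_wing` and `F_total` in newtons.
#' @examples
#' quasi_steady_force(1e-10, 650, 42 * pi / 180)$F_per_wing
#' @export
quasi_steady_force <- function(S2, omega_bar, alpha_bar,
                               params = aero_params()) {
  if (any(S2 < 0) || any(omega_bar < 0))
    stop("invalid parameters: S2 and omega_bar must be non-negative")
  if (any(alpha_bar <= 0) || any(alpha_bar >= pi))
    stop("invalid parameters: alpha_bar must lie in (0, pi)")
  Fw <- 0.5 * params$rho * S2 * omega_bar^2 *
    sin(alpha_bar) * params$C_F_alpha
  list(F_per_wing = Fw, F_total = params$n_wings * Fw)
}

#' @rdname quasi_steady_force
#' @param R wingspan (single wing), m.
#' @param c_bar mean chord, m.
#' @param S2_star normalised second-moment-of-area (dimensionless).
#' @param f wingbeat frequency, Hz.
#' @param A_phi peak-to-peak stroke amplitude, rad.
#' @export
quasi_steady_force_decomposed <- function(R, c_bar, S2_star, f, A_phi,
                                          alpha_bar,
                                          params = aero_params()) {
  if (any(R <= 0) || any(c_bar <= 0) || any(S2_star <= 0) || any(f < 0) ||
      any(A_phi < 0))
    stop("invalid parameters in decomposed force model")
  quasi_steady_force(S2 = R^3 * c_bar * S2_star,
                     omega_bar = 2 * f * A_phi,
                     alpha_bar = alpha_bar, params = params)
}

#' Weight-support ratio
#'
#' Ratio of total wingbeat-average vertical force to body weight; a ratio of
#' 1 means hovering weight support.
#'
#' @param F_total total vertical aerodynamic force, N.
#' @param mass_mg body mass in milligrams (> 0).
#' @param params an [aero_params()] object (supplies `g`).
#' @return dimensionless ratio.
#' @export
weight_support_ratio <- function(F_total, mass_mg, params = aero_params()) {
  if (any(mass_mg <= 0)) stop("mass must be positive")
  F_total / (mass_mg * 1e-6 * params$g)
}

#' Calibrate the force coefficient against a dataset
#'
#' Sets `C_F_alpha` so that the mass-weighted mean weight-support ratio of a
#' set of species equals 1, i.e. so the model predicts weight support on
#' average across the dataset.
#'
#' @param S2 second-moments-of-area, m^4.
#' @param omega_bar angular speeds, rad s^-1.
#' @param alpha_bar mid-stroke angles-of-attack, rad.
#' @param mass_mg body masses, mg.
#' @param params baseline [aero_params()]; all fields except `C_F_alpha` are
#'   kept.
#' @return an [aero_params()] object with the calibrated coefficient.
#' @export
calibrate_cfalpha <- function(S2, omega_bar, alpha_bar, mass_mg,
                              params = aero_params()) {
  base <- aero_params(rho = params$rho, g = params$g, C_F_alpha = 1,
                      n_wings = params$n_wings)
  Fv <- quasi_steady_force(S2, omega_bar, alpha_bar, base)$F_total
  ratio <- weight_support_ratio(Fv, mass_mg, base)
  wsr <- sum(mass_mg * ratio) / sum(mass_mg)
  aero_params(rho = params$rho, g = params$g, C_F_alpha = 1 / wsr,
              n_wings = params$n_wings)
}

#' Rescale a force to a species-specific wingbeat frequency
#'
#' Forces computed at a common reference frequency `f_mean` are converted to
#' the species-specific frequency `f` by the quadratic frequency dependence
#' of the quasi-steady model: `F * (f / f_mean)^2`.
#'
#' @param F force, N.
#' @param f species-specific wingbeat frequency, Hz (> 0).
#' @param f_mean reference (grand-mean) wingbeat frequency, Hz (> 0).
#' @return rescaled force, N.
#' @export
frequency_rescale <- function(F, f, f_mean) {
  if (any(f <= 0) || any(f_mean <= 0)) stop("frequencies must be positive")
  F * (f / f_mean)^2
}

# Similarity and single-metric weight-support exponents, derived from
# F ~ S2 omega^2 with S2 = R^3 c_bar S2_star, omega ~ f A_phi,
# C_F ~ sin(alpha), all other metrics held at similarity.
.baseline_table <- list(
  S2         = c(a_sim = 4 / 3, a_ws = 1),
  R          = c(a_sim = 1 / 3, a_ws = 2 / 9),
  c_bar      = c(a_sim = 1 / 3, a_ws = 0),
  S2_star    = c(a_sim = 0,     a_ws = -1 / 3),
  f          = c(a_sim = 0,     a_ws = -1 / 6),
  A_phi      = c(a_sim = 0,     a_ws = -1 / 6),
  omega_bar  = c(a_sim = 0,     a_ws = -1 / 6),
  alpha      = c(a_sim = 0,     a_ws = -1 / 3),
  S2_omega2  = c(a_sim = 4 / 3, a_ws = 1)
)

#' Similarity and single-metric weight-support scaling exponents
#'
#' For each morphology or kinematics metric in the quasi-steady force model,
#' returns (1) its exponent against body mass under geometric/kinematic
#' similarity (`a_sim`) and (2) the exponent it alone would need, all other
#' metrics at similarity, for the force to remain proportional to body
#' weight (`a_ws`). Derived from `F ~ S2 omega_bar^2`,
#' `S2 = R^3 c_bar S2_star`, `omega_bar ~ f A_phi`, `C_F ~ sin(alpha)`:
#' e.g. for the second-moment-of-area `a_sim = 4/3` and `a_ws = 1`; for
#' wingspan, `F ~ R^3 m^(1/3) omega^2 = m` gives `a_ws = 2/9`; for frequency
#' `m^(4/3) f^2 = m` gives `a_ws = -1/6`.
#'
#' @param metric one of `"S2"`, `"R"`, `"c_bar"`, `"S2_star"`, `"f"`,
#'   `"A_phi"`, `"omega_bar"`, `"alpha"`, `"S2_omega2"`.
#' @return list of class `scaling_baseline`: `metric`, `a_sim`, `a_ws`.
#' @examples
#' expected_exponents("R")$a_ws    # 2/9
#' @export
expected_exponents <- function(metric) {
  if (length(metric) != 1 || !metric %in% names(.baseline_table))
    stop("invalid parameter: unknown metric '", paste(metric, collapse = ","),
         "'. Supported: ", paste(names(.baseline_table), collapse = ", "))
  b <- .baseline_table[[metric]]
  structure(list(metric = metric, a_sim = unname(b["a_sim"]),
                 a_ws = unname(b["a_ws"])), class = "scaling_baseline")
}

#' Relative allometric scaling factor for weight support
#'
#' Expresses a fitted allometric exponent as the percentage of the way from
#' the similarity baseline to the single-metric weight-support baseline:
#' `a_star = 100 * (a_allo - a_sim) / (a_ws - a_sim)`. 0% means the metric
#' scales at similarity (contributing nothing to weight support across
#' sizes); 100% means its allometry alone fully maintains weight support.
#'
#' @param a_allo fitted allometric exponent.
#' @param a_sim similarity exponent.
#' @param a_ws single-metric weight-support exponent (must differ from
#'   `a_sim`).
#' @return a_star in percent (not rounded).
#' @examples
#' relative_scaling_factor(1.008, 4 / 3, 1)   # ~97.6
#' @export
relative_scaling_factor <- function(a_allo, a_sim, a_ws) {
  if (any(a_ws == a_sim))
    stop("undefined baseline: a_ws equals a_sim")
  100 * (a_allo - a_sim) / (a_ws - a_sim)
}

#' Round half away from zero
#'
#' Integer rounding used when reproducing printed percentage tables (base R
#' `round()` rounds half to even). A tolerance of ~1.5e-8 at the half-way
#' boundary absorbs binary representation error in values that are exact
#' halves in decimal arithmetic (e.g. a ratio equal to 70.5 computed through
#' floating point).
#'
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
round_half_away <- function(x)
  sign(x) * floor(abs(x) + 0.5 + sqrt(.Machine$double.eps))

#' Decompose weight-support compensation across metrics
#'
#' Converts per-metric allometric fits into relative allometric scaling
#' factors and reports the component sum for the metrics that multiply into
#' the decomposed force model (`f`, `R`, `c_bar`, `S2_star`): if their
#' allometries jointly maintain weight support, the component a* values sum
#' to roughly 100%.
#'
#' @param fits named list of [`scaling_fit`] objects; names are metric names
#'   accepted by [expected_exponents()]. Must contain at least
#'   `{f, R, c_bar, S2_star}` or `{S2, f}`.
#' @param alpha_level significance threshold applied to each fit's p-value.
#' @return object of class `ws_decomposition`: a data.frame `table` with
#'   columns metric, n, p_value, r_squared, intercept, slope, ci_lower,
#'   ci_upper, a_sim, a_ws, a_star, a_star_rounded, significant; plus
#'   `component_metrics` and `component_sum` (sum of rounded component a*).
#' @examples
#' fits <- list(
#'   f = scaling_fit(-0.037, -0.238, 0.164, 8),
#'   R = scaling_fit(0.272, 0.173, 0.371, 8),
#'   c_bar = scaling_fit(0.271, 0.147, 0.394, 8),
#'   S2_star = scaling_fit(-0.031, -0.061, 0.000, 8))
#' contribution_decomposition(fits)$component_sum  # 105
#' @export
contribution_decomposition <- function(fits, alpha_level = 0.05) {
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("configuration error: 'fits' must be a named list of metrics")
  comp_full <- c("f", "R", "c_bar", "S2_star")
  comp_s2 <- c("S2", "f")
  if (!all(comp_full %in% names(fits)) && !all(comp_s2 %in% names(fits)))
    stop("configuration error: fits must include {f, R, c_bar, S2_star} ",
         "or {S2, f}")
  rows <- lapply(names(fits), function(m) {
    b <- expected_exponents(m)
    fit <- fits[[m]]
    a_star <- relative_scaling_factor(fit$slope, b$a_sim, b$a_ws)
    data.frame(metric = m, n = fit$n, p_value = fit$p_value,
               r_squared = fit$r_squared, intercept = fit$intercept,
               slope = fit$slope, ci_lower = fit$ci[1], ci_upper = fit$ci[2],
               a_sim = b$a_sim, a_ws = b$a_ws, a_star = a_star,
               a_star_rounded = round_half_away(a_star),
               significant = !is.na(fit$p_value) &
                 fit$p_value < alpha_level,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  comp <- if (all(comp_full %in% tab$metric)) comp_full else comp_s2
  csum <- sum(tab$a_star_rounded[match(comp, tab$metric)])
  structure(list(table = tab, component_metrics = comp,
                 component_sum = csum), class = "ws_decomposition")
}

#' @export
print.ws_decomposition <- function(x, ...) {
  cat("Weight-support contribution decomposition\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s slope %7.3f  a_sim %6.3f  a_ws %6.3f  a* %4d%%%s\n",
                tab$metric[i], tab$slope[i], tab$a_sim[i], tab$a_ws[i],
                as.integer(tab$a_star_rounded[i]),
                ifelse(isTRUE(tab$significant[i]), " *", "")))
  }
  cat(sprintf("  component sum (%s): %d%%\n",
              paste(x$component_metrics, collapse = " + "),
              as.integer(x$component_sum)))
  invisible(x)
}
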