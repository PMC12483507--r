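#' Wingbeat trace object
#'
#' Time series of the three wing Euler angles relative to the stroke plane:
#' stroke angle `phi` (fore-aft sweep within the stroke plane), deviation
#' angle `eta` (out-of-plane motion), and rotation angle `theta` (pitch about
#' the spanwise axis). Angles in degrees, time in seconds.
#'
#' @param t strictly increasing time vector, s.
#' @param phi,eta,theta angle vectors, degrees.
#' @return data.frame of class `wingbeat_trace`.
#' @export
wingbeat_trace <- function(t, phi, eta = 0 * t, theta = 0 * t) {
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (!all(is.finite(c(phi, eta, theta)))) stop("angles must be finite")
  structure(data.frame(t_s = t, phi_deg = phi, eta_deg = eta,
                       theta_deg = theta),
            class = c("wingbeat_trace", "data.frame"))
}

#' Average left and right wing traces
#'
#' Pointwise mean of the three wing angles over matching timebases, the
#' standard preprocessing step before Fourier fitting when both wings were
#' tracked.
#'
#' @param trace_L,trace_R [wingbeat_trace()] objects on the same timebase.
#' @return a [wingbeat_trace()].
#' @export
average_left_right <- function(trace_L, trace_R) {
  if (nrow(trace_L) != nrow(trace_R) ||
      max(abs(trace_L$t_s - trace_R$t_s)) > median(diff(trace_L$t_s)))
    stop("alignment error: left/right timebases do not match")
  wingbeat_trace(trace_L$t_s,
                 (trace_L$phi_deg + trace_R$phi_deg) / 2,
                 (trace_L$eta_deg + trace_R$eta_deg) / 2,
                 (trace_L$theta_deg + trace_R$theta_deg) / 2)
}

# Wingbeat period: coarse least-squares scan over integer numbers of cycles
# in the trace (the stroke angle is near-sinusoidal, so a fundamental-only
# fit identifies the right cycle count even under angle noise), then a
# continuous polish minimizing the full-order Fourier residual. The scan is
# bounded by the Nyquist-style sampling contract (>= 20 samples/wingbeat).
estimate_period <- function(t, phi, order = 4) {
  n <- length(phi)
  if (n < 8) stop("trace too short to identify a wingbeat period")
  dur <- diff(range(t))
  rss <- function(Tw, ord) {
    B <- fourier_basis(t, Tw, ord)
    sum(stats::lm.fit(B, phi)$residuals^2)
  }
  c_max <- max(2, floor(n / 20))
  cands <- seq_len(c_max)
  r1 <- vapply(dur / cands, rss, numeric(1), ord = 1)
  c_best <- cands[which.min(r1)]
  lower <- dur / (c_best + 0.6)
  upper <- if (c_best > 1) dur / (c_best - 0.6) else 1.8 * dur
  stats::optimize(rss, interval = c(lower, upper), tol = 1e-12,
                  ord = order)$minimum
}

fourier_basis <- function(t, period, order) {
  w <- 2 * pi / period
  B <- matrix(1, length(t), 1 + 2 * order)
  for (k in seq_len(order)) {
    B[, 2 * k] <- cos(k * w * t)
    B[, 2 * k + 1] <- sin(k * w * t)
  }
  colnames(B) <- c("mean",
                   as.vector(rbind(paste0("cos", seq_len(order)),
                                   paste0("sin", seq_len(order)))))
  B
}

#' Fit a Fourier series to a wingbeat trace
#'
#' Identifies the wingbeat period from successive stroke-angle maxima
#' (refined by least squares) and fits an order-`order` Fourier series to
#' each of the three wing angles by linear least squares on the raw samples.
#' Analytic derivatives of the fitted series are available through
#' [eval_fourier()].
#'
#' @param trace a [wingbeat_trace()] spanning at least one full wingbeat.
#' @param order Fourier order (default 4).
#' @param period optional known wingbeat period, s; estimated when `NULL`.
#' @return list of class `fourier_fit`: `period` (s), `order`, `coef`
#'   (named list per angle: mean, cos/sin coefficient pairs, degrees),
#'   `rms_resid` (degrees per angle), `t_range`.
#' @export
fit_wingbeat_fourier <- function(trace, order = 4, period = NULL) {
  stopifnot(inherits(trace, "wingbeat_trace"))
  t <- trace$t_s
  if (length(t) < 2 * order + 2)
    stop("underdetermined fit: fewer samples than Fourier coefficients")
  if (is.null(period)) {
    if (stats::sd(trace$phi_deg) < 1e-9) {
      period <- diff(range(t))     # constant stroke angle: period arbitrary
    } else {
      period <- estimate_period(t, trace$phi_deg, order)
    }
  }
  B <- fourier_basis(t, period, order)
  coefs <- list(); rms <- c()
  for (ang in c("phi", "eta", "theta")) {
    y <- trace[[paste0(ang, "_deg")]]
    f <- stats::lm.fit(B, y)
    coefs[[ang]] <- stats::setNames(f$coefficients, colnames(B))
    rms[ang] <- sqrt(mean(f$residuals^2))
  }
  structure(list(period = period, order = order, coef = coefs,
                 rms_resid = rms, t_range = range(t)),
            class = "fourier_fit")
}

#' Evaluate a fitted Fourier series (or its time derivative)
#'
#' @param fit a [fit_wingbeat_fourier()] result.
#' @param angle one of `"phi"`, `"eta"`, `"theta"`.
#' @param t times, s.
#' @param deriv 0 for the angle (degrees), 1 for its rate (deg s^-1).
#' @return numeric vector.
#' @export
eval_fourier <- function(fit, angle = c("phi", "eta", "theta"), t,
                         deriv = 0) {
  angle <- match.arg(angle)
  cf <- fit$coef[[angle]]
  w <- 2 * pi / fit$period
  out <- if (deriv == 0) rep(cf[1], length(t)) else rep(0, length(t))
  for (k in seq_len(fit$order)) {
    a <- cf[2 * k]; b <- cf[2 * k + 1]
    if (deriv == 0) {
      out <- out + a * cos(k * w * t) + b * sin(k * w * t)
    } else {
      out <- out + k * w * (-a * sin(k * w * t) + b * cos(k * w * t))
    }
  }
  unname(out)
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("Fourier wingbeat fit: order %d, period %.4g s (f = %.1f Hz)\n",
              x$order, x$period, 1 / x$period))
  cat(sprintf("  residual RMS (deg): phi %.3g, eta %.3g, theta %.3g\n",
              x$rms_resid["phi"], x$rms_resid["eta"], x$rms_resid["theta"]))
  invisible(x)
}

# Angle-of-attack from the fitted angles: the angle between the wing plane
# and the velocity direction of the reference spanwise station.
# Stroke-plane frame: z normal to the stroke plane, phi sweeps in-plane,
# eta elevates out of plane, theta pitches the chord about the span axis
# (theta = 0: wing plane in the stroke plane).
alpha_at <- function(fit, t, station = 1) {
  d2r <- pi / 180
  phi <- eval_fourier(fit, "phi", t) * d2r
  eta <- eval_fourier(fit, "eta", t) * d2r
  theta <- eval_fourier(fit, "theta", t) * d2r
  dphi <- eval_fourier(fit, "phi", t, deriv = 1) * d2r
  deta <- eval_fourier(fit, "eta", t, deriv = 1) * d2r
  # span unit vector and its time derivative (velocity direction at the
  # reference station; station fraction scales magnitude only)
  sx <- sin(phi) * cos(eta); sy <- cos(phi) * cos(eta); sz <- sin(eta)
  vx <- dphi * cos(phi) * cos(eta) - deta * sin(phi) * sin(eta)
  vy <- -dphi * sin(phi) * cos(eta) - deta * cos(phi) * sin(eta)
  vz <- deta * cos(eta)
  vmag <- sqrt(vx^2 + vy^2 + vz^2) * station
  # chord direction at theta = 0 (in the stroke plane, perpendicular to the
  # span's in-plane projection), pitched by theta about the span axis;
  # wing normal = span x chord
  c0x <- cos(phi); c0y <- -sin(phi); c0z <- rep(0, length(phi))
  # third frame vector completing span/chord0: e3 = s x c0
  e3x <- sy * c0z - sz * c0y
  e3y <- sz * c0x - sx * c0z
  e3z <- sx * c0y - sy * c0x
  cx <- cos(theta) * c0x + sin(theta) * e3x
  cy <- cos(theta) * c0y + sin(theta) * e3y
  cz <- cos(theta) * c0z + sin(theta) * e3z
  nx <- sy * cz - sz * cy
  ny <- sz * cx - sx * cz
  nz <- sx * cy - sy * cx
  num <- abs(vx * nx + vy * ny + vz * nz)
  alpha <- rep(NA_real_, length(t))
  ok <- vmag > 1e-9
  alpha[ok] <- asin(pmin(1, num[ok] / vmag[ok])) / d2r
  alpha
}

#' Wingbeat-average kinematic summary from a Fourier fit
#'
#' Derives the standard wingbeat-average parameters: wingbeat frequency
#' `f = 1/T`; stroke, deviation, and rotation amplitudes as peak-to-peak
#' ranges of the fitted curves over one period; wingbeat-average angular
#' speed `omega_bar = 2 f A_phi` (reported in deg s^-1 and rad s^-1; for a
#' sinusoidal stroke this equals the cycle mean of
#' `omega(t) = sqrt(phi_dot^2 + eta_dot^2)`); mean angle-of-attack
#' `alpha_bar` evaluated at the two mid-stroke phases (the extrema of
#' `phi_dot`, where force production peaks); and peak angular rates.
#'
#' @param fit a [fit_wingbeat_fourier()] result.
#' @param station spanwise station fraction (of R) whose velocity defines
#'   the angle-of-attack reference direction (default 1, the wingtip).
#' @param n_eval evaluation grid size over one period.
#' @return list of class `wingbeat_summary`: `f_Hz`, `A_phi_deg`,
#'   `A_eta_deg`, `A_theta_deg`, `omega_bar_deg_s`, `omega_bar_rad_s`,
#'   `alpha_bar_deg`, `phi_dot_peak`, `eta_dot_peak`, `theta_dot_peak`
#'   (deg s^-1).
#' @export
derive_wingbeat_summary <- function(fit, station = 1, n_eval = 2000) {
  stopifnot(inherits(fit, "fourier_fit"))
  tt <- seq(0, fit$period, length.out = n_eval + 1)[-(n_eval + 1)]
  phi <- eval_fourier(fit, "phi", tt)
  eta <- eval_fourier(fit, "eta", tt)
  theta <- eval_fourier(fit, "theta", tt)
  dphi <- eval_fourier(fit, "phi", tt, deriv = 1)
  deta <- eval_fourier(fit, "eta", tt, deriv = 1)
  dtheta <- eval_fourier(fit, "theta", tt, deriv = 1)
  f <- 1 / fit$period
  A_phi <- diff(range(phi))
  omega_bar <- 2 * f * A_phi
  # mid-stroke phases: extrema of phi_dot (one per half-stroke)
  mid <- c(which.max(dphi), which.min(dphi))
  alpha_mid <- alpha_at(fit, tt[mid], station = station)
  structure(list(
    f_Hz = f, A_phi_deg = A_phi, A_eta_deg = diff(range(eta)),
    A_theta_deg = diff(range(theta)),
    omega_bar_deg_s = omega_bar, omega_bar_rad_s = omega_bar * pi / 180,
    alpha_bar_deg = mean(alpha_mid),
    phi_dot_peak = max(abs(dphi)), eta_dot_peak = max(abs(deta)),
    theta_dot_peak = max(abs(dtheta))
  ), class = "wingbeat_summary")
}

#' @export
print.wingbeat_summary <- function(x, ...) {
  cat(sprintf("Wingbeat summary: f = %.1f Hz, A_phi = %.1f deg\n",
              x$f_Hz, x$A_phi_deg))
  cat(sprintf("  omega_bar = %.0f deg/s (%.0f rad/s), alpha_bar = %.1f deg\n",
              x$omega_bar_deg_s, x$omega_bar_rad_s, x$alpha_bar_deg))
  invisible(x)
}

#' Summarize a wingbeat trace
#'
#' Convenience wrapper: Fourier fit followed by the wingbeat-average
#' summary.
#'
#' @inheritParams fit_wingbeat_fourier
#' @inheritParams derive_wingbeat_summary
#' @return a `wingbeat_summary` (see [derive_wingbeat_summary()]).
#' @export
summarize_wingbeat <- function(trace, order = 4, period = NULL, station = 1) {
  derive_wingbeat_summary(fit_wingbeat_fourier(trace, order, period),
                          station = station)
}

#' Body-kinematics summary over a flight sequence
#'
#' Flight speed by central differences of the body track, climb angle
#' `gamma_climb = atan(U_ver / U_hor)`, stroke-plane pitch
#' `beta_strokeplane = beta_body - 45` (the stroke plane is fixed at 45
#' degrees to the body long axis), advance ratio
#' `J = U / (omega_bar_rad * R)`, the hovering flag `J < 0.1`, and the
#' sequence-mean wingbeat frequency `f_hat = n_wingbeats / T_sequence`.
#'
#' @param track data.frame with columns `t_s`, `x_m`, `y_m`, `z_m` (z
#'   vertical) and optionally `body_pitch_deg`.
#' @param n_wingbeats number of wingbeats in the sequence.
#' @param omega_bar_rad_s wingbeat-average angular speed, rad s^-1 (> 0).
#' @param R_m single-wing span in metres (> 0).
#' @param hover_threshold advance-ratio threshold for hovering (default 0.1).
#' @return list of class `body_kinematics`: `U_m_s`, `gamma_climb_deg`,
#'   `beta_body_deg`, `beta_strokeplane_deg`, `J`, `hovering`, `f_hat_Hz`.
#' @export
body_kinematics_summary <- function(track, n_wingbeats, omega_bar_rad_s,
                                    R_m, hover_threshold = 0.1) {
  need <- c("t_s", "x_m", "y_m", "z_m")
  if (!all(need %in% names(track)))
    stop("track needs columns: ", paste(need, collapse = ", "))
  if (nrow(track) < 3) stop("need at least 3 body positions")
  if (R_m <= 0 || omega_bar_rad_s <= 0)
    stop("R and omega_bar must be positive")
  t <- track$t_s
  cd <- function(p) {
    n <- length(p)
    c((p[2] - p[1]) / (t[2] - t[1]),
      (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
      (p[n] - p[n - 1]) / (t[n] - t[n - 1]))
  }
  vx <- cd(track$x_m); vy <- cd(track$y_m); vz <- cd(track$z_m)
  U_vec <- sqrt(vx^2 + vy^2 + vz^2)
  U <- mean(U_vec)
  U_hor <- mean(sqrt(vx^2 + vy^2)); U_ver <- mean(vz)
  gamma <- if (U_hor > 0) atan(U_ver / U_hor) * 180 / pi else
    90 * sign(U_ver)
  beta_body <- if ("body_pitch_deg" %in% names(track))
    mean(track$body_pitch_deg) else NA_real_
  Tseq <- diff(range(t))
  J <- U / (omega_bar_rad_s * R_m)
  structure(list(
    U_m_s = U, gamma_climb_deg = gamma, beta_body_deg = beta_body,
    beta_strokeplane_deg = beta_body - 45, J = J,
    hovering = J < hover_threshold,
    f_hat_Hz = n_wingbeats / Tseq
  ), class = "body_kinematics")
}

#' @export
print.body_kinematics <- function(x, ...) {
  cat(sprintf(
    "Body kinematics: U = %.3f m/s, climb %.1f deg, J = %.3f (%s)\n",
    x$U_m_s, x$gamma_climb_deg, x$J,
    if (isTRUE(x$hovering)) "hovering" else "not hovering"))
  cat(sprintf("  beta_body = %.1f deg, beta_strokeplane = %.1f deg, f_hat = %.1f Hz\n",
              x$beta_body_deg, x$beta_strokeplane_deg, x$f_hat_Hz))
  invisible(x)
}
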