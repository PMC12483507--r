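#' Scenario configuration for the synthetic-data generator
#'
#' Defines the generative conditions for a synthetic clade: how many species,
#' the body-mass range, and which scaling scenario links wing morphology and
#' wingbeat kinematics to mass. The three scenarios encode the alternative
#' hypotheses for how weight support is maintained across sizes:
#' \describe{
#'   \item{isometry}{geometric and kinematic similarity: `R ~ m^(1/3)`,
#'     `c_bar ~ m^(1/3)`, `S2_star` and all kinematics constant (so
#'     `S2 ~ m^(4/3)` and weight support degrades in small species).}
#'   \item{morphology_compensated}{wing morphology alone maintains weight
#'     support: `R ~ m^(2/9)`, `c_bar ~ m^(1/3)`, kinematics constant, so
#'     `S2 ~ m`.}
#'   \item{kinematics_compensated}{morphology isometric, wingbeat frequency
#'     `f ~ m^(-1/6)` maintains weight support.}
#' }
#'
#' @param n_species number of species (>= 3).
#' @param mass_range body-mass range in mg, `c(min, max)`, both > 0.
#' @param scenario one of `"isometry"`, `"morphology_compensated"`,
#'   `"kinematics_compensated"`.
#' @param shape_exponent extra mass exponent on `S2_star` (default 0).
#' @param noise_sd_log10 residual SD applied to each trait on the log10
#'   scale (multiplicative biology; default 0.02).
#' @param kin_noise_sd additive angle noise SD in degrees for generated
#'   wingbeat traces (default 2).
#' @param seed integer RNG seed (mandatory).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 28, mass_range = c(3, 132),
                            scenario = c("isometry",
                                         "morphology_compensated",
                                         "kinematics_compensated"),
                            shape_exponent = 0, noise_sd_log10 = 0.02,
                            kin_noise_sd = 2, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_species < 3) stop("invalid parameter: n_species must be >= 3")
  if (length(mass_range) != 2 || mass_range[1] <= 0 ||
      mass_range[1] >= mass_range[2])
    stop("invalid parameter: mass_range must satisfy 0 < min < max")
  if (noise_sd_log10 < 0 || kin_noise_sd < 0)
    stop("invalid parameter: noise SDs must be >= 0")
  structure(list(n_species = as.integer(n_species), mass_range = mass_range,
                 scenario = scenario, shape_exponent = shape_exponent,
                 noise_sd_log10 = noise_sd_log10,
                 kin_noise_sd = kin_noise_sd, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file with the [scenario_config()] fields; `seed` required.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(scenario_config, cfg[intersect(names(cfg),
                                         names(formals(scenario_config)))])
}

#' Simulate a pure-birth clade with Brownian-motion body masses
#'
#' Generates a Yule (pure-birth) phylogeny, rescales it to unit root-to-tip
#' depth, and evolves log10 body mass along its branches by Brownian motion
#' from a root value. The tree supplies a plausible covariance structure for
#' phylogenetic analyses; it does not emulate any particular clade.
#'
#' @param n_species number of tips (>= 3).
#' @param birth_rate speciation rate (> 0); affects topology/branching times.
#' @param sigma2_bm BM rate of log10 mass per unit depth (>= 0).
#' @param root_mass_log10 root value of log10 body mass (mass in mg).
#' @param seed integer RNG seed.
#' @return list: `tree` (ultrametric `phylo`, unit depth), `mass_mg` (named
#'   vector), `log10_mass` (named vector).
#' @export
simulate_clade <- function(n_species, birth_rate = 1, sigma2_bm = 0.1,
                           root_mass_log10 = log10(20), seed = 1) {
  if (n_species < 3) stop("invalid parameter: n_species must be >= 3")
  if (birth_rate <= 0) stop("invalid parameter: birth_rate must be > 0")
  if (sigma2_bm < 0) stop("invalid parameter: sigma2_bm must be >= 0")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  lm10 <- bm_tips(tree, sigma2_bm, root_mass_log10)
  list(tree = tree, mass_mg = 10^lm10, log10_mass = lm10)
}

# Brownian motion along the tree edges; returns tip values named by label.
bm_tips <- function(tree, sigma2, root_value) {
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  ntip <- length(tree$tip.label)
  vals <- rep(NA_real_, ntip + tree$Nnode)
  vals[ntip + 1] <- root_value
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (i in seq_len(nrow(tree$edge)))
    vals[tree$edge[i, 2]] <- vals[tree$edge[i, 1]] + inc[i]
  stats::setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Synthesize a wing outline with a Beta-density chord profile
#'
#' Builds a symmetric wing outline whose spanwise chord distribution is
#' proportional to the Beta(p, q) density on the normalized span, so the
#' enclosed area is `R * c_bar` and the normalised second-moment-of-area is
#' analytically the second raw moment of the Beta distribution,
#' `p (p + 1) / ((p + q) (p + q + 1))`. The hinge landmark sits at the span
#' axis origin.
#'
#' @param R wingspan, mm (> 0).
#' @param c_bar mean chord, mm (> 0).
#' @param beta_p,beta_q Beta shape parameters (>= 1; smaller values make the
#'   chord profile diverge at the wing base or tip).
#' @param n_points approximate number of outline points (>= 50).
#' @return a [wing_outline()] object.
#' @examples
#' w <- synth_wing_outline(10, 3, 3, 2)
#' morphology_from_outline(w)$S2_star       # ~ 3*4 / (5*6) = 0.4
#' @export
synth_wing_outline <- function(R, c_bar, beta_p = 3, beta_q = 2,
                               n_points = 400) {
  if (R <= 0 || c_bar <= 0) stop("R and c_bar must be positive")
  if (beta_p <= 0 || beta_q <= 0) stop("beta shapes must be positive")
  if (n_points < 50) stop("n_points must be >= 50")
  nr <- max(25, ceiling(n_points / 2))
  rh <- seq(0, 1, length.out = nr)
  cr <- c_bar * stats::dbeta(rh, beta_p, beta_q)
  if (any(!is.finite(cr)))
    stop("generation error: chord profile diverges at the base or tip ",
         "(need beta_p >= 1 and beta_q >= 1)")
  x <- rh * R
  lower <- cbind(x, -cr / 2)
  upper <- cbind(rev(x), rev(cr) / 2)
  pts <- rbind(c(0, 0), lower, c(R, 0), upper)
  out <- wing_outline(pts, hinge_index = 1, check = FALSE)
  if (self_intersects(out$points))
    stop("generation error: parameters produce a self-intersecting outline")
  if (abs(polygon_area(out$points)) < 1e-12)
    stop("generation error: degenerate outline")
  out
}

#' Synthesize a periodic wingbeat trace
#'
#' Generates the canonical hovering wingbeat pattern: a sinusoidal stroke
#' angle at frequency `f` with peak-to-peak amplitude `A_phi`, a
#' small-amplitude second-harmonic deviation angle, and a smoothed
#' square-wave rotation angle whose mid-stroke plateau equals the requested
#' mid-stroke angle-of-attack (rotation convention: `theta = 0` puts the
#' wing plane in the stroke plane, so the mid-stroke angle-of-attack is
#' `|theta|` when deviation is small). Gaussian angle noise is added to all
#' three angles.
#'
#' @param f wingbeat frequency, Hz (> 0).
#' @param A_phi peak-to-peak stroke amplitude, degrees.
#' @param A_eta peak-to-peak deviation amplitude, degrees.
#' @param alpha_mid target mid-stroke angle-of-attack, degrees; the rotation
#'   amplitude is `A_theta = 2 * alpha_mid`.
#' @param n_wingbeats number of wingbeats to generate.
#' @param sample_rate sampling rate, Hz (>= 20 f).
#' @param kin_noise_sd additive angle noise SD, degrees.
#' @param seed optional integer seed.
#' @return a [wingbeat_trace()].
#' @details The rotation template is the flat-top two-harmonic wave
#'   `sin(x) + sin(3x)/6` (x the wingbeat phase), scaled so the value at the
#'   two mid-stroke phases equals `alpha_mid`. Being band-limited to the
#'   third harmonic it is represented exactly by the order-4 Fourier fit of
#'   [fit_wingbeat_fourier()], so noiseless traces round-trip the generative
#'   mid-stroke angle-of-attack to solver tolerance.
#' @export
synth_wingbeat_trace <- function(f, A_phi = 100, A_eta = 10, alpha_mid = 42,
                                 n_wingbeats = 3, sample_rate = 40 * f,
                                 kin_noise_sd = 0, seed = NULL) {
  if (f <= 0) stop("f must be positive")
  if (A_phi < 0 || A_eta < 0) stop("amplitudes must be >= 0")
  if (sample_rate < 20 * f)
    stop("undersampling error: sample_rate must be >= 20 * f")
  t <- seq(0, n_wingbeats / f, by = 1 / sample_rate)
  x <- 2 * pi * f * t
  phi <- (A_phi / 2) * cos(x)
  eta <- (A_eta / 2) * cos(2 * x)
  theta <- alpha_mid * (sin(x) + sin(3 * x) / 6) / (5 / 6)
  if (kin_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    phi <- phi + stats::rnorm(length(t), 0, kin_noise_sd)
    eta <- eta + stats::rnorm(length(t), 0, kin_noise_sd)
    theta <- theta + stats::rnorm(length(t), 0, kin_noise_sd)
  }
  wingbeat_trace(t, phi, eta, theta)
}

#' Synthesize a body track
#'
#' Straight-line body trajectory at constant speed and climb angle with a
#' constant body pitch, plus optional Gaussian position jitter: the minimal
#' body-kinematics input for the hovering filter.
#'
#' @param duration_s sequence duration, s.
#' @param U_m_s flight speed, m s^-1.
#' @param climb_deg climb angle, degrees.
#' @param beta_body_deg body pitch angle, degrees.
#' @param sample_rate sampling rate, Hz.
#' @param pos_noise_sd_m positional jitter SD, m.
#' @param seed optional integer seed.
#' @return data.frame: `t_s`, `x_m`, `y_m`, `z_m`, `body_pitch_deg`.
#' @export
synth_body_track <- function(duration_s = 0.15, U_m_s = 0.05, climb_deg = 0,
                             beta_body_deg = 30, sample_rate = 2500,
                             pos_noise_sd_m = 0, seed = NULL) {
  t <- seq(0, duration_s, by = 1 / sample_rate)
  g <- climb_deg * pi / 180
  x <- U_m_s * cos(g) * t
  z <- U_m_s * sin(g) * t
  y <- rep(0, length(t))
  if (pos_noise_sd_m > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(length(t), 0, pos_noise_sd_m)
    y <- y + stats::rnorm(length(t), 0, pos_noise_sd_m)
    z <- z + stats::rnorm(length(t), 0, pos_noise_sd_m)
  }
  data.frame(t_s = t, x_m = x, y_m = y, z_m = z,
             body_pitch_deg = rep(beta_body_deg, length(t)))
}

# Scenario exponents for each trait vs body mass.
scenario_exponents <- function(scenario, shape_exponent = 0) {
  base <- switch(scenario,
    isometry = c(R = 1 / 3, c_bar = 1 / 3, S2_star = 0, f = 0, A_phi = 0,
                 alpha = 0),
    morphology_compensated = c(R = 2 / 9, c_bar = 1 / 3, S2_star = 0, f = 0,
                               A_phi = 0, alpha = 0),
    kinematics_compensated = c(R = 1 / 3, c_bar = 1 / 3, S2_star = 0,
                               f = -1 / 6, A_phi = 0, alpha = 0),
    stop("invalid parameter: unknown scenario '", scenario, "'")
  )
  base["S2_star"] <- base["S2_star"] + shape_exponent
  base
}

# Reference trait values at the reference mass (mg): a mid-sized hoverfly.
.ref_traits <- c(mass = 30, R = 9.6, c_bar = 3.2, S2_star = 0.34, f = 186,
                 A_phi = 100, alpha = 42)

#' Generate a synthetic species set under a scaling scenario
#'
#' Simulates a clade ([simulate_clade()]), maps the Brownian-motion tip
#' values of log10 body mass affinely onto the configured mass range (so the
#' phylogenetic correlation structure is preserved and all masses stay in
#' range), and derives per-species wing morphology and wingbeat kinematics
#' from mass via the scenario's power laws, with independent log-normal
#' residual noise of SD `noise_sd_log10` per trait. `S2` is computed from
#' the generated components (`S2 = S2_star * R^3 * c_bar`).
#'
#' @param config a [scenario_config()].
#' @param birth_rate,sigma2_bm clade-simulation parameters passed to
#'   [simulate_clade()].
#' @return list of class `species_set`: `tree` (`phylo`), `traits`
#'   (data.frame: species, mass_mg, R_mm, cbar_mm, S2star, S2_mm4, f_Hz,
#'   Aphi_deg, alpha_deg), `config`.
#' @examples
#' ss <- generate_species_set(scenario_config(seed = 1, noise_sd_log10 = 0))
#' coef(ols_loglog(ss$traits$mass_mg, ss$traits$S2_mm4))["slope"]  # 4/3
#' @export
generate_species_set <- function(config, birth_rate = 1, sigma2_bm = 0.1) {
  stopifnot(inherits(config, "scenario_config"))
  ex <- scenario_exponents(config$scenario, config$shape_exponent)
  clade <- simulate_clade(config$n_species, birth_rate = birth_rate,
                          sigma2_bm = sigma2_bm,
                          root_mass_log10 = log10(.ref_traits["mass"]),
                          seed = config$seed)
  lm10 <- clade$log10_mass
  lo <- log10(config$mass_range[1]); hi <- log10(config$mass_range[2])
  if (diff(range(lm10)) < 1e-12) {
    lm10[] <- (lo + hi) / 2
  } else {
    lm10 <- lo + (lm10 - min(lm10)) / diff(range(lm10)) * (hi - lo)
  }
  mass <- 10^lm10
  rel <- lm10 - log10(.ref_traits["mass"])   # log10(m / m_ref)
  n <- config$n_species
  gen <- function(trait) {
    noise <- if (config$noise_sd_log10 > 0)
      stats::rnorm(n, 0, config$noise_sd_log10) else rep(0, n)
    .ref_traits[trait] * 10^(ex[trait] * rel + noise)
  }
  traits <- data.frame(
    species = names(lm10), mass_mg = unname(mass),
    R_mm = unname(gen("R")), cbar_mm = unname(gen("c_bar")),
    S2star = unname(gen("S2_star")), f_Hz = unname(gen("f")),
    Aphi_deg = unname(gen("A_phi")), alpha_deg = unname(gen("alpha")),
    stringsAsFactors = FALSE
  )
  traits$S2_mm4 <- traits$S2star * traits$R_mm^3 * traits$cbar_mm
  traits <- traits[, c("species", "mass_mg", "R_mm", "cbar_mm", "S2star",
                       "S2_mm4", "f_Hz", "Aphi_deg", "alpha_deg")]
  structure(list(tree = clade$tree, traits = traits, config = config),
            class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat(sprintf(
    "Synthetic species set: %d species, scenario '%s', mass %.3g-%.3g mg\n",
    nrow(x$traits), x$config$scenario, min(x$traits$mass_mg),
    max(x$traits$mass_mg)))
  invisible(x)
}

#' Beta shape parameters matching a target normalised second-moment-of-area
#'
#' Solves for `q` (given `p`) such that the second raw moment of Beta(p, q),
#' the `S2_star` of a [synth_wing_outline()], equals the target.
#'
#' @param S2_star target in (0, p / (p + 2)] so that `q >= 1`.
#' @param p first shape parameter (default 3).
#' @return c(p, q).
#' @export
beta_shapes_for_s2star <- function(S2_star, p = 3) {
  if (S2_star <= 0 || S2_star >= 1) stop("S2_star must be in (0, 1)")
  s <- (-S2_star + sqrt(S2_star^2 + 4 * S2_star * p * (p + 1))) /
    (2 * S2_star)
  q <- s - p
  if (q < 1) stop("target S2_star too large for beta_p = ", p,
                  " (chord would diverge at the tip)")
  c(p = p, q = q)
}

#' Write a species set to disk
#'
#' Writes the Newick tree, the species trait table CSV, one outline
#' coordinate CSV per species (Beta-profile wings matching each species'
#' `R`, `c_bar` and `S2star`), and one wingbeat-trace CSV per species.
#'
#' @param ss a [generate_species_set()] result.
#' @param dir output directory (created if needed).
#' @param n_wingbeats wingbeats per generated trace.
#' @return invisibly, the list of written paths.
#' @export
write_species_set <- function(ss, dir, n_wingbeats = 3) {
  stopifnot(inherits(ss, "species_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = file.path(dir, "tree.nwk"),
                traits = file.path(dir, "traits.csv"))
  ape::write.tree(ss$tree, paths$tree)
  utils::write.csv(format_num_df(ss$traits), paths$traits,
                   row.names = FALSE, quote = FALSE)
  tr <- ss$traits
  for (i in seq_len(nrow(tr))) {
    pq <- beta_shapes_for_s2star(tr$S2star[i])
    w <- synth_wing_outline(tr$R_mm[i], tr$cbar_mm[i], pq[1], pq[2])
    write_wing_outline(w, file.path(dir, paste0("outline_", tr$species[i],
                                                ".csv")))
    trace <- synth_wingbeat_trace(
      f = tr$f_Hz[i], A_phi = tr$Aphi_deg[i], A_eta = 0.1 * tr$Aphi_deg[i],
      alpha_mid = tr$alpha_deg[i], n_wingbeats = n_wingbeats,
      kin_noise_sd = ss$config$kin_noise_sd,
      seed = ss$config$seed + i)
    utils::write.csv(format_num_df(as.data.frame(trace)),
                     file.path(dir, paste0("trace_", tr$species[i], ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

# Format numeric columns to 6 significant digits so repeated runs give
# byte-identical CSVs.
format_num_df <- function(d) {
  for (j in seq_along(d))
    if (is.numeric(d[[j]])) d[[j]] <- formatC(d[[j]], digits = 6,
                                              format = "g")
  d
}
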