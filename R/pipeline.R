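#' Pipeline configuration
#'
#' Configuration for [run_pipeline()]: either `mode = "synthetic"` with a
#' [scenario_config()], or `mode = "files"` with paths to a Newick tree, a
#' species trait CSV, per-species outline CSVs, and per-species wingbeat
#' trace CSVs.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param scenario a [scenario_config()] (synthetic mode).
#' @param tree_path,traits_path Newick / trait-CSV paths (files mode).
#' @param outline_paths,trace_paths named character vectors (names =
#'   species) of outline and trace CSV paths (files mode; optional --
#'   morphology/kinematics stages are skipped for species without files).
#' @param aero an [aero_params()] object; `C_F_alpha` is recalibrated
#'   against the dataset when `calibrate = TRUE`.
#' @param calibrate recalibrate `C_F_alpha` so the mass-weighted mean
#'   weight-support ratio is 1 (default TRUE).
#' @param out_dir output directory for report JSON and CSV tables (`NULL`
#'   for no files).
#' @param seed integer seed (mandatory; all pipeline randomness derives from
#'   it).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), scenario = NULL,
                            tree_path = NULL, traits_path = NULL,
                            outline_paths = NULL, trace_paths = NULL,
                            aero = aero_params(), calibrate = TRUE,
                            out_dir = NULL, seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (mode == "synthetic" && !inherits(scenario, "scenario_config"))
    stop("synthetic mode needs a scenario_config")
  if (mode == "files" && (is.null(tree_path) || is.null(traits_path)))
    stop("files mode needs tree_path and traits_path")
  structure(list(mode = mode, scenario = scenario, tree_path = tree_path,
                 traits_path = traits_path, outline_paths = outline_paths,
                 trace_paths = trace_paths, aero = aero,
                 calibrate = calibrate, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full scaling-analysis pipeline
#'
#' End-to-end analysis: load or generate the species set; regress each
#' morphology and kinematics metric against body mass with PGLS under
#' Brownian motion; compute Blomberg's K per trait; evaluate the
#' quasi-steady force model per species, regress each log metric on the log
#' model force by OLS (force on the abscissa), and decompose the relative
#' contribution of each metric's allometry to weight support; report
#' weight-support ratios and the hovering (advance-ratio) filter summary.
#' Deterministic for a given config and seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `traits`, `fits_mass` (PGLS
#'   fits vs mass), `fits_force` (OLS fits vs model force),
#'   `classification`, `signal` (Blomberg K table), `decomposition_mass`,
#'   `decomposition_force`, `weight_support`, `hovering`, `aero`, `seed`.
#'   When `config$out_dir` is set, writes `report.json` and CSV tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "synthetic") {
    ss <- stage("simulate", generate_species_set(config$scenario))
    tree <- ss$tree
    traits <- ss$traits
  } else {
    tree <- stage("load-tree", ape::read.tree(config$tree_path))
    traits <- stage("load-traits", utils::read.csv(config$traits_path))
    need <- c("species", "mass_mg", "R_mm", "cbar_mm", "S2star", "f_Hz",
              "Aphi_deg", "alpha_deg")
    if (!all(need %in% names(traits)))
      stop("[stage load-traits] traits CSV needs columns: ",
           paste(need, collapse = ", "))
    if (is.null(traits$S2_mm4))
      traits$S2_mm4 <- traits$S2star * traits$R_mm^3 * traits$cbar_mm
  }

  # morphology stage: recompute metrics from outlines where provided
  if (config$mode == "files" && length(config$outline_paths)) {
    for (sp in names(config$outline_paths)) {
      i <- match(sp, traits$species)
      if (is.na(i)) stop("[stage morphology] unknown species '", sp, "'")
      mo <- stage(paste0("morphology:", sp), morphology_from_outline(
        read_wing_outline(config$outline_paths[[sp]]),
        mass = traits$mass_mg[i]))
      traits$R_mm[i] <- mo$R; traits$cbar_mm[i] <- mo$c_bar
      traits$S2star[i] <- mo$S2_star; traits$S2_mm4[i] <- mo$S2
    }
  }
  # kinematics stage: summarize traces where provided
  if (config$mode == "files" && length(config$trace_paths)) {
    for (sp in names(config$trace_paths)) {
      i <- match(sp, traits$species)
      if (is.na(i)) stop("[stage kinematics] unknown species '", sp, "'")
      d <- stage(paste0("kinematics:", sp),
                 utils::read.csv(config$trace_paths[[sp]]))
      ws <- stage(paste0("kinematics:", sp), summarize_wingbeat(
        wingbeat_trace(d$t_s, d$phi_deg, d$eta_deg, d$theta_deg)))
      traits$f_Hz[i] <- ws$f_Hz; traits$Aphi_deg[i] <- ws$A_phi_deg
      traits$alpha_deg[i] <- ws$alpha_bar_deg
    }
  }

  mass <- stats::setNames(traits$mass_mg, traits$species)
  metric_cols <- c(S2 = "S2_mm4", R = "R_mm", c_bar = "cbar_mm",
                   S2_star = "S2star", f = "f_Hz", A_phi = "Aphi_deg",
                   omega_bar = "omega_bar", alpha = "alpha_deg")
  traits$omega_bar <- 2 * traits$f_Hz * traits$Aphi_deg # deg/s

  # PGLS of each metric vs mass
  fits_mass <- lapply(names(metric_cols), function(m) {
    y <- stats::setNames(traits[[metric_cols[m]]], traits$species)
    stage(paste0("pgls:", m), pgls_loglog(tree, mass, y, metric = m))
  })
  names(fits_mass) <- names(metric_cols)
  classification <- vapply(names(fits_mass), function(m)
    allometry_classify(fits_mass[[m]], expected_exponents(m)$a_sim),
    character(1))

  # Blomberg's K per trait (seeded permutations)
  sig_traits <- c("mass", names(metric_cols))
  signal <- do.call(rbind, lapply(seq_along(sig_traits), function(i) {
    m <- sig_traits[i]
    y <- if (m == "mass") mass else
      stats::setNames(traits[[metric_cols[m]]], traits$species)
    if (stats::var(log10(y)) < 1e-20)       # constant trait: no signal test
      return(data.frame(trait = m, K = NA_real_, p_value = NA_real_,
                        n_perm = 0L, stringsAsFactors = FALSE))
    k <- stage(paste0("blomberg:", m),
               blomberg_k(tree, log10(y), n_perm = 999,
                          seed = config$seed + i))
    data.frame(trait = m, K = k$K, p_value = k$p_value,
               n_perm = k$n_perm, stringsAsFactors = FALSE)
  }))

  # quasi-steady forces (SI units) and weight support
  aero <- config$aero
  S2_m4 <- traits$S2_mm4 * 1e-12
  omega_rad <- traits$omega_bar * pi / 180
  alpha_rad <- traits$alpha_deg * pi / 180
  if (config$calibrate)
    aero <- stage("calibrate", calibrate_cfalpha(
      S2_m4, omega_rad, alpha_rad, traits$mass_mg, aero))
  Fv <- quasi_steady_force(S2_m4, omega_rad, alpha_rad, aero)
  traits$F_total_N <- Fv$F_total
  traits$ws_ratio <- weight_support_ratio(Fv$F_total, traits$mass_mg, aero)

  # hovering filter: synthetic hovering body tracks per species
  J <- vapply(seq_len(nrow(traits)), function(i) {
    trk <- synth_body_track(U_m_s = 0.05, seed = config$seed + 1000 + i,
                            pos_noise_sd_m = 0)
    bk <- body_kinematics_summary(trk, n_wingbeats = 25,
                                  omega_bar_rad_s = omega_rad[i],
                                  R_m = traits$R_mm[i] / 1000)
    bk$J
  }, numeric(1))
  hovering <- list(J = J, pass_rate = mean(J < 0.1))

  # OLS of each log metric (response) on log model force (predictor),
  # force on the abscissa, each trait on the ordinate
  fits_force <- lapply(names(metric_cols), function(m) {
    y <- traits[[metric_cols[m]]]
    stage(paste0("ols-force:", m),
          ols_loglog(traits$F_total_N, y, metric = m))
  })
  names(fits_force) <- names(metric_cols)
  fits_force$S2_omega2 <- stage("ols-force:S2_omega2",
                                ols_loglog(traits$F_total_N,
                                           S2_m4 * omega_rad^2,
                                           metric = "S2_omega2"))
  decomposition_mass <- contribution_decomposition(fits_mass)
  decomposition_force <- contribution_decomposition(fits_force)

  report <- structure(list(
    traits = traits, fits_mass = fits_mass, fits_force = fits_force,
    classification = classification, signal = signal,
    decomposition_mass = decomposition_mass,
    decomposition_force = decomposition_force,
    weight_support = stats::setNames(traits$ws_ratio, traits$species),
    hovering = hovering, aero = aero, seed = config$seed
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Scaling-analysis pipeline report (%d species, seed %d)\n",
              nrow(x$traits), x$seed))
  cat(sprintf("  weight-support ratio: %.3f-%.3f (C_F_alpha = %.3f)\n",
              min(x$weight_support), max(x$weight_support),
              x$aero$C_F_alpha))
  cat(sprintf("  hovering pass rate (J < 0.1): %.0f%%\n",
              100 * x$hovering$pass_rate))
  cat("  a* vs mass:\n")
  print(x$decomposition_mass)
  invisible(x)
}

fits_to_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) summary(f)))
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` plus CSV tables (`fits_mass.csv`, `fits_force.csv`,
#' `decomposition_mass.csv`, `decomposition_force.csv`, `species.csv`) in
#' the standard scaling-table layout (metric, n, p, R2, intercept, slope,
#' CI95, baselines, a*). Numeric formatting is fixed to 6
#' significant digits so identical runs produce byte-identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the report path.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(format_num_df(d),
                                          file.path(dir, f),
                                          row.names = FALSE, quote = FALSE)
  tab_m <- fits_to_table(report$fits_mass)
  tab_f <- fits_to_table(report$fits_force)
  tab_m$allometry <- report$classification[tab_m$metric]
  wcsv(tab_m, "fits_mass.csv")
  wcsv(tab_f, "fits_force.csv")
  wcsv(report$decomposition_mass$table, "decomposition_mass.csv")
  wcsv(report$decomposition_force$table, "decomposition_force.csv")
  wcsv(report$traits, "species.csv")
  wcsv(report$signal, "blomberg_k.csv")
  js <- list(
    seed = report$seed,
    aero = unclass(report$aero),
    fits_mass = tab_m, fits_force = tab_f,
    allometry = as.list(report$classification),
    blomberg_k = report$signal,
    a_star_mass = stats::setNames(
      report$decomposition_mass$table$a_star_rounded,
      report$decomposition_mass$table$metric),
    a_star_force = stats::setNames(
      report$decomposition_force$table$a_star_rounded,
      report$decomposition_force$table$metric),
    component_sum_mass = report$decomposition_mass$component_sum,
    component_sum_force = report$decomposition_force$component_sum,
    weight_support_ratio = as.list(report$weight_support),
    hovering_pass_rate = report$hovering$pass_rate
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = 6,
                       dataframe = "rows")
  invisible(path)
}
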