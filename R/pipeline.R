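#' Run the full bite-force pipeline from a configuration
#'
#' Orchestrates the whole analysis — PCSA table, per-muscle mechanics,
#' closed-mouth bite forces, gape sweep, muscle-stress calibration and
#' parameter sensitivity — and writes a report bundle (CSV + JSON + plain
#' text) to an output directory. Every constant used is logged in the
#' JSON report; given identical inputs the bundle is byte-identical across
#' reruns.
#'
#' @param config A named list, or the path of a YAML/JSON file holding
#'   one, with entries:
#'   \describe{
#'   \item{architecture}{path of a muscle-architecture CSV (required); see
#'     [read_architecture()].}
#'   \item{landmarks}{path of a landmark CSV/JSON ([read_landmarks()]); or}
#'   \item{action, d_cbp}{geometry-free inputs: path of a CSV with columns
#'     `muscle,phi_deg,theta_deg,lever_mm[,moment_sign]`, and a named list
#'     of out-levers in mm.}
#'   \item{constants}{optional list of [model_constants()] overrides.}
#'   \item{f_alive}{optional named list, in vivo force (N) per bite point,
#'     enabling calibration.}
#'   \item{gape_step, max_gape, full_sweep}{gape-sweep controls (defaults
#'     0.5, 60, FALSE); sweeps run only in geometry mode.}
#'   \item{sensitivity_fraction}{perturbation fraction (default 0.05).}
#'   \item{exclude}{optional muscles forced into the opener set.}
#'   }
#' @param out_dir Directory for the report bundle (created if needed).
#' @return Invisibly, a list with the fitted [bite_model()], the gape
#'   sweeps, calibrations, sensitivity tables and the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("'config' must be a list or the path of a YAML/JSON file",
         call. = FALSE)
  if (is.null(config$architecture))
    stop("config entry 'architecture' (CSV path) is required", call. = FALSE)
  constants <- do.call(model_constants, as.list(config$constants))
  arch <- read_architecture(config$architecture)

  if (!is.null(config$landmarks)) {
    geom <- read_landmarks(config$landmarks)
    model <- bite_model(arch, geometry = geom, constants = constants,
                        exclude = config$exclude)
  } else if (!is.null(config$action)) {
    if (is.null(config$d_cbp))
      stop("geometry-free mode needs config entry 'd_cbp'", call. = FALSE)
    act <- utils::read.csv(config$action, stringsAsFactors = FALSE)
    need <- c("muscle", "phi_deg", "theta_deg", "lever_mm")
    missing_cols <- setdiff(need, names(act))
    if (length(missing_cols))
      stop("action file ", config$action, " is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    action <- data.frame(muscle = act$muscle, phi = act$phi_deg,
                         theta = act$theta_deg, lever = act$lever_mm,
                         stringsAsFactors = FALSE)
    if ("moment_sign" %in% names(act)) action$moment_sign <- act$moment_sign
    model <- bite_model(arch, action = action,
                        d_cbp = unlist(config$d_cbp),
                        constants = constants, exclude = config$exclude)
  } else {
    stop("config must provide either 'landmarks' or 'action' + 'd_cbp'",
         call. = FALSE)
  }

  step <- config$gape_step %||% 0.5
  max_gape <- config$max_gape %||% 60
  full_sweep <- isTRUE(config$full_sweep)
  frac <- config$sensitivity_fraction %||% 0.05
  bps <- names(model$forces)

  sweeps <- if (!is.null(model$geometry)) {
    stats::setNames(lapply(bps, function(bp)
      sweep_gape(model, bp, step = step, max_gape = max_gape,
                 full_sweep = full_sweep)), bps)
  }
  f_alive <- config$f_alive
  fits <- if (!is.null(f_alive)) {
    avail <- intersect(names(f_alive), bps)
    stats::setNames(lapply(avail, function(bp) {
      ref <- if (!is.null(sweeps)) sweeps[[bp]]$optimal_force
             else model$forces[[bp]]
      fit <- fit_muscle_stress(as.numeric(f_alive[[bp]]), ref,
                               constants$muscle_stress)
      fit$bite_point <- bp
      fit$gape <- if (!is.null(sweeps)) sweeps[[bp]]$optimal_gape else 0
      fit
    }), avail)
  }
  sens <- stats::setNames(
    lapply(bps, function(bp) sensitivity(model, bp, fraction = frac)), bps)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_report_bundle(model, sweeps, fits, sens, out_dir)
  invisible(list(model = model, sweeps = sweeps, calibrations = fits,
                 sensitivity = sens, paths = paths))
}

write_report_bundle <- function(model, sweeps, fits, sens, out_dir) {
  p <- function(f) file.path(out_dir, f)
  arch <- model$architecture
  pcsa_tab <- data.frame(muscle = arch$muscle, mass_g = arch$mass,
                         fibre_length_mm = arch$fibre_length,
                         pcsa_cm2 = unname(pcsa(arch, model$constants)))
  utils::write.csv(pcsa_tab, p("pcsa_table.csv"), row.names = FALSE)
  utils::write.csv(model$mechanics, p("mechanics_table.csv"),
                   row.names = FALSE)

  summary_tab <- data.frame(
    bite_point = names(model$forces),
    fcalc_closed_N = round(unname(model$forces), 6),
    optimal_gape_deg = if (!is.null(sweeps))
      vapply(sweeps, function(s) s$optimal_gape, numeric(1)) else NA_real_,
    fcalc_optimal_N = if (!is.null(sweeps))
      vapply(sweeps, function(s) s$optimal_force, numeric(1)) else NA_real_,
    fitted_stress_Ncm2 = vapply(names(model$forces), function(bp)
      if (!is.null(fits[[bp]])) fits[[bp]]$fitted_stress else NA_real_,
      numeric(1)))
  utils::write.csv(summary_tab, p("bite_summary.csv"), row.names = FALSE)
  for (bp in names(sens))
    utils::write.csv(as.data.frame(sens[[bp]]$entries),
                     p(sprintf("sensitivity_%s.csv", bp)))
  if (!is.null(sweeps))
    for (bp in names(sweeps))
      utils::write.csv(sweeps[[bp]]$profile,
                       p(sprintf("gape_profile_%s.csv", bp)),
                       row.names = FALSE)

  report <- list(
    constants = unclass(model$constants),
    excluded_muscles = model$excluded,
    out_levers_mm = as.list(model$d_cbp),
    bite_forces = as.list(model$forces),
    gape = model$gape,
    optimal = if (!is.null(sweeps)) lapply(sweeps, function(s)
      list(gape_deg = s$optimal_gape, force_N = s$optimal_force)),
    calibration = if (!is.null(fits)) lapply(fits, function(f)
      list(f_alive_N = f$f_alive, f_calc_ref_N = f$f_calc_ref,
           gape_deg = f$gape, fitted_stress_Ncm2 = f$fitted_stress)))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  txt <- c("Static-equilibrium bite-force report",
           "====================================",
           sprintf("muscle stress %.3f N/cm2, density %.4f g/cm3, mass correction %.3f",
                   model$constants$muscle_stress, model$constants$density,
                   model$constants$mass_correction),
           sprintf("excluded from the bite-force sum: %s",
                   paste(model$excluded, collapse = ", ")),
           "",
           sprintf("%-10s %14s %14s %14s %18s", "bite point",
                   "Fcalc closed N", "opt. gape deg", "Fcalc opt. N",
                   "fitted stress"),
           vapply(seq_len(nrow(summary_tab)), function(i)
             sprintf("%-10s %14.3f %14s %14s %18s",
                     summary_tab$bite_point[i], summary_tab$fcalc_closed_N[i],
                     ifelse(is.na(summary_tab$optimal_gape_deg[i]), "-",
                            sprintf("%.2f", summary_tab$optimal_gape_deg[i])),
                     ifelse(is.na(summary_tab$fcalc_optimal_N[i]), "-",
                            sprintf("%.3f", summary_tab$fcalc_optimal_N[i])),
                     ifelse(is.na(summary_tab$fitted_stress_Ncm2[i]), "-",
                            sprintf("%.3f", summary_tab$fitted_stress_Ncm2[i]))),
             character(1)))
  writeLines(txt, p("report.txt"))
  c(pcsa = p("pcsa_table.csv"), mechanics = p("mechanics_table.csv"),
    summary = p("bite_summary.csv"), json = p("report.json"),
    text = p("report.txt"))
}
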