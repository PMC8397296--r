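#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults fixed at the study's stated
#' values: 0.50 nm Zn-Zn bimetallic cutoff, 0.25 nm O-Zn binding threshold,
#' 0.20 nm Zn-water solvation cutoff, 5 ps frame spacing, and boxplot
#' quantiles 5/25/50/75/95. Inputs may be files (topology/trajectory paths
#' plus a label map) or a synthetic configuration; stages are any subset of
#' \code{"simulate"}, \code{"structure"}, \code{"bundles"}, \code{"events"},
#' \code{"t1"}.
#'
#' @param topology,trajectory Input file paths (optional when `synthetic`).
#' @param label_map Label map object or YAML path (optional when `synthetic`).
#' @param synthetic A [synthetic_config()] to generate the inputs.
#' @param schedule Optional [event_schedule()] for the synthetic stage.
#' @param stages Character vector of stage names to run.
#' @param zn_zn_cut,o_zn_cut,zn_water_cut Detection cutoffs (nm).
#' @param hb_d_cut,hb_angle_cut Hydrogen-bond criterion.
#' @param dt Frame spacing (ps) if the trajectory file carries none.
#' @param quantiles Boxplot quantiles.
#' @param fit_range Optional decay-fit range (ns).
#' @param temperature_k,viscosity_pa_s,freq_1h_mhz,r_ch_nm,acf_max_lag_ps
#'   Relaxation-stage parameters.
#' @param t1_carbons Carbon names for the T1 stage.
#' @param seed Integer seed for stochastic stages.
#' @param out_dir Output directory.
#' @return List of class \code{nanosite_run_config}.
#' @export
run_config <- function(topology = NULL, trajectory = NULL, label_map = NULL,
                       synthetic = NULL, schedule = NULL,
                       stages = c("structure", "bundles", "events"),
                       zn_zn_cut = 0.50, o_zn_cut = 0.25, zn_water_cut = 0.20,
                       hb_d_cut = 0.35, hb_angle_cut = 30, dt = 5,
                       quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       fit_range = NULL, temperature_k = 300,
                       viscosity_pa_s = 8.5e-4, freq_1h_mhz = 400.13,
                       r_ch_nm = 0.109, acf_max_lag_ps = 2000,
                       t1_carbons = c("C7"), seed = 1L, out_dir = tempdir()) {
  known <- c("simulate", "structure", "bundles", "events", "t1")
  bad <- setdiff(stages, known)
  if (length(bad))
    ns_abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
             "config_error")
  structure(as.list(environment()), class = "nanosite_run_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on either file inputs
#' or a freshly generated synthetic system, writing one manifest (config
#' echo, package version, seed) plus per-stage CSV/JSON outputs into
#' `config$out_dir`. All stochastic stages are seeded from `config$seed`, so
#' identical configurations produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a named list of stage results; also writes files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nanosite_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  t0 <- Sys.time()

  if (!is.null(config$synthetic)) {
    np <- build_nanoparticle(config$synthetic)
    topo <- np$topology
    traj <- generate_trajectory(np, config$schedule, config$synthetic)
    if ("simulate" %in% config$stages) {
      write_gro(topo, traj$coords, diag(config$synthetic$box_edge, 3),
                file.path(config$out_dir, "synthetic.gro"), times = traj$times)
      results$simulate <- list(topology = topo, trajectory = traj)
    }
  } else {
    if (is.null(config$topology) || is.null(config$trajectory))
      ns_abort("either synthetic config or topology+trajectory inputs required",
               "io_error")
    for (f in c(config$topology, config$trajectory))
      if (!file.exists(f))
        ns_abort(paste0("missing input file: ", f), "io_error")
    lm <- config$label_map
    if (is.character(lm)) lm <- read_label_map(lm)
    topo <- load_topology(config$topology, lm)
    traj <- load_trajectory(config$trajectory, topo, dt = config$dt)
  }

  log_stage <- function(name, t_start, note = "") {
    message(sprintf("[nanosite] stage=%s elapsed=%.2fs %s", name,
                    as.numeric(Sys.time() - t_start, units = "secs"), note))
  }

  if ("structure" %in% config$stages) {
    ts <- Sys.time()
    rg <- radius_of_gyration(traj, topo, selection = setdiff(atom_roles(),
                                                             c("WATER_O", "WATER_H", "CL", "OTHER")))
    ecc <- eccentricity(traj, topo, selection = "GOLD")
    rdf_zn <- radial_distribution(traj, topo, reference = NULL, target = "ZN",
                                  from_center = TRUE)
    results$structure <- list(rg = rg, eccentricity = ecc, rdf_zn = rdf_zn)
    write.csv(rg, file.path(config$out_dir, "radius_of_gyration.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(rdf_zn), file.path(config$out_dir, "rdf_zn.csv"),
              row.names = FALSE)
    log_stage("structure", ts, sprintf("rg_mean=%.3fnm", attr(rg, "mean")))
  }

  if ("bundles" %in% config$stages) {
    ts <- Sys.time()
    b <- detect_bundles(traj, topo, d_cut = config$hb_d_cut,
                        angle_cut = config$hb_angle_cut)
    results$bundles <- b
    write.csv(b$frequency, file.path(config$out_dir, "bundle_frequency.csv"),
              row.names = FALSE)
    log_stage("bundles", ts, sprintf("n_records=%d", nrow(b$records)))
  }

  if ("events" %in% config$stages) {
    ts <- Sys.time()
    ev <- build_events(traj, topo, kind = "znpair", cutoff = config$zn_zn_cut)
    if (n_substrates(topo) > 0) {
      ev <- dplyr::bind_rows(ev,
        build_events(traj, topo, kind = "binding", o_cut = config$o_zn_cut),
        build_events(traj, topo, kind = "precat", threshold = config$o_zn_cut))
    }
    results$events <- ev
    write.csv(as.data.frame(ev), file.path(config$out_dir, "events.csv"),
              row.names = FALSE)
    if (nrow(ev[ev$kind == "znpair", ]) > 0) {
      curve <- population_curve(ev[ev$kind == "znpair", ])
      if (length(unique(curve$t_ns)) >= 3) {
        dec <- fit_decay(curve, fit_range = config$fit_range)
        results$decay <- dec
        write_report(dec, "json", file.path(config$out_dir, "decay.json"))
      }
      results$location <- location_stats(ev[ev$kind == "znpair", ])
      write.csv(results$location,
                file.path(config$out_dir, "site_location.csv"),
                row.names = FALSE)
    }
    log_stage("events", ts, sprintf("n_events=%d", nrow(ev)))
  }

  if ("t1" %in% config$stages) {
    ts <- Sys.time()
    rg <- results$structure$rg %||%
      radius_of_gyration(traj, topo, selection = setdiff(atom_roles(),
                                                         c("WATER_O", "WATER_H", "CL", "OTHER")))
    tum <- stokes_einstein(config$temperature_k, config$viscosity_pa_s,
                           hydrodynamic_radius(attr(rg, "mean")))
    t1s <- list()
    for (cb in config$t1_carbons) {
      a <- ch_acf(traj, topo, cb, max_lag = config$acf_max_lag_ps)
      ft <- fit_internal_acf(a, max_lag_ps = config$acf_max_lag_ps)
      t1 <- t1_13c(ft, tum, n_h = 1, b0_proton_mhz = config$freq_1h_mhz,
                   r_ch = config$r_ch_nm, label = cb)
      t1s[[cb]] <- dplyr::bind_cols(tibble(carbon = cb), tidy(t1),
                                    glance(ft)[, c("s2", "tau1_ps", "tau2_ps")])
    }
    results$t1 <- dplyr::bind_rows(t1s)
    write.csv(results$t1, file.path(config$out_dir, "t1.csv"),
              row.names = FALSE)
    log_stage("t1", ts)
  }

  manifest <- .build_manifest(config)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[nanosite] pipeline done in %.2fs (%d stage(s))",
                  as.numeric(Sys.time() - t0, units = "secs"),
                  length(config$stages)))
  invisible(results)
}

.build_manifest <- function(config) {
  list(
    package = "nanosite",
    version = as.character(utils::packageVersion("nanosite")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      zn_zn_cut_nm = config$zn_zn_cut,
      o_zn_cut_nm = config$o_zn_cut,
      zn_water_cut_nm = config$zn_water_cut,
      hb_d_cut_nm = config$hb_d_cut,
      hb_angle_cut_deg = config$hb_angle_cut,
      dt_ps = config$dt,
      quantiles = config$quantiles,
      temperature_k = config$temperature_k,
      viscosity_pa_s = config$viscosity_pa_s,
      freq_1h_mhz = config$freq_1h_mhz,
      r_ch_nm = config$r_ch_nm
    ))
}

#' Write a result to CSV or JSON
#'
#' Schema-stable writers for pipeline results. Decay fits become JSON with
#' keys \code{N0}, \code{lambda_ns_inv}, \code{residual}; tibbles become CSV
#' with a header row; any list becomes JSON. JSON round-trips losslessly via
#' [jsonlite::read_json()].
#'
#' @param x Result object (tibble, decay fit, or list).
#' @param format \code{"csv"} or \code{"json"}.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, format = c("csv", "json"), path) {
  format <- match.arg(format)
  if (inherits(x, "nanosite_decay"))
    x <- list(N0 = x$n0, lambda_ns_inv = x$lambda, residual = x$residual_norm)
  if (format == "csv") {
    if (!is.data.frame(x))
      ns_abort("csv output requires a data frame", "io_error")
    ok <- tryCatch(suppressWarnings({
      write.csv(as.data.frame(x), path, row.names = FALSE); TRUE
    }), error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) ns_abort(paste0("cannot write ", path), "io_error")
  } else {
    ok <- tryCatch({
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) ns_abort(paste0("cannot write ", path), "io_error")
  }
  invisible(path)
}
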