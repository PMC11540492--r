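#' Scenario presets
#'
#' The four design scenarios for the electrified catheter, plus the
#' post-polarization relaxation run:
#' \describe{
#'   \item{S1}{working and counter electrodes in the hub only
#'     (d = 0.245 mm), 48 h at 1.5 / -0.6 V vs Ag/AgCl.}
#'   \item{S1-relax}{S1 followed by 120 h at open circuit.}
#'   \item{S2-1.7, S2-1.9}{as S1 with the working electrode at 1.7 or
#'     1.9 V.}
#'   \item{S3}{working electrode extended through the connectors and the
#'     full tube (d = 0.245 mm everywhere); counter electrode in the hub
#'     only; 1.5 V, 48 h.}
#'   \item{S4}{as S3 but with the wire surface area matched to the fluid
#'     volume: hub wire d = 0.615 mm, connector/tube wire d = 0.054 mm,
#'     giving equal wire-area/fluid-volume ratio in hub and tube.}
#' }
#'
#' @param name one of `"S1"`, `"S1-relax"`, `"S2-1.7"`, `"S2-1.9"`,
#'   `"S3"`, `"S4"`.
#' @return list of class `scenario`: `name`, `segments`, `schedule`,
#'   `times` (default snapshot times, s).
#' @export
scenario_preset <- function(name = c("S1", "S1-relax", "S2-1.7", "S2-1.9",
                                     "S3", "S4")) {
  name <- match.arg(name)
  h <- 3600
  pol <- function(t_end_h, we = 1.5)
    list(t_start = 0, t_end = t_end_h * h, we = we, ce = -0.6)
  segs <- switch(name,
    "S3" = default_segments(d_we_luer = 2.45e-4, d_we_tube = 2.45e-4),
    "S4" = default_segments(d_we_hub = 6.15e-4, d_we_luer = 0.54e-4,
                            d_we_tube = 0.54e-4),
    default_segments()
  )
  sched <- switch(name,
    "S1-relax" = polarization_schedule(list(
      pol(48),
      list(t_start = 48 * h, t_end = 168 * h, polarized = FALSE))),
    "S2-1.7" = polarization_schedule(list(pol(48, we = 1.7))),
    "S2-1.9" = polarization_schedule(list(pol(48, we = 1.9))),
    polarization_schedule(list(pol(48)))
  )
  times <- seq(0, sched$t_end[nrow(sched)], by = h)
  structure(list(name = name, segments = segs, schedule = sched,
                 times = times), class = "scenario")
}

#' Load and validate a model configuration file
#'
#' Reads a YAML configuration and merges it over the tabulated defaults.
#' Recognized top-level blocks: `scenario` (preset name used as the
#' base), `chemistry` (overrides in tabulated units, see
#' [chem_params()]), `electrodes` (`we`/`ce` blocks with `E0`, `i0`,
#' `alpha`, `potential`), `geometry` (list of segment blocks with
#' `name`, `length`, `diameter`, `temperature`, `d_we`, `d_ce`),
#' `initial` (`pH0`, `C_NaCl`), `schedule` (list of phases with
#' `t_start_h`, `t_end_h`, `we`, `ce` or `polarized: false`), `controls`
#' (`cells_per_segment`, `rtol`, `atol`). An empty file yields the full
#' default (S1) configuration.
#'
#' @param path path to a YAML file.
#' @return list of class `catheter_config` with fully resolved
#'   components: `segments`, `schedule`, `times`, `chem`, `we`, `ce`,
#'   `c0`, `controls`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("scenario", "chemistry", "electrodes", "geometry", "initial",
             "schedule", "controls")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown configuration blocks: ",
                            paste(unknown, collapse = ", "))
  base <- scenario_preset(if (is.null(cfg$scenario)) "S1" else cfg$scenario)

  segments <- base$segments
  if (!is.null(cfg$geometry)) {
    segments <- lapply(cfg$geometry, function(s) {
      need <- setdiff(c("name", "length", "diameter", "temperature"), names(s))
      if (length(need)) stop("geometry block missing fields: ",
                             paste(need, collapse = ", "))
      segment(s$name, s$length, s$diameter, s$temperature,
              d_we = if (is.null(s$d_we)) 0 else s$d_we,
              d_ce = if (is.null(s$d_ce)) 0 else s$d_ce)
    })
  }
  schedule <- base$schedule
  if (!is.null(cfg$schedule)) {
    schedule <- polarization_schedule(lapply(cfg$schedule, function(p) {
      pol <- if (!is.null(p$polarized)) p$polarized else TRUE
      list(t_start = p$t_start_h * 3600, t_end = p$t_end_h * 3600,
           we = p$we, ce = p$ce, polarized = pol)
    }))
  }
  chem <- chem_params(if (is.null(cfg$chemistry)) list() else cfg$chemistry)
  mk_el <- function(role, blk) {
    do.call(electrode_spec, c(list(role = role),
      blk[intersect(names(blk), c("E0", "i0", "alpha", "potential"))]))
  }
  we <- mk_el("working", cfg$electrodes$we)
  ce <- mk_el("counter", cfg$electrodes$ce)
  # potential overrides flow into the preset schedule (an explicit
  # schedule block keeps its own per-phase potentials)
  if (is.null(cfg$schedule)) {
    schedule$phi_we[schedule$polarized] <- we$potential
    schedule$phi_ce[schedule$polarized] <- ce$potential
  }
  init <- cfg$initial
  c0 <- initial_composition(
    pH0 = if (is.null(init$pH0)) 5.5 else init$pH0,
    C_NaCl = if (is.null(init$C_NaCl)) 154.04 else init$C_NaCl,
    Ka_H2O = chem$Ka_H2O)
  controls <- list(cells_per_segment = c(30, 5, 10, 200),
                   rtol = 1e-6, atol = 1e-9)
  if (!is.null(cfg$controls)) {
    unknown <- setdiff(names(cfg$controls), names(controls))
    if (length(unknown)) stop("unknown controls: ",
                              paste(unknown, collapse = ", "))
    controls[names(cfg$controls)] <- cfg$controls
  }
  structure(list(name = base$name, segments = segments, schedule = schedule,
                 times = seq(0, schedule$t_end[nrow(schedule)], by = 3600),
                 chem = chem, we = we, ce = ce, c0 = c0,
                 controls = controls),
            class = "catheter_config")
}

#' Run a scenario (preset name, scenario, or loaded configuration)
#'
#' Builds the grid, integrates the model through the scenario's
#' polarization schedule and, if `out_dir` is given, writes: tidy
#' compartment volume-average CSV, per-snapshot axial profile CSV
#' (species columns plus pH), a plain-text summary (extrema with
#' locations, compartment pH, total charge passed) and the conservation
#' audit.
#'
#' @param x scenario name (see [scenario_preset()]), a `scenario`, or a
#'   `catheter_config` from [load_config()].
#' @param out_dir optional output directory (created if missing).
#' @param cells_per_segment grid resolution (one count per segment).
#' @param rtol,atol solver tolerances.
#' @param times optional output times, s.
#' @return the `catheter_sim` result, with the summary attached as
#'   attribute `"summary"`.
#' @export
run_scenario <- function(x, out_dir = NULL,
                         cells_per_segment = c(30, 5, 10, 200),
                         rtol = 1e-6, atol = 1e-9, times = NULL) {
  if (is.character(x)) x <- scenario_preset(x)
  if (inherits(x, "catheter_config")) {
    cells_per_segment <- x$controls$cells_per_segment
    rtol <- x$controls$rtol; atol <- x$controls$atol
    cfg <- x
  } else if (inherits(x, "scenario")) {
    cfg <- list(name = x$name, segments = x$segments, schedule = x$schedule,
                times = x$times, chem = chem_params(),
                we = electrode_spec("working"), ce = electrode_spec("counter"),
                c0 = initial_composition())
  } else stop("x must be a scenario name, scenario, or catheter_config")

  grid <- catheter_grid(cfg$segments, cells_per_segment)
  res <- simulate_catheter(grid, cfg$schedule,
                           times = if (is.null(times)) cfg$times else times,
                           c0 = cfg$c0, chem = cfg$chem,
                           we = cfg$we, ce = cfg$ce,
                           rtol = rtol, atol = atol)
  summ <- scenario_summary(res)
  attr(res, "summary") <- summ
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tidy_volume_averages(res),
                     file.path(out_dir, "volume_averages.csv"),
                     row.names = FALSE)
    utils::write.csv(.profile_table(res),
                     file.path(out_dir, "profiles.csv"), row.names = FALSE)
    writeLines(.format_summary(cfg$name, summ),
               file.path(out_dir, "summary.txt"))
    aud <- conservation_audit(res)
    writeLines(c(sprintf("chlorine_drift %g", aud$chlorine_drift),
                 sprintf("sodium_drift %g", aud$sodium_drift),
                 sprintf("charge_residual_mol %g", aud$charge_residual_mol),
                 sprintf("flagged %s",
                         if (length(aud$flagged)) paste(aud$flagged, collapse = ",")
                         else "none")),
               file.path(out_dir, "audit.txt"))
  }
  res
}

# wide per-snapshot profile table: time_s, x_m, one column per species, pH
.profile_table <- function(res) {
  do.call(rbind, lapply(seq_along(res$times), function(m) {
    cm <- res$conc[, , m]
    df <- data.frame(time_s = res$times[m], x_m = res$grid$x,
                     compartment = res$grid$compartment)
    for (sp in species_names()) df[[sp]] <- cm[sp, ]
    df$pH <- ph_field(cm)
    df
  }))
}

#' Summary of a simulation run
#'
#' @param res a `catheter_sim`.
#' @return list: final-time domain extrema of HOCl, ClO2- and pH with
#'   axial locations, per-compartment final pH and HOCl volume averages,
#'   peak tube volume-average HOCl over time (value and time), and total
#'   charge passed at each electrode (C, trapezoidal).
#' @export
scenario_summary <- function(res) {
  t_fin <- res$times[length(res$times)]
  hocl <- field_extrema(res, "HOCl", t_fin)
  clo2 <- field_extrema(res, "ClO2", t_fin)
  ph <- field_extrema(res, "pH", t_fin)
  tube_ts <- volume_average(res, "tube", "HOCl")
  peak_i <- which.max(tube_ts$value)
  comps <- unique(res$grid$compartment)
  comp_tbl <- do.call(rbind, lapply(comps, function(cp) {
    data.frame(compartment = cp,
               HOCl_avg_mM = volume_average(res, cp, "HOCl", t_fin),
               pH_min = field_extrema(res, "pH", t_fin, cp)$min,
               pH_max = field_extrema(res, "pH", t_fin, cp)$max)
  }))
  tt <- res$currents$time_s
  n <- length(tt)
  trapz <- function(y) sum(diff(tt) * (y[-n] + y[-1]) / 2)
  list(t_final_s = t_fin, hocl = hocl, clo2 = clo2, pH = ph,
       compartments = comp_tbl,
       tube_peak_HOCl_mM = tube_ts$value[peak_i],
       tube_peak_time_h = tube_ts$time_s[peak_i] / 3600,
       charge_we_C = trapz(res$currents$I_we_A),
       charge_ce_C = trapz(res$currents$I_ce_A))
}

.format_summary <- function(name, s) {
  c(sprintf("scenario %s, t_final = %.1f h", name, s$t_final_s / 3600),
    sprintf("HOCl max %.4g mM at x = %.4f m; min %.4g mM", s$hocl$max,
            s$hocl$x_max, s$hocl$min),
    sprintf("ClO2- max %.4g mM at x = %.4f m", s$clo2$max, s$clo2$x_max),
    sprintf("pH min %.3f (x = %.4f m), max %.3f (x = %.4f m)",
            s$pH$min, s$pH$x_min, s$pH$max, s$pH$x_max),
    sprintf("tube volume-average HOCl peak %.4g mM at %.1f h",
            s$tube_peak_HOCl_mM, s$tube_peak_time_h),
    sprintf("charge passed: WE %.4g C, CE %.4g C", s$charge_we_C, s$charge_ce_C),
    "",
    utils::capture.output(print(s$compartments, row.names = FALSE)))
}
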