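#' Polarization schedule
#'
#' A run is a sequence of contiguous phases starting at t = 0; during a
#' polarized phase both electrodes are held at constant potential, during
#' an open-circuit phase all electrode fluxes are identically zero.
#'
#' @param phases list of phase descriptions, each a list with `t_start`,
#'   `t_end` (s), and either `we`/`ce` applied potentials (V vs Ag/AgCl)
#'   or `polarized = FALSE`.
#' @return data.frame of class `polarization_schedule` with columns
#'   `t_start`, `t_end`, `polarized`, `phi_we`, `phi_ce`.
#' @examples
#' # 48 h polarized then 120 h open circuit
#' polarization_schedule(list(
#'   list(t_start = 0, t_end = 48 * 3600, we = 1.5, ce = -0.6),
#'   list(t_start = 48 * 3600, t_end = 168 * 3600, polarized = FALSE)
#' ))
#' @export
polarization_schedule <- function(phases) {
  df <- do.call(rbind, lapply(phases, function(p) {
    pol <- if (!is.null(p$polarized)) p$polarized else TRUE
    data.frame(t_start = p$t_start, t_end = p$t_end, polarized = pol,
               phi_we = if (pol) p$we else NA_real_,
               phi_ce = if (pol) p$ce else NA_real_)
  }))
  if (df$t_start[1] != 0) stop("schedule must start at t = 0")
  if (any(df$t_end <= df$t_start)) stop("phases must have positive duration")
  if (nrow(df) > 1 && any(abs(df$t_start[-1] - df$t_end[-nrow(df)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  class(df) <- c("polarization_schedule", "data.frame")
  df
}

# Build the method-of-lines right-hand side as a closure over precomputed
# grid quantities. State ordering is species-fastest (cell-major), which
# keeps the Jacobian banded with half-bandwidth = n_species.
.make_rhs <- function(grid, chem, we, ce) {
  K <- grid$n_cells
  nm <- species_names()
  # face conductances from series diffusion resistance of the two half
  # cells, G[i, f] = 1 / (h_k/(A_k D_k) + h_k1/(A_k1 D_k1))  [m3/s];
  # exact for piecewise-constant area and diffusivity, second-order at
  # segment junctions
  h <- grid$dx / 2
  resist <- sweep(1 / grid$D[, -K, drop = FALSE], 2, h[-K] / grid$area[-K], "*") +
            sweep(1 / grid$D[, -1, drop = FALSE], 2, h[-1] / grid$area[-1], "*")
  G <- 1 / resist  # 10 x (K-1)
  kd <- .deg_constants_at(chem, grid$T)        # 4 x K
  s2v_we <- surface_to_volume(grid, "working")
  s2v_ce <- surface_to_volume(grid, "counter")
  we_cells <- which(grid$a_we > 0)
  ce_cells <- which(grid$a_ce > 0)
  Vrow <- matrix(rep(grid$V, each = 10), nrow = 10)
  Tk <- grid$T
  zero <- numeric(10)

  function(t, y, parms) {
    polarized <- parms$polarized
    cmat <- matrix(y, nrow = 10, dimnames = list(nm, NULL))
    # diffusion: J[i, f] > 0 flows from cell f to f+1 (mol/s)
    J <- G * (cmat[, -K, drop = FALSE] - cmat[, -1, drop = FALSE])
    dc <- (cbind(zero, J) - cbind(J, zero)) / Vrow
    # homogeneous chemistry
    hocl <- cmat[1, ]
    r_eq1 <- chem$ka * (hocl - cmat[2, ] * cmat[6, ] / chem$Ka_HOCl)
    r_eq2 <- chem$ka_star * (1 - cmat[8, ] * cmat[6, ] / chem$Ka_H2O)
    r_deg <- rbind(kd[1, ] * hocl, kd[2, ] * hocl * hocl,
                   kd[3, ] * hocl * cmat[3, ], kd[4, ] * hocl * cmat[2, ])
    dc <- dc + chem$S_eq %*% rbind(r_eq1, r_eq2) + chem$S_deg %*% r_deg
    # electrode sources on wire-bearing cells
    if (polarized) {
      st_we <- electrode_state(parms$we, cmat[, we_cells, drop = FALSE],
                               Tk[we_cells])
      dc[, we_cells] <- dc[, we_cells] +
        sweep(st_we$flux, 2, s2v_we[we_cells], "*")
      st_ce <- electrode_state(parms$ce, cmat[, ce_cells, drop = FALSE],
                               Tk[ce_cells])
      dc[, ce_cells] <- dc[, ce_cells] +
        sweep(st_ce$flux, 2, s2v_ce[ce_cells], "*")
    }
    if (anyNA(dc)) {
      bad <- which(is.na(dc), arr.ind = TRUE)[1, ]
      stop("NaN in rhs at t = ", t, " s, species ", nm[bad[1]],
           ", cell ", bad[2])
    }
    list(as.vector(dc))
  }
}

#' Evaluate the semi-discrete right-hand side once
#'
#' Computes dc/dt for a given concentration field: finite-volume
#' divergence of diffusive fluxes (variable cross-section, no-flux ends),
#' homogeneous chemistry at the local cell temperature, and — when
#' polarized — electrode surface fluxes mapped onto wire-bearing cells via
#' the wire area/volume density. Exposed mainly for verification; the
#' integrator uses the same code path.
#'
#' @param c concentration field, 10 x K matrix (mol/m3), species in
#'   canonical order.
#' @param grid a [catheter_grid()].
#' @param chem a [chem_params()].
#' @param we,ce [electrode_spec()]s (used when `polarized`).
#' @param polarized logical.
#' @return 10 x K matrix dc/dt, mol/(m3 s).
#' @export
assemble_rhs <- function(c, grid, chem = chem_params(),
                         we = electrode_spec("working"),
                         ce = electrode_spec("counter"),
                         polarized = TRUE) {
  cm <- .as_cmat(c)
  if (ncol(cm) != grid$n_cells) stop("field has ", ncol(cm),
                                     " cells, grid has ", grid$n_cells)
  rhs <- .make_rhs(grid, chem, we, ce)
  out <- matrix(rhs(0, as.vector(cm),
                    list(polarized = polarized, we = we, ce = ce))[[1]],
                nrow = 10, dimnames = list(species_names(), NULL))
  out
}

#' Integrate the reaction-transport model through a polarization schedule
#'
#' Runs the stiff method-of-lines integration (backward-differentiation
#' formulas with a banded internally-generated Jacobian) over all phases
#' of the schedule. Phase boundaries are hard restarts. Concentration
#' snapshots, electrode currents and conservation totals are recorded at
#' the requested output times.
#'
#' @param grid a [catheter_grid()].
#' @param schedule a [polarization_schedule()].
#' @param times output times, s; must start at 0 and lie within the
#'   schedule. Default: hourly over the schedule.
#' @param c0 initial composition, named vector of length 10 (mol/m3),
#'   applied uniformly; default [initial_composition()].
#' @param chem a [chem_params()].
#' @param we,ce [electrode_spec()]s; applied potentials are overridden
#'   per-phase by the schedule.
#' @param rtol,atol solver tolerances (relative; absolute in mol/m3).
#' @param maxsteps maximum internal steps per output interval.
#' @return object of class `catheter_sim`: list with `times` (s), `conc`
#'   (10 x K x n_times array, mol/m3), `grid`, `schedule`, `currents`
#'   (data.frame: time_s, I_we_A, I_ce_A), `chem`, `electrodes`.
#' @export
simulate_catheter <- function(grid,
                              schedule = polarization_schedule(list(
                                list(t_start = 0, t_end = 48 * 3600,
                                     we = 1.5, ce = -0.6))),
                              times = NULL,
                              c0 = initial_composition(),
                              chem = chem_params(),
                              we = electrode_spec("working"),
                              ce = electrode_spec("counter"),
                              rtol = 1e-6, atol = 1e-9,
                              maxsteps = 50000) {
  t_end <- schedule$t_end[nrow(schedule)]
  if (is.null(times)) times <- seq(0, t_end, by = 3600)
  times <- sort(unique(times))
  if (times[1] != 0 || times[length(times)] > t_end + 1e-9)
    stop("output times must start at 0 and lie within the schedule")
  K <- grid$n_cells
  y <- as.vector(matrix(rep(as.numeric(c0[species_names()]), K), nrow = 10))
  rhs <- .make_rhs(grid, chem, we, ce)
  conc <- array(NA_real_, c(10, K, length(times)),
                dimnames = list(species_names(), NULL, NULL))
  stored <- logical(length(times))

  for (ph in seq_len(nrow(schedule))) {
    p0 <- schedule$t_start[ph]; p1 <- schedule$t_end[ph]
    pol <- schedule$polarized[ph]
    we_ph <- we; ce_ph <- ce
    if (pol) {
      we_ph$potential <- schedule$phi_we[ph]
      ce_ph$potential <- schedule$phi_ce[ph]
    }
    sel <- which(times >= p0 - 1e-9 & times <= p1 + 1e-9)
    tt <- sort(unique(c(p0, times[sel], p1)))
    sol <- deSolve::ode(y = y, times = tt, func = rhs,
                        parms = list(polarized = pol, we = we_ph, ce = ce_ph),
                        method = "lsode", jactype = "bandint",
                        bandup = 10L, banddown = 10L,
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
    if (attr(sol, "istate")[1] < 0)
      stop("stiff integration failed in phase ", ph, " (t = ", p0, "..", p1,
           " s, polarized = ", pol, "); consider loosening rtol/atol")
    for (m in sel) {
      row <- which(abs(sol[, 1] - times[m]) <= 1e-6 * max(1, times[m]))[1]
      conc[, , m] <- matrix(sol[row, -1], nrow = 10)
      stored[m] <- TRUE
    }
    y <- as.numeric(sol[nrow(sol), -1])
    neg <- min(y)
    if (neg < -10 * atol)
      stop("persistent negative concentration (", signif(neg, 3),
           " mol/m3) at end of phase ", ph)
  }
  if (!all(stored)) stop("internal error: missing snapshots")

  res <- structure(list(times = times, conc = conc, grid = grid,
                        schedule = schedule, chem = chem,
                        electrodes = list(we = we, ce = ce),
                        controls = list(rtol = rtol, atol = atol)),
                   class = "catheter_sim")
  res$currents <- .electrode_currents(res)
  res
}

# total electrode currents (A) at every snapshot
.electrode_currents <- function(res) {
  g <- res$grid
  out <- data.frame(time_s = res$times, I_we_A = 0, I_ce_A = 0)
  for (m in seq_along(res$times)) {
    ph <- .phase_at(res$schedule, res$times[m])
    if (!res$schedule$polarized[ph]) next
    cm <- res$conc[, , m]
    for (el in c("we", "ce")) {
      cells <- if (el == "we") which(g$a_we > 0) else which(g$a_ce > 0)
      if (!length(cells)) next
      spec <- res$electrodes[[el]]
      spec$potential <- res$schedule[[paste0("phi_", el)]][ph]
      st <- electrode_state(spec, cm[, cells, drop = FALSE], g$T[cells])
      a <- if (el == "we") g$a_we[cells] else g$a_ce[cells]
      out[[paste0("I_", el, "_A")]][m] <- sum(st$i * a)
    }
  }
  out
}

# phase index containing time t (boundaries resolve to the later phase,
# matching the hard-restart semantics)
.phase_at <- function(schedule, t) {
  ph <- findInterval(t, schedule$t_start)
  max(1, min(ph, nrow(schedule)))
}

#' @export
print.catheter_sim <- function(x, ...) {
  cat("catheter simulation:", x$grid$n_cells, "cells,",
      length(x$times), "snapshots, t =", format(max(x$times) / 3600),
      "h\n")
  tmax <- length(x$times)
  cat(sprintf("  final domain max HOCl: %.4g mM, pH range %.2f .. %.2f\n",
              max(x$conc["HOCl", , tmax]),
              min(ph_field(x$conc[, , tmax])),
              max(ph_field(x$conc[, , tmax]))))
  invisible(x)
}

#' Compartment volume-average concentration
#'
#' Volume-weighted mean concentration over the cells of one compartment
#' (or the whole catheter), at one snapshot or as a time series.
#'
#' @param result a `catheter_sim`.
#' @param compartment a compartment label (`"hub"`, `"luer_top"`,
#'   `"luer_bottom"`, `"tube"`) or `"all"`.
#' @param species species name.
#' @param t snapshot time, s; omit for the full time series.
#' @return scalar (mol/m3) or a data.frame (time_s, value).
#' @export
volume_average <- function(result, compartment, species, t = NULL) {
  g <- result$grid
  cells <- if (identical(compartment, "all")) seq_len(g$n_cells)
           else which(g$compartment == compartment)
  if (!length(cells)) stop("unknown compartment: ", compartment)
  i <- .sp_idx(species)
  V <- g$V[cells]
  avg <- apply(result$conc[i, cells, , drop = FALSE], 3,
               function(cc) sum(cc * V) / sum(V))
  if (is.null(t)) return(data.frame(time_s = result$times, value = avg))
  m <- which(abs(result$times - t) <= 1e-6 * max(1, t))
  if (!length(m)) stop("t = ", t, " s is not a snapshot time")
  avg[m[1]]
}

#' pH field from a concentration state
#'
#' pH = -log10(c_H+ / 1000) with c_H+ in mol/m3 (i.e. pH of the molar
#' concentration), floored at the package-wide trace concentration.
#'
#' @param c a composition (named vector) or a 10 x K concentration matrix.
#' @return pH, scalar or vector over cells.
#' @examples
#' ph_field(initial_composition(5.5, 154.04))  # 5.5
#' @export
ph_field <- function(c) {
  cm <- .as_cmat(c)
  unname(-log10(pmax(cm["H", ], .EPS_C) / 1000))
}

#' Domain extrema of a species (or pH) at a snapshot
#'
#' @param result a `catheter_sim`.
#' @param species species name, or `"pH"`.
#' @param t snapshot time, s.
#' @param compartment optional compartment restriction.
#' @return list with `min`, `max`, `x_min`, `x_max` (axial locations, m).
#' @export
field_extrema <- function(result, species, t, compartment = NULL) {
  m <- which(abs(result$times - t) <= 1e-6 * max(1, t))
  if (!length(m)) stop("t = ", t, " s is not a snapshot time")
  g <- result$grid
  cells <- if (is.null(compartment)) seq_len(g$n_cells)
           else which(g$compartment == compartment)
  if (!length(cells)) stop("unknown compartment: ", compartment)
  v <- if (identical(species, "pH")) ph_field(result$conc[, , m[1]])[cells]
       else result$conc[.sp_idx(species), cells, m[1]]
  list(min = min(v), max = max(v),
       x_min = g$x[cells[which.min(v)]], x_max = g$x[cells[which.max(v)]])
}

#' Volume-weighted total moles of a species at every snapshot
#' @param result a `catheter_sim`.
#' @param species species name.
#' @return numeric vector over snapshots, mol.
#' @export
total_moles <- function(result, species) {
  i <- .sp_idx(species)
  apply(result$conc[i, , , drop = FALSE], 3,
        function(cc) sum(cc * result$grid$V))
}

#' Tidy long-format volume averages for all compartments and species
#' @param result a `catheter_sim`.
#' @return data.frame (time_s, compartment, species, volume_avg_mol_m3).
#' @export
tidy_volume_averages <- function(result) {
  comps <- unique(result$grid$compartment)
  do.call(rbind, lapply(comps, function(cp) {
    do.call(rbind, lapply(species_names(), function(sp) {
      ts <- volume_average(result, cp, sp)
      data.frame(time_s = ts$time_s, compartment = cp, species = sp,
                 volume_avg_mol_m3 = ts$value)
    }))
  }))
}
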