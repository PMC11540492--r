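#' Semi-infinite diffusion reference solution
#'
#' Closed-form solution of pure one-dimensional diffusion into a
#' semi-infinite medium held at `c_left` on the boundary:
#' c(x, t) = c_left * erfc(x / (2 sqrt(D t))). Used as an independent
#' analytic oracle for the transport discretization with chemistry and
#' electrodes switched off, before the far boundary is felt.
#'
#' @param D diffusion coefficient, m2/s.
#' @param c_left boundary concentration, mol/m3.
#' @param x distance from the boundary, m (vectorized).
#' @param t time, s (> 0).
#' @return concentration, mol/m3.
#' @export
erfc_diffusion_reference <- function(D, c_left, x, t) {
  if (t <= 0) stop("t must be positive")
  c_left * pracma::erfc(x / (2 * sqrt(D * t)))
}

#' Brute-force well-mixed chemistry oracle
#'
#' Integrates the homogeneous chemistry (equilibria + degradation) in a
#' well-mixed volume with a deliberately naive fixed-step classical
#' Runge-Kutta scheme, halving the step until two successive refinements
#' agree to `tol` in relative terms. Independent of the stiff
#' method-of-lines solver; used only for oracle-equivalence tests.
#'
#' Note the kinetically-relaxed equilibria make the system stiff
#' (relaxation rates of order ka c_H / Ka); explicit integration then
#' needs very small steps, so keep `t_end` short or pass a reduced
#' `chem` when the equilibria are active.
#'
#' @param c0 initial composition, named vector (mol/m3).
#' @param T absolute temperature, K.
#' @param t_end end time, s.
#' @param chem a [chem_params()].
#' @param include character subset of `c("equilibria", "degradation")`.
#' @param dt0 initial step, s.
#' @param tol relative agreement between refinements.
#' @param max_halvings refinement limit.
#' @return named composition at `t_end` (mol/m3).
#' @export
batch_chemistry_oracle <- function(c0, T, t_end,
                                   chem = chem_params(),
                                   include = c("equilibria", "degradation"),
                                   dt0 = t_end / 256, tol = 1e-8,
                                   max_halvings = 24) {
  if (t_end <= 0) stop("t_end must be positive")
  include <- match.arg(include, several.ok = TRUE)
  kd <- drop(.deg_constants_at(chem, T))
  f <- function(c) {
    r <- numeric(10)
    if ("equilibria" %in% include) {
      r1 <- chem$ka * (c[1] - c[2] * c[6] / chem$Ka_HOCl)
      r2 <- chem$ka_star * (1 - c[8] * c[6] / chem$Ka_H2O)
      r <- r + drop(chem$S_eq %*% c(r1, r2))
    }
    if ("degradation" %in% include) {
      rd <- c(kd[1] * c[1], kd[2] * c[1]^2, kd[3] * c[1] * c[3],
              kd[4] * c[1] * c[2])
      r <- r + drop(chem$S_deg %*% rd)
    }
    r
  }
  run <- function(n) {
    h <- t_end / n
    c <- as.numeric(c0[species_names()])
    for (s in seq_len(n)) {
      k1 <- f(c)
      k2 <- f(c + h / 2 * k1)
      k3 <- f(c + h / 2 * k2)
      k4 <- f(c + h * k3)
      c <- c + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(c))) stop("oracle diverged; reduce the step")
    }
    c
  }
  n <- max(2, ceiling(t_end / dt0))
  prev <- run(n)
  for (j in seq_len(max_halvings)) {
    n <- 2 * n
    cur <- run(n)
    scale <- pmax(abs(cur), 1e-12)
    if (max(abs(cur - prev) / scale) < tol)
      return(stats::setNames(cur, species_names()))
    prev <- cur
  }
  stop("oracle did not converge within ", max_halvings, " halvings")
}

#' Conservation and charge-bookkeeping audit of a simulation
#'
#' Checks, across all snapshots of a run: (i) relative drift of total
#' chlorine atoms (electrode and homogeneous reactions only interconvert
#' chlorine species, nothing leaves the catheter); (ii) relative drift of
#' total Na+ (fully inert); (iii) the charge ledger — the change in total
#' ionic charge between snapshots against the time integral of
#' (I_we + I_ce)/F (trapezoidal on the recorded currents).
#'
#' @param result a `catheter_sim` with at least 2 snapshots.
#' @param drift_tol relative drift above which a quantity is flagged.
#' @return list of class `conservation_audit`: `chlorine_drift`,
#'   `sodium_drift`, `charge_residual_mol`, `charge_scale_mol`, `flagged`
#'   (character vector of failing checks).
#' @export
conservation_audit <- function(result, drift_tol = 1e-4) {
  if (length(result$times) < 2) stop("need at least 2 snapshots")
  sp <- species_set()
  cl_species <- sp$name[sp$cl_atoms > 0]
  cl_tot <- Reduce(`+`, lapply(cl_species, function(s) total_moles(result, s)))
  na_tot <- total_moles(result, "Na")
  cl_drift <- max(abs(cl_tot - cl_tot[1])) / cl_tot[1]
  na_drift <- max(abs(na_tot - na_tot[1])) / na_tot[1]
  # charge ledger
  z <- sp$charge
  q <- vapply(seq_along(result$times), function(m)
    sum((z %*% result$conc[, , m]) * result$grid$V), numeric(1))
  I_sum <- result$currents$I_we_A + result$currents$I_ce_A
  tt <- result$times
  n <- length(I_sum)
  q_pred <- q[1] + cumsum(c(0, diff(tt) * (I_sum[-n] + I_sum[-1]) / 2)) / .FARADAY
  charge_resid <- max(abs(q - q_pred))
  charge_scale <- max(abs(q - q[1]), 1e-12)
  flagged <- character(0)
  if (cl_drift > drift_tol) flagged <- c(flagged, "chlorine")
  if (na_drift > drift_tol) flagged <- c(flagged, "sodium")
  structure(list(chlorine_drift = cl_drift, sodium_drift = na_drift,
                 charge_residual_mol = charge_resid,
                 charge_scale_mol = charge_scale, flagged = flagged),
            class = "conservation_audit")
}

#' @export
print.conservation_audit <- function(x, ...) {
  cat("conservation audit\n")
  cat(sprintf("  chlorine drift : %.3e relative%s\n", x$chlorine_drift,
              if ("chlorine" %in% x$flagged) "  ** FLAGGED **" else ""))
  cat(sprintf("  sodium drift   : %.3e relative%s\n", x$sodium_drift,
              if ("sodium" %in% x$flagged) "  ** FLAGGED **" else ""))
  cat(sprintf("  charge ledger  : residual %.3e mol (scale %.3e mol)\n",
              x$charge_residual_mol, x$charge_scale_mol))
  invisible(x)
}
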