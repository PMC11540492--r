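#' Catheter segment description
#'
#' One axial segment of the catheter (hub, Luer-lock top, Luer-lock
#' bottom, or tube), modelled as a straight cylinder at a fixed
#' temperature, optionally threaded by working and/or counter electrode
#' wires whose lateral surface carries the electrochemistry.
#'
#' @param name segment label, also the compartment label used in reports.
#' @param length axial length, m.
#' @param diameter lumen inner diameter, m.
#' @param temperature absolute temperature, K.
#' @param d_we,d_ce working / counter electrode wire diameter in this
#'   segment, m (0 when the wire does not reach this segment).
#' @return list of class `segment`.
#' @export
segment <- function(name, length, diameter, temperature,
                    d_we = 0, d_ce = 0) {
  if (length <= 0) stop("segment '", name, "': length must be positive")
  if (diameter <= 0) stop("segment '", name, "': diameter must be positive")
  if (temperature <= 0) stop("segment '", name, "': temperature must be positive")
  if (d_we < 0 || d_ce < 0) stop("segment '", name, "': wire diameters must be >= 0")
  if (pi / 4 * (d_we^2 + d_ce^2) >= pi / 4 * diameter^2)
    stop("segment '", name, "': wires fill the lumen")
  structure(list(name = name, length = length, diameter = diameter,
                 temperature = temperature, d_we = d_we, d_ce = d_ce),
            class = "segment")
}

#' Default hub/Luer/tube segment stack
#'
#' Hub 32.6 mm x 5.4 mm with both electrode wires (0.245 mm); Luer top
#' 6.4 mm x 4.0 mm; Luer bottom 12.2 mm x 1.6 mm; tube 300 mm x 1.6 mm.
#' Total length 0.3512 m. Hub and connectors at 25 C, tube at body
#' temperature 37 C.
#'
#' @param d_we_hub,d_we_luer,d_we_tube working-electrode wire diameter (m)
#'   in the hub, the two Luer segments, and the tube; the defaults place
#'   the working electrode in the hub only.
#' @param d_ce_hub counter-electrode wire diameter in the hub (m); the
#'   counter electrode never extends beyond the hub.
#' @return list of four [segment()] objects.
#' @export
default_segments <- function(d_we_hub = 2.45e-4, d_we_luer = 0,
                             d_we_tube = 0, d_ce_hub = 2.45e-4) {
  list(
    segment("hub",         3.26e-2, 5.4e-3, 298.15, d_we = d_we_hub, d_ce = d_ce_hub),
    segment("luer_top",    6.4e-3,  4.0e-3, 298.15, d_we = d_we_luer),
    segment("luer_bottom", 1.22e-2, 1.6e-3, 298.15, d_we = d_we_luer),
    segment("tube",        0.3,     1.6e-3, 310.15, d_we = d_we_tube)
  )
}

#' Temperature scaling of an aqueous diffusion coefficient
#'
#' D(T) = D(298 K) * (T / 298 K)^(3/2).
#'
#' @param D298 diffusion coefficient at 298 K, m2/s.
#' @param T absolute temperature, K.
#' @return diffusion coefficient at `T`, m2/s.
#' @examples
#' diffusivity_at(1.14e-9, 310.15)
#' @export
diffusivity_at <- function(D298, T) {
  if (any(T <= 0)) stop("temperature must be positive")
  D298 * (T / 298)^1.5
}

#' Build the discretized axial grid
#'
#' Reduces the catheter to a one-dimensional finite-volume grid with
#' variable fluid cross-section: each cell's fluid volume is its lumen
#' cross-section minus the wire cross-sections, times its width; wire
#' lateral area per cell is pi d_wire dx; the face area at a segment
#' junction is the smaller of the two adjoining fluid cross-sections (no
#' flaring). Per-cell diffusivities are the 298 K values scaled to the
#' segment temperature.
#'
#' @param segments ordered list of [segment()]s (top of the hub is x = 0).
#' @param cells_per_segment integer vector, one entry (>= 2) per segment.
#'   Default 30/5/10/200, about 245 cells for the default stack.
#' @param species a [species_set()].
#' @return list of class `catheter_grid`: `x` (cell centers, m), `dx`,
#'   `area` (fluid cross-section, m2), `V` (fluid volume, m3), `A_face`
#'   (interior face areas, m2), `T` (K), `compartment` (labels), `a_we`,
#'   `a_ce` (wire lateral areas, m2), `D` (10 x K diffusivity matrix,
#'   m2/s), `L_total` (m).
#' @examples
#' g <- catheter_grid(default_segments(), c(6, 2, 3, 20))
#' sum(g$dx)  # 0.3512
#' @export
catheter_grid <- function(segments,
                          cells_per_segment = c(30, 5, 10, 200),
                          species = species_set()) {
  if (length(cells_per_segment) != length(segments))
    stop("need one cell count per segment")
  if (any(cells_per_segment < 2)) stop("at least 2 cells per segment")
  x <- dx <- area <- Tk <- a_we <- a_ce <- numeric(0)
  comp <- character(0)
  x0 <- 0
  for (j in seq_along(segments)) {
    s <- segments[[j]]
    n <- cells_per_segment[j]
    h <- s$length / n
    A <- pi / 4 * (s$diameter^2 - s$d_we^2 - s$d_ce^2)
    x   <- c(x, x0 + (seq_len(n) - 0.5) * h)
    dx  <- c(dx, rep(h, n))
    area <- c(area, rep(A, n))
    Tk  <- c(Tk, rep(s$temperature, n))
    a_we <- c(a_we, rep(pi * s$d_we * h, n))
    a_ce <- c(a_ce, rep(pi * s$d_ce * h, n))
    comp <- c(comp, rep(s$name, n))
    x0 <- x0 + s$length
  }
  K <- length(x)
  A_face <- pmin(area[-K], area[-1])
  D <- outer(species$D298, rep(1, K)) * rep(diffusivity_at(1, Tk), each = 10)
  rownames(D) <- species$name
  g <- list(x = x, dx = dx, area = area, V = area * dx, A_face = A_face,
            T = Tk, compartment = comp, a_we = a_we, a_ce = a_ce,
            D = D, L_total = x0, n_cells = K)
  class(g) <- "catheter_grid"
  g
}

#' @export
print.catheter_grid <- function(x, ...) {
  cat("catheter grid:", x$n_cells, "cells over", format(x$L_total), "m\n")
  for (cp in unique(x$compartment)) {
    k <- x$compartment == cp
    cat(sprintf("  %-12s %3d cells, V = %.3e m3, T = %.2f K\n",
                cp, sum(k), sum(x$V[k]), x$T[k][1]))
  }
  invisible(x)
}

#' Wire surface-area density per cell
#'
#' Ratio of electrode wire lateral area to fluid volume, per cell (1/m).
#' Converts a surface flux (mol/(m2 s)) into a volumetric source
#' (mol/(m3 s)) on wire-bearing cells; zero elsewhere.
#'
#' @param grid a [catheter_grid()].
#' @param role `"working"` or `"counter"`.
#' @return numeric vector over cells, 1/m.
#' @export
surface_to_volume <- function(grid, role = c("working", "counter")) {
  role <- match.arg(role)
  a <- if (role == "working") grid$a_we else grid$a_ce
  a / grid$V
}
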