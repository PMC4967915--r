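# helper: a circle of pseudo-atoms at radius rho, height z
.ring_atoms <- function(rho, z, spacing, phase = 0) {
  if (rho <= 0) return(cbind(x = 0, y = 0, z = z))
  n <- max(6L, ceiling(2 * pi * rho / spacing))
  th <- phase + 2 * pi * seq_len(n) / n
  cbind(x = rho * cos(th), y = rho * sin(th), z = z)
}

# helper: a filled disk (annulus) of pseudo-atoms
.disk_atoms <- function(rho_in, rho_out, z, spacing) {
  rings <- seq(max(rho_in, 0), rho_out, by = spacing)
  do.call(rbind, lapply(seq_along(rings), function(i) {
    .ring_atoms(rings[i], z, spacing, phase = i * 0.5)
  }))
}

#' Build a toy calyx structure with an analytically known cavity
#'
#' Constructs a pseudo-atom beta-barrel stand-in: a cylindrical cavity of
#' radius `cavity_radius` and height `cavity_depth` enclosed by carbon
#' walls and caps, with two "gate" tyrosine residues (numbers 102 and
#' 147) facing each other across the cavity mid-plane at a controllable
#' gap.  Wall atom centres sit at `cavity_radius + r_C + probe` from the
#' axis so the probe-inflated surface coincides with the analytic
#' cylinder; the analytic cavity volume pi r^2 depth is attached as the
#' `analytic_volume` attribute.
#'
#' By default the gate is fully retracted (`gate_gap = 2 *
#' (cavity_radius + r_C + probe)`): the gate tips sit in the wall ring
#' and the cavity is the plain cylinder, so the analytic volume is exact.
#' Smaller gaps move the tips inward and add a constriction ring at the
#' mid-plane; `gate_gap = 0` seals the lower chamber completely.  At
#' intermediate gaps the protruding tips occlude part of the cylinder,
#' so the analytic value is exact only at the extremes.
#'
#' @param n_strands number of wall "strands" (>= 6; wall atoms are
#'   assigned round-robin to strand residues).
#' @param cavity_radius cavity radius in Angstrom (>= `probe`).
#' @param cavity_depth cavity height in Angstrom.
#' @param gate_gap distance between the two gate tip atoms in Angstrom;
#'   `NULL` (default) fully retracts the gate.
#' @param probe probe radius the fixture is built for (default 1.4).
#' @param wall_spacing atom spacing in the walls (default 1.0; must stay
#'   below `2 * probe` for a probe-tight wall).
#' @return a `calyx_structure` with attributes `analytic_volume`
#'   (Angstrom^3), `gate` (a [gate_spec()] oriented upper side up),
#'   `upper_seed` and `lower_seed` (coordinates inside the two
#'   chambers).
#' @export
make_toy_calyx <- function(n_strands = 8, cavity_radius = 4,
                           cavity_depth = 10, gate_gap = NULL, probe = 1.4,
                           wall_spacing = 1.0) {
  r_c <- vdw_radii()[["C"]]
  a_wall <- r_c + probe
  R0 <- cavity_radius + a_wall
  if (n_strands < 6) stop("'n_strands' must be at least 6")
  if (cavity_radius < probe) stop("'cavity_radius' must be >= the probe radius")
  if (cavity_depth <= 0) stop("'cavity_depth' must be positive")
  if (is.null(gate_gap)) gate_gap <- 2 * R0
  if (gate_gap < 0 || gate_gap > 2 * R0) {
    stop("'gate_gap' must lie in [0, ", format(2 * R0), "] (self-intersecting geometry)")
  }
  z_mid <- cavity_depth / 2

  wall <- do.call(rbind, lapply(seq(0, cavity_depth, by = wall_spacing),
                                function(z) {
    .ring_atoms(R0, z, wall_spacing, phase = z)
  }))
  bottom <- .disk_atoms(0, R0, -a_wall, wall_spacing)
  top <- .disk_atoms(0, R0, cavity_depth + a_wall, wall_spacing)
  rho_ring <- gate_gap / 2 + a_wall
  gate_ring <- if (rho_ring < R0 - wall_spacing / 2) {
    .disk_atoms(rho_ring, R0 - wall_spacing / 2, z_mid, wall_spacing)
  } else NULL

  n_wall <- nrow(wall)
  blocks <- list(
    data.frame(name = "C", element = "C", resid = "WAL",
               resno = 1L + (seq_len(n_wall) %% n_strands),
               wall, stringsAsFactors = FALSE),
    data.frame(name = "C", element = "C", resid = "CAP",
               resno = 200L, rbind(bottom, top), stringsAsFactors = FALSE)
  )
  if (!is.null(gate_ring)) {
    blocks <- c(blocks, list(
      data.frame(name = "C", element = "C", resid = "GAT", resno = 201L,
                 gate_ring, stringsAsFactors = FALSE)))
  }
  # the two gate tyrosines: OH tip atoms facing each other across the
  # mid-plane, CZ anchors slightly outward
  tips <- data.frame(
    name = c("OH", "CZ", "OH", "CZ"),
    element = c("O", "C", "O", "C"),
    resid = "TYR", resno = c(102L, 102L, 147L, 147L),
    x = c(gate_gap / 2, gate_gap / 2 + 1.4, -gate_gap / 2, -gate_gap / 2 - 1.4),
    y = 0, z = z_mid, stringsAsFactors = FALSE)
  blocks <- c(blocks, list(tips))
  atoms <- do.call(rbind, blocks)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- "A"
  atoms$insert <- ""
  atoms$occ <- 1
  st <- new_structure(atoms)
  attr(st, "analytic_volume") <- pi * cavity_radius^2 * cavity_depth
  attr(st, "gate") <- gate_spec(residues = c(102, 147),
                                up_point = c(0, 0, 0.75 * cavity_depth))
  # suggested flood-fill seeds: clear of the gate tips' inflated spheres
  # (radius r_O + probe around the mid-plane) and of the caps
  tip_clear <- vdw_radii()[["O"]] + probe + 1
  attr(st, "upper_seed") <- c(0, 0, min(cavity_depth - 1, z_mid + tip_clear))
  attr(st, "lower_seed") <- c(0, 0, max(1, z_mid - tip_clear))
  st
}
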