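# 26 lattice ray directions (all nonzero offsets in {-1,0,1}^3)
.ray_dirs <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# shift a 3-D logical array by an integer offset, filling with FALSE
.shift3 <- function(A, s) {
  d <- dim(A)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) + s[k]
    i[i >= 1 & i <= d[k]]
  })
  dst <- lapply(1:3, function(k) src[[k]] - s[k])
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

# mark grid cells within (radius_i + pad) of any atom centre
.block_mask <- function(dims, origin, spacing, coords, radii, pad) {
  M <- array(FALSE, dims)
  for (k in seq_len(nrow(coords))) {
    r <- radii[k] + pad
    lo <- pmax(1, ceiling((coords[k, ] - r - origin) / spacing) + 1)
    hi <- pmin(dims, floor((coords[k, ] + r - origin) / spacing) + 1)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    px <- origin[1] + (ix - 1) * spacing - coords[k, 1]
    py <- origin[2] + (iy - 1) * spacing - coords[k, 2]
    pz <- origin[3] + (iz - 1) * spacing - coords[k, 3]
    d2 <- outer(outer(px^2, py^2, `+`), pz^2, `+`)
    sub <- M[ix, iy, iz, drop = FALSE]
    M[ix, iy, iz] <- array(sub | (d2 <= r^2), dim(d2))
  }
  M
}

#' Cavity volume configuration
#'
#' @param grid grid spacing in Angstrom (default 0.5).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param buriedness_rays number of ray directions (26, the full cubic
#'   lattice star; the only supported value).
#' @param buriedness_min minimum number of rays that must hit protein for
#'   a point to count as buried (default 18).
#' @param buriedness_cutoff ray length in Angstrom (default 12).
#' @param seed_point optional length-3 cavity seed coordinate; defaults
#'   to the gate-plane midpoint.
#' @param max_points flood-fill hard cap; exceeding it means the pocket
#'   is open to solvent (default 2e6).
#' @return object of class `cavity_config`.
#' @export
cavity_config <- function(grid = 0.5, probe = 1.4, buriedness_rays = 26,
                          buriedness_min = 18, buriedness_cutoff = 12,
                          seed_point = NULL, max_points = 2e6) {
  stopifnot(grid > 0, probe >= 0, buriedness_min >= 0,
            buriedness_min <= buriedness_rays, buriedness_cutoff > 0)
  if (buriedness_rays != 26) {
    stop("only the 26-direction lattice ray set is supported")
  }
  structure(list(grid = grid, probe = probe, buriedness_rays = 26,
                 buriedness_min = buriedness_min,
                 buriedness_cutoff = buriedness_cutoff,
                 seed_point = seed_point, max_points = max_points),
            class = "cavity_config")
}

#' Grid-based cavity volumes split at the gate plane
#'
#' Counts grid points that are (i) outside every probe-inflated atom
#' sphere, (ii) buried -- at least `buriedness_min` of 26 lattice ray
#' directions hit protein within the cutoff -- and (iii) 26-connected to
#' the seed point by flood fill.  The volume is the point count times the
#' grid cell volume; points are partitioned into the upper and lower
#' sub-pocket by the gate plane, so `total = upper + lower` exactly in
#' point counts.  For a holo structure the ligand (and waters) should be
#' excluded via `exclude_resid` so the pocket it occupies is measured.
#'
#' @param structure a `calyx_structure`.
#' @param gate a [gate_spec()].
#' @param config a [cavity_config()].
#' @param exclude_resid residue names excluded from the occupancy test
#'   (e.g. `c("S1P", "HOH")`).
#' @param model model index.
#' @return object of class `cavity_result`: `total`, `upper`, `lower`
#'   (Angstrom^3), `n_points` (named counts), `grid`, `probe`, `plane`.
#' @export
cavity_volumes <- function(structure, gate = gate_spec(),
                           config = cavity_config(),
                           exclude_resid = character(0), model = 1) {
  stopifnot(inherits(structure, "calyx_structure"),
            inherits(config, "cavity_config"))
  a <- structure$atoms
  co <- structure_coords(structure, model)
  keep <- !(a$resid %in% exclude_resid) & a$element != "H"
  coords <- co[keep, , drop = FALSE]
  radii <- a$radius[keep]
  gm <- gate_metrics(structure, gate, model)
  plane <- gm$plane

  h <- config$grid
  margin <- max(radii) + config$probe + 2 * h
  origin <- apply(coords, 2, min) - margin
  upper_c <- apply(coords, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((upper_c - origin) / h)) + 1L)

  blocked <- .block_mask(dims, origin, h, coords, radii, config$probe)
  free <- !blocked
  occ <- .block_mask(dims, origin, h, coords, radii, 0)

  # buriedness: count ray directions that hit protein within the cutoff
  hits <- array(0L, dims)
  for (d in seq_len(nrow(.ray_dirs))) {
    dir <- .ray_dirs[d, ]
    steplen <- h * sqrt(sum(dir^2))
    K <- max(1L, floor(config$buriedness_cutoff / steplen))
    hit <- array(FALSE, dims)
    for (k in seq_len(K)) hit <- hit | .shift3(occ, k * dir)
    hits <- hits + hit
  }
  candidate <- free & (hits >= config$buriedness_min)

  seed <- config$seed_point
  if (is.null(seed)) seed <- plane$point
  si <- as.integer(round((seed - origin) / h)) + 1L
  if (any(si < 1) || any(si > dims)) stop("seed point outside the grid")
  in_atom <- any(sqrt(rowSums(sweep(coords, 2, seed)^2)) < radii)
  if (in_atom) stop("seed point lies inside an atom")
  if (!candidate[si[1], si[2], si[3]]) {
    stop("seed point is not inside a buried cavity region; supply ",
         "'seed_point' inside the pocket")
  }

  visited <- array(FALSE, dims)
  visited[si[1], si[2], si[3]] <- TRUE
  frontier <- visited
  repeat {
    grown <- array(FALSE, dims)
    for (d in seq_len(nrow(.ray_dirs))) {
      grown <- grown | .shift3(frontier, .ray_dirs[d, ])
    }
    frontier <- grown & candidate & !visited
    if (!any(frontier)) break
    visited <- visited | frontier
    if (sum(visited) > config$max_points) {
      stop("pocket not enclosed: flood fill exceeded ", config$max_points,
           " points")
    }
  }

  idx <- which(visited, arr.ind = TRUE)
  pts <- sweep((idx - 1) * h, 2, origin, `+`)
  signed <- as.numeric((pts - matrix(plane$point, nrow(pts), 3,
                                     byrow = TRUE)) %*% plane$normal)
  # orient the "upper" side: explicit up_point, else the seed's side,
  # else the side holding more cavity points
  flip <- 1
  if (!is.null(gate$up_point)) {
    flip <- sign(sum((gate$up_point - plane$point) * plane$normal))
  } else {
    s_seed <- sum((seed - plane$point) * plane$normal)
    if (abs(s_seed) > h / 2) {
      flip <- sign(s_seed)
    } else if (sum(signed < 0) > sum(signed >= 0)) flip <- -1
  }
  if (flip == 0) flip <- 1
  signed <- signed * flip
  n_up <- sum(signed >= 0)
  n_lo <- sum(signed < 0)
  cell <- h^3
  out <- list(total = (n_up + n_lo) * cell, upper = n_up * cell,
              lower = n_lo * cell,
              n_points = c(total = n_up + n_lo, upper = n_up, lower = n_lo),
              grid = h, probe = config$probe,
              plane = list(point = plane$point, normal = plane$normal * flip),
              gate_min_distance = gm$min_distance)
  class(out) <- "cavity_result"
  out
}

#' @export
print.cavity_result <- function(x, ...) {
  cat(sprintf("Cavity volumes (grid %.2f A, probe %.2f A):\n", x$grid, x$probe))
  cat(sprintf("  total %.1f A^3 = upper %.1f + lower %.1f A^3 (%d points)\n",
              x$total, x$upper, x$lower, x$n_points["total"]))
  invisible(x)
}
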