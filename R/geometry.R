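.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA")

# atom-table row indices of a residue, optionally restricted by chain
.residue_rows <- function(structure, resno, chain = NULL) {
  a <- structure$atoms
  hit <- a$resno == resno
  if (!is.null(chain)) hit <- hit & a$chain == chain
  which(hit)
}

#' C-alpha to C-alpha distance between two residues
#'
#' The standard calyx-opening metric: the Euclidean distance between the
#' CA atoms of two residues (e.g. 93-141 for the broadest opening,
#' 99-144 in the middle, 103-147 at the bottom of the apoM barrel).
#'
#' @param structure a `calyx_structure`.
#' @param res_a,res_b residue numbers.
#' @param chain optional chain restriction.
#' @param model model index.
#' @return distance in Angstrom.
#' @export
ca_distance <- function(structure, res_a, res_b, chain = NULL, model = 1) {
  co <- structure_coords(structure, model)
  a <- structure$atoms
  pick <- function(res) {
    i <- .residue_rows(structure, res, chain)
    i <- i[trimws(a$name[i]) == "CA"]
    if (length(i) == 0) stop("residue ", res, " has no CA atom")
    i[1]
  }
  sqrt(sum((co[pick(res_a), ] - co[pick(res_b), ])^2))
}

# Kabsch: optimal proper rotation matrix aligning mobile (centred) onto
# reference (centred); determinant correction forbids improper rotations
.kabsch_rotation <- function(ref_c, mob_c) {
  H <- crossprod(mob_c, ref_c)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superposition RMSD (Kabsch)
#'
#' Superposes a mobile coordinate set onto a reference by the optimal
#' proper rotation (SVD with determinant correction, so mirror images are
#' never matched) and returns the post-fit RMSD.
#'
#' @param ref,mobile `calyx_structure` objects or n x 3 coordinate
#'   matrices.
#' @param selection optional atom row indices applied to both.
#' @param model_ref,model_mobile model indices when structures are given.
#' @return the RMSD in Angstrom, with attributes `rotation` (3 x 3
#'   matrix), `fitted` (fitted mobile coordinates), and `degenerate`
#'   (TRUE for collinear selections, with a warning).
#' @export
superpose_rmsd <- function(ref, mobile, selection = NULL,
                           model_ref = 1, model_mobile = 1) {
  as_coords <- function(x, model) {
    if (inherits(x, "calyx_structure")) structure_coords(x, model) else as.matrix(x)
  }
  P <- as_coords(ref, model_ref)
  Q <- as_coords(mobile, model_mobile)
  if (!is.null(selection)) {
    P <- P[selection, , drop = FALSE]
    Q <- Q[selection, , drop = FALSE]
  }
  if (nrow(P) != nrow(Q)) stop("selections differ in atom count")
  if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  sv <- svd(Pc)$d
  degenerate <- sv[2] < 1e-8 * max(sv[1], 1e-12)
  if (degenerate) warning("collinear (degenerate) selection: rotation not unique")
  R <- .kabsch_rotation(Pc, Qc)
  fitted <- Qc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Pc)^2)))
  attr(rmsd, "rotation") <- R
  attr(rmsd, "fitted") <- sweep(fitted, 2, colMeans(P), `+`)
  attr(rmsd, "degenerate") <- degenerate
  rmsd
}

#' Windowed RMSF with standard errors
#'
#' Splits the trajectory into `n_windows` equal blocks (remainder frames
#' dropped and logged), superposes every frame of a block onto the block
#' mean structure, and computes per-atom root mean square fluctuations
#' within each block.  Reported are the across-window mean and standard
#' error (0 by convention for a single window) -- the block-averaging
#' scheme behind "averaged over N windows, error bars show the standard
#' error" analyses.
#'
#' @param structure a multi-model `calyx_structure`.
#' @param selection atom row indices (default: CA atoms, or all atoms if
#'   none are named CA).
#' @param n_windows number of trajectory blocks.
#' @return data.frame with `atom` (row index), `rmsf_mean`, `rmsf_se`
#'   (Angstrom).
#' @export
windowed_rmsf <- function(structure, selection = NULL, n_windows = 1) {
  stopifnot(inherits(structure, "calyx_structure"), n_windows >= 1)
  nf <- structure$n_models
  if (n_windows > nf) stop("more windows than frames")
  if (is.null(selection)) {
    selection <- which(trimws(structure$atoms$name) == "CA")
    if (length(selection) == 0) selection <- seq_len(nrow(structure$atoms))
  }
  per <- nf %/% n_windows
  dropped <- nf - per * n_windows
  if (dropped > 0) message(dropped, " trailing frame(s) dropped")
  rmsf <- matrix(0, nrow = n_windows, ncol = length(selection))
  for (w in seq_len(n_windows)) {
    frames <- ((w - 1) * per + 1):(w * per)
    coords <- lapply(frames, function(m) {
      structure_coords(structure, m)[selection, , drop = FALSE]
    })
    # fit to running mean: first frame as seed, two refinement passes
    ref <- coords[[1]]
    for (pass in 1:2) {
      fitted <- lapply(coords, function(co) {
        if (nrow(co) >= 3) {
          attr(superpose_rmsd(ref, co), "fitted")
        } else co
      })
      ref <- Reduce(`+`, fitted) / length(fitted)
    }
    dev <- vapply(fitted, function(co) rowSums((co - ref)^2),
                  numeric(length(selection)))
    rmsf[w, ] <- sqrt(rowMeans(matrix(dev, nrow = length(selection))))
  }
  se <- if (n_windows > 1) apply(rmsf, 2, stats::sd) / sqrt(n_windows) else
    rep(0, length(selection))
  data.frame(atom = selection, rmsf_mean = colMeans(rmsf), rmsf_se = se)
}

#' Specify a tyrosine gate
#'
#' The two residues whose side chains partition the binding pocket into
#' an upper (hydrophilic) and lower (hydrophobic) sub-pocket -- positions
#' 102 and 147 in apoM.  The partition plane passes through the midpoint
#' of the two gate side-chain oxygen atoms, normal to the barrel axis
#' (first principal axis of the CA atoms, or of all atoms when no CA
#' exists).
#'
#' @param residues length-2 residue numbers (default `c(102, 147)`).
#' @param chain optional chain restriction.
#' @param axis_residues optional residue numbers defining the barrel-axis
#'   CA selection (default: all CA atoms).
#' @param up_point optional length-3 coordinate on the "upper" side of
#'   the gate plane, used to orient the upper/lower split.
#' @return object of class `gate_spec`.
#' @export
gate_spec <- function(residues = c(102, 147), chain = NULL,
                      axis_residues = NULL, up_point = NULL) {
  stopifnot(length(residues) == 2L)
  out <- list(residues = residues, chain = chain,
              axis_residues = axis_residues, up_point = up_point)
  class(out) <- "gate_spec"
  out
}

.barrel_axis <- function(structure, gate, model = 1) {
  a <- structure$atoms
  co <- structure_coords(structure, model)
  sel <- which(trimws(a$name) == "CA")
  if (!is.null(gate$axis_residues)) {
    sel <- intersect(sel, which(a$resno %in% gate$axis_residues))
  }
  if (length(sel) < 3) sel <- seq_len(nrow(a))
  pc <- stats::prcomp(co[sel, , drop = FALSE])
  ax <- pc$rotation[, 1]
  ax / sqrt(sum(ax^2))
}

.gate_sidechains <- function(structure, gate, model = 1) {
  a <- structure$atoms
  co <- structure_coords(structure, model)
  lapply(gate$residues, function(res) {
    i <- .residue_rows(structure, res, gate$chain)
    if (length(i) == 0) stop("gate residue ", res, " absent from structure")
    i <- i[!(trimws(a$name[i]) %in% .backbone_names) & a$element[i] != "H"]
    if (length(i) == 0) stop("gate residue ", res, " has no side-chain heavy atoms")
    list(rows = i, coords = co[i, , drop = FALSE])
  })
}

#' Gate geometry of a frame
#'
#' Minimum side-chain heavy-atom distance between the two gate residues,
#' plus the partition plane (midpoint of the gate side-chain oxygens,
#' normal to the barrel axis).
#'
#' @param structure a `calyx_structure`.
#' @param gate a [gate_spec()].
#' @param model model index.
#' @return list with `min_distance` (Angstrom) and `plane`
#'   (`point`, `normal`).
#' @export
gate_metrics <- function(structure, gate = gate_spec(), model = 1) {
  sc <- .gate_sidechains(structure, gate, model)
  a <- structure$atoms
  d2 <- outer(seq_len(nrow(sc[[1]]$coords)), seq_len(nrow(sc[[2]]$coords)),
              Vectorize(function(i, j) {
                sum((sc[[1]]$coords[i, ] - sc[[2]]$coords[j, ])^2)
              }))
  anchor <- vapply(sc, function(s) {
    ox <- s$rows[a$element[s$rows] == "O"]
    co <- if (length(ox)) {
      structure_coords(structure, model)[ox, , drop = FALSE]
    } else s$coords
    colMeans(co)
  }, numeric(3))
  if (any(vapply(sc, function(s) !any(a$element[s$rows] == "O"), TRUE))) {
    warning("gate residue without side-chain oxygen: using side-chain centroid")
  }
  list(min_distance = sqrt(min(d2)),
       plane = list(point = rowMeans(anchor),
                    normal = .barrel_axis(structure, gate, model)))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A bond is counted present in a frame iff the donor--acceptor distance
#' is at most `d_DA` and, when donor hydrogens are supplied, the best
#' D-H...A angle is at least `angle_min` degrees; without hydrogens a
#' documented distance-only fallback applies (the crystal-structure
#' case).  Occupancy is the percentage of frames in which the bond is
#' present.
#'
#' @param structure a `calyx_structure` (models are frames).
#' @param donors,acceptors atom row indices; all donor x acceptor pairs
#'   are evaluated (identical indices are skipped).
#' @param hydrogens optional list parallel to `donors`, each element the
#'   row indices of hydrogens attached to that donor.
#' @param d_DA distance cutoff in Angstrom (default 3.5).
#' @param angle_min D-H...A angle cutoff in degrees (default 150).
#' @return data.frame with `donor`, `acceptor`, `occupancy_pct`.
#' @export
hbond_occupancy <- function(structure, donors, acceptors, hydrogens = NULL,
                            d_DA = 3.5, angle_min = 150) {
  stopifnot(inherits(structure, "calyx_structure"))
  if (length(donors) == 0 || length(acceptors) == 0) {
    stop("empty donor or acceptor selection")
  }
  pairs <- expand.grid(donor = donors, acceptor = acceptors)
  pairs <- pairs[pairs$donor != pairs$acceptor, , drop = FALSE]
  present <- matrix(FALSE, nrow = structure$n_models, ncol = nrow(pairs))
  for (m in seq_len(structure$n_models)) {
    co <- structure_coords(structure, m)
    for (p in seq_len(nrow(pairs))) {
      d <- co[pairs$donor[p], ]
      acc <- co[pairs$acceptor[p], ]
      ok <- sqrt(sum((d - acc)^2)) <= d_DA
      hyd <- if (!is.null(hydrogens)) {
        hydrogens[[match(pairs$donor[p], donors)]]
      } else NULL
      if (ok && length(hyd)) {
        ang <- vapply(hyd, function(h) {
          v1 <- d - co[h, ]
          v2 <- acc - co[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, numeric(1))
        ok <- max(ang) >= angle_min
      }
      present[m, p] <- ok
    }
  }
  data.frame(donor = pairs$donor, acceptor = pairs$acceptor,
             occupancy_pct = 100 * colMeans(present))
}
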