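#' Aggregate atom-pairwise forces into a residue force profile
#'
#' For every frame, all atom-pair force vectors between the ligand and the
#' atoms of one protein residue are vector-summed; the profile value for
#' that residue is the time average of the magnitude of this per-frame
#' vector sum, converted to pN (1 kJ/mol/nm = 1.66054 pN).  Frames in
#' which a residue has no pair on record contribute zero force for that
#' residue; missing frame indices are processed and their count logged via
#' a message.
#'
#' @param records data.frame of pairwise force records with columns
#'   `frame`, `atom_i`, `atom_j`, `fx`, `fy`, `fz` (kJ/mol/nm).  Records
#'   may be stored in either orientation; rows whose `atom_j` is a ligand
#'   atom are flipped (swap ids, negate the vector) before aggregation.
#' @param ligand_atoms atom ids belonging to the ligand.
#' @param atom_residues mapping of protein atom id to residue: a
#'   data.frame with columns `atom_id` and `residue`, or a named vector
#'   (names = atom ids).
#' @param source label stored on the profile, e.g. `"equilibrium"` or
#'   `"pulling"`.
#' @return object of class `residue_force_profile`: data.frame with
#'   columns `residue`, `mean_force_pN`, `n_frames`, plus a `source`
#'   attribute.
#' @export
aggregate_residue_profile <- function(records, ligand_atoms, atom_residues,
                                      source = "equilibrium") {
  need <- c("frame", "atom_i", "atom_j", "fx", "fy", "fz")
  stopifnot(all(need %in% names(records)))
  if (is.data.frame(atom_residues)) {
    map <- stats::setNames(as.character(atom_residues$residue),
                           as.character(atom_residues$atom_id))
  } else {
    map <- stats::setNames(as.character(atom_residues), names(atom_residues))
  }
  lig <- as.character(ligand_atoms)

  ai <- as.character(records$atom_i)
  aj <- as.character(records$atom_j)
  i_lig <- ai %in% lig
  j_lig <- aj %in% lig
  keep <- xor(i_lig, j_lig)  # ligand-protein pairs only
  if (!any(keep)) stop("no ligand-protein atom pairs found in the records")
  rec <- records[keep, , drop = FALSE]
  flip <- j_lig[keep]  # ligand sits on the j side: swap and negate
  prot <- ifelse(flip, ai[keep], aj[keep])
  sgn <- ifelse(flip, -1, 1)

  unknown <- setdiff(unique(prot), names(map))
  if (length(unknown)) {
    stop("atom id(s) without residue mapping: ",
         paste(sort(unknown), collapse = ", "))
  }
  res <- map[prot]

  frames <- sort(unique(records$frame))
  n_frames <- length(frames)
  gaps <- if (n_frames > 1) diff(range(frames)) + 1 - n_frames else 0
  if (gaps > 0) message(gaps, " frame index gap(s) in the force records")

  key <- paste(rec$frame, res, sep = "\r")
  sums <- rowsum(cbind(rec$fx, rec$fy, rec$fz) * sgn, key, reorder = FALSE)
  mag <- sqrt(rowSums(sums^2))
  res_of_key <- sub("^[^\r]*\r", "", rownames(sums))
  total <- tapply(mag, res_of_key, sum)
  prof <- data.frame(residue = names(total),
                     mean_force_pN = as.numeric(total) / n_frames *
                       PN_PER_KJ_MOL_NM,
                     n_frames = n_frames, row.names = NULL,
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$residue), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, source = source,
            class = c("residue_force_profile", "data.frame"))
}

#' Select key binding residues by force threshold
#'
#' Residues whose time-averaged force is strictly above `threshold`,
#' sorted by decreasing force (the >70 pN rule identifies the main
#' anchoring residues; >40 pN marks contributors during pulling).
#'
#' @param profile a `residue_force_profile`.
#' @param threshold force threshold in pN (default 70).
#' @return character vector of residue labels, strongest first.
#' @export
select_key_residues <- function(profile, threshold = 70) {
  stopifnot(inherits(profile, "residue_force_profile"), threshold >= 0)
  sel <- profile[profile$mean_force_pN > threshold, , drop = FALSE]
  sel$residue[order(sel$mean_force_pN, decreasing = TRUE)]
}

#' Flag residues with markedly increased forces under pulling
#'
#' Compares a pulling profile against an equilibrium profile over the
#' union of their residues (missing residues are treated as zero force)
#' and flags residues whose pulling force exceeds `abs_floor` and whose
#' pulling/equilibrium ratio exceeds `ratio` (a zero equilibrium force
#' counts as an infinite ratio).
#'
#' @param pulling,equilibrium `residue_force_profile` objects.
#' @param abs_floor absolute pulling-force floor in pN (default 40).
#' @param ratio minimum pulling/equilibrium ratio (default 2).
#' @return data.frame of flagged residues with both forces and the ratio,
#'   sorted by decreasing pulling force.
#' @export
diff_profiles <- function(pulling, equilibrium, abs_floor = 40, ratio = 2) {
  stopifnot(inherits(pulling, "residue_force_profile"),
            inherits(equilibrium, "residue_force_profile"))
  residues <- union(pulling$residue, equilibrium$residue)
  fp <- stats::setNames(rep(0, length(residues)), residues)
  fe <- fp
  fp[pulling$residue] <- pulling$mean_force_pN
  fe[equilibrium$residue] <- equilibrium$mean_force_pN
  r <- ifelse(fe > 0, fp / fe, ifelse(fp > 0, Inf, 0))
  flag <- fp > abs_floor & r > ratio
  out <- data.frame(residue = residues[flag],
                    pulling_pN = as.numeric(fp[flag]),
                    equilibrium_pN = as.numeric(fe[flag]),
                    ratio = as.numeric(r[flag]), stringsAsFactors = FALSE)
  out[order(out$pulling_pN, decreasing = TRUE), , drop = FALSE]
}

#' Synthetic atom-pairwise force fixture
#'
#' Generates per-frame ligand--residue atom-pair force records whose
#' residue-aggregated, time-averaged magnitudes equal `designed_means`
#' (in pN) up to the generator's own relative noise.  Each residue's
#' per-frame target vector is split over two atom pairs whose vector sum
#' is exact, so aggregation recovers the designed magnitude exactly per
#' frame; only the frame-to-frame magnitude noise averages out.
#'
#' @param designed_means named numeric vector of target mean forces in pN
#'   (names are residue labels).
#' @param n_frames number of frames.
#' @param noise_sd relative standard deviation of the per-frame magnitude
#'   (default 0.1; 0 gives exact recovery from a single frame).
#' @param seed RNG seed.
#' @return list with `records` (data.frame frame/atom_i/atom_j/fx/fy/fz in
#'   kJ/mol/nm), `ligand_atoms`, `atom_residues` (data.frame), and
#'   `designed_means`.
#' @export
make_pairforce_fixture <- function(designed_means, n_frames = 1e4,
                                   noise_sd = 0.1, seed = 1) {
  stopifnot(all(designed_means >= 0), n_frames >= 1, noise_sd >= 0)
  if (is.null(names(designed_means))) {
    names(designed_means) <- sprintf("RES%d", seq_along(designed_means))
  }
  if (!is.null(seed)) set.seed(seed)
  n_res <- length(designed_means)
  lig_atoms <- c(1L, 2L)
  prot_atoms <- matrix(2L + seq_len(2L * n_res), nrow = n_res, byrow = TRUE)
  rows <- vector("list", n_res)
  for (r in seq_len(n_res)) {
    m_kj <- designed_means[r] / PN_PER_KJ_MOL_NM
    mag <- m_kj * pmax(0, 1 + noise_sd * stats::rnorm(n_frames))
    u <- matrix(stats::rnorm(3 * n_frames), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    target <- u * mag
    w <- matrix(stats::rnorm(3 * n_frames, sd = m_kj / 4 + 1e-12), ncol = 3)
    f1 <- target / 2 + w
    f2 <- target / 2 - w
    rows[[r]] <- data.frame(
      frame = rep(seq_len(n_frames), 2L),
      atom_i = rep(lig_atoms, each = n_frames),
      atom_j = rep(prot_atoms[r, ], each = n_frames),
      fx = c(f1[, 1], f2[, 1]), fy = c(f1[, 2], f2[, 2]),
      fz = c(f1[, 3], f2[, 3]))
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$frame, records$atom_j), , drop = FALSE]
  rownames(records) <- NULL
  mapping <- data.frame(atom_id = as.integer(t(prot_atoms)),
                        residue = rep(names(designed_means), each = 2L),
                        stringsAsFactors = FALSE)
  list(records = records, ligand_atoms = lig_atoms, atom_residues = mapping,
       designed_means = designed_means)
}
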