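#' Define a titratable group
#'
#' A protonatable site described by its intrinsic (water) pKa and four
#' environmental perturbation terms: desolvation, hydrogen bonding,
#' electrostatic reorganization, and Coulombic interactions.  The terms
#' are numeric inputs (pH units); their structure-based estimation is out
#' of scope.  The charge convention follows the group kind: an acid is 0
#' when protonated and -1 when deprotonated; a base is +1 when protonated
#' and 0 when deprotonated.
#'
#' @param label unique group label, e.g. `"phosphate_O1"`.
#' @param kind `"acid"` or `"base"`.
#' @param pKa_water pKa of the isolated group in water (pH units).
#' @param desolvation,hydrogen_bond,reorganization,coulombic perturbation
#'   terms in pH units (default 0).
#' @return object of class `titratable_group`.
#' @export
titratable_group <- function(label, kind = c("acid", "base"), pKa_water,
                             desolvation = 0, hydrogen_bond = 0,
                             reorganization = 0, coulombic = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, is.finite(pKa_water))
  structure(list(label = label, kind = kind, pKa_water = pKa_water,
                 terms = c(desolvation = desolvation,
                           hydrogen_bond = hydrogen_bond,
                           reorganization = reorganization,
                           coulombic = coulombic)),
            class = "titratable_group")
}

#' Bundle titratable groups into a set
#'
#' @param ... `titratable_group` objects (or a single list of them).
#' @param context free-text context label, e.g. `"S1P bound"`.
#' @return object of class `titratable_set`.
#' @export
titratable_set <- function(..., context = "") {
  groups <- list(...)
  if (length(groups) == 1L && !inherits(groups[[1]], "titratable_group")) {
    groups <- groups[[1]]
  }
  stopifnot(all(vapply(groups, inherits, TRUE, "titratable_group")))
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(groups = stats::setNames(groups, labels), context = context),
            class = "titratable_set")
}

#' Effective pKa of a titratable group
#'
#' The intrinsic water pKa plus the sum of the four environmental
#' perturbation terms.
#'
#' @param group a [titratable_group()].
#' @return effective pKa (pH units).
#' @export
effective_pka <- function(group) {
  stopifnot(inherits(group, "titratable_group"))
  group$pKa_water + sum(group$terms)
}

#' Henderson-Hasselbalch protonated fraction
#'
#' \eqn{\theta = 1 / (1 + 10^{pH - pKa})}; exactly 0.5 at `pH == pKa`,
#' strictly increasing in pKa and decreasing in pH.
#'
#' @param pKa effective pKa (vectorised).
#' @param pH solution pH.
#' @return protonated fraction in `[0, 1]`.
#' @export
protonated_fraction <- function(pKa, pH) 1 / (1 + 10^(pH - pKa))

# effective pKa for every group of a set, as a named vector
.set_pkas <- function(set) {
  vapply(set$groups, effective_pka, numeric(1))
}

#' Net proton exchange between two protonation contexts
#'
#' Sums the change in Henderson-Hasselbalch protonated fraction over
#' matched titratable groups:
#' \eqn{n = \sum_g \theta(pKa^{free}_g, pH) - \theta(pKa^{bound}_g, pH)}.
#' Positive `n` means the ligand gains protons upon unbinding; the
#' reported headline quantity is the magnitude, with the direction kept in
#' the result.
#'
#' @param bound,free [titratable_set()] objects enumerating the same
#'   groups (matched by label).
#' @param pH solution pH (default 7).
#' @return list with `n` (signed), `magnitude`, `direction` (`"gained"`,
#'   `"released"` or `"none"`), and `per_group` contributions.
#' @export
net_proton_exchange <- function(bound, free, pH = 7) {
  stopifnot(inherits(bound, "titratable_set"), inherits(free, "titratable_set"))
  lb <- names(bound$groups)
  lf <- names(free$groups)
  if (!setequal(lb, lf)) {
    stop("unmatched groups: ",
         paste(c(setdiff(lb, lf), setdiff(lf, lb)), collapse = ", "))
  }
  pkb <- .set_pkas(bound)[lb]
  pkf <- .set_pkas(free)[lb]
  per <- protonated_fraction(pkf, pH) - protonated_fraction(pkb, pH)
  n <- sum(per)
  list(n = n, magnitude = abs(n),
       direction = if (n > 0) "gained" else if (n < 0) "released" else "none",
       per_group = stats::setNames(per, lb), pH = pH)
}

#' Isoelectric point of a titratable set
#'
#' Bisection on the net charge
#' \eqn{Q(pH) = \sum_{bases} \theta - \sum_{acids} (1 - \theta)} until
#' `|Q| < 1e-6` within pH 0..14.  Requires at least one acid and one base
#' (otherwise Q never crosses zero).
#'
#' @param set a [titratable_set()].
#' @return the pH of zero net charge.
#' @export
isoelectric_point <- function(set) {
  stopifnot(inherits(set, "titratable_set"))
  kinds <- vapply(set$groups, `[[`, "", "kind")
  if (!any(kinds == "acid") || !any(kinds == "base")) {
    stop("no isoelectric point: the set needs at least one acid and one base")
  }
  pkas <- .set_pkas(set)
  Q <- function(pH) {
    th <- protonated_fraction(pkas, pH)
    sum(th[kinds == "base"]) - sum(1 - th[kinds == "acid"])
  }
  lo <- 0; hi <- 14
  qlo <- Q(lo); qhi <- Q(hi)
  if (sign(qlo) == sign(qhi)) stop("no isoelectric point in pH 0..14")
  repeat {
    mid <- (lo + hi) / 2
    qm <- Q(mid)
    if (abs(qm) < 1e-6 || (hi - lo) < 1e-12) return(mid)
    if (sign(qm) == sign(qlo)) { lo <- mid; qlo <- qm } else hi <- mid
  }
}

#' Track proton exchange and pI along a trajectory
#'
#' Applies [net_proton_exchange()] (relative to the first frame) and
#' [isoelectric_point()] to a per-frame pKa table, e.g. pKa values
#' extracted along an enforced-unbinding trajectory.  Frames missing any
#' group of the first frame's schema are skipped and logged.
#'
#' @param pka_table data.frame with columns `frame`, `label`, `kind`,
#'   `pKa` (effective pKa per group and frame).
#' @param pH solution pH (default 7).
#' @return data.frame with columns `frame`, `n` (signed proton exchange
#'   vs. frame 0), `magnitude`, and `pI` (NA when the frame's set has no
#'   acid/base pair); skipped frames are recorded in the
#'   `skipped_frames` attribute.
#' @export
protonation_timeseries <- function(pka_table, pH = 7) {
  need <- c("frame", "label", "kind", "pKa")
  stopifnot(all(need %in% names(pka_table)))
  if (nrow(pka_table) == 0) {
    return(data.frame(frame = numeric(0), n = numeric(0),
                      magnitude = numeric(0), pI = numeric(0)))
  }
  frames <- sort(unique(pka_table$frame))
  make_set <- function(sub, ctx) {
    titratable_set(lapply(seq_len(nrow(sub)), function(i) {
      titratable_group(sub$label[i], sub$kind[i], sub$pKa[i])
    }), context = ctx)
  }
  ref_sub <- pka_table[pka_table$frame == frames[1], , drop = FALSE]
  ref <- make_set(ref_sub, "frame 0")
  schema <- sort(ref_sub$label)
  out <- vector("list", length(frames))
  skipped <- numeric(0)
  for (k in seq_along(frames)) {
    sub <- pka_table[pka_table$frame == frames[k], , drop = FALSE]
    if (!identical(sort(sub$label), schema)) {
      skipped <- c(skipped, frames[k])
      next
    }
    s <- make_set(sub, sprintf("frame %g", frames[k]))
    ex <- net_proton_exchange(ref, s, pH)
    pI <- tryCatch(isoelectric_point(s), error = function(e) NA_real_)
    out[[k]] <- data.frame(frame = frames[k], n = ex$n,
                           magnitude = ex$magnitude, pI = pI)
  }
  if (length(skipped)) {
    message(length(skipped), " frame(s) skipped (incomplete group schema): ",
            paste(skipped, collapse = ", "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  attr(res, "skipped_frames") <- skipped
  res
}

#' Titratable sets for S1P bound to apoM and free in water
#'
#' Convenience constructors using the reported pKa values: the two
#' phosphate oxygens at ~4 in the bound complex versus ~6 in water, and
#' the amine at 14 bound versus 11 in water.  Each phosphate oxygen is an
#' independent one-proton acid site; the amine is a base.
#'
#' @param phosphate_pKa length-2 pKa values of the two phosphate oxygens.
#' @param amine_pKa amine pKa.
#' @param context context label.
#' @return a [titratable_set()].
#' @export
s1p_titratable_set <- function(phosphate_pKa = c(4, 4), amine_pKa = 14,
                               context = "S1P bound") {
  stopifnot(length(phosphate_pKa) == 2L)
  titratable_set(
    titratable_group("phosphate_O1", "acid", phosphate_pKa[1]),
    titratable_group("phosphate_O2", "acid", phosphate_pKa[2]),
    titratable_group("amine_N", "base", amine_pKa),
    context = context
  )
}
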