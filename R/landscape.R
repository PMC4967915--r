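#' Construct a model unbinding free-energy landscape
#'
#' Builds an analytic one-dimensional free-energy profile \eqn{U(\xi)} that
#' stands in for a ligand-unbinding potential of mean force along a
#' protein--ligand separation coordinate \eqn{\xi} (nm).  The profile is
#' zero on a bound shelf up to `bound_min`, rises smoothly (a monotone
#' cubic spline through quintic-smoothstep knots) to `barrier` at
#' `plateau_start`, and stays exactly at `barrier` beyond it.  An optional
#' `shoulder` carves a local metastable dip into the rising flank, giving
#' profiles with an intermediate state (as seen for unbinding pathways that
#' visit a secondary anchoring residue).
#'
#' @param barrier barrier height in kJ/mol (\eqn{\ge 0}; 0 gives a flat
#'   landscape).
#' @param bound_min position of the bound minimum in nm; \eqn{U} is 0 for
#'   \eqn{\xi \le} `bound_min`.
#' @param plateau_start nm; \eqn{U(\xi) =} `barrier` for all
#'   \eqn{\xi \ge} `plateau_start`.  Must satisfy
#'   `bound_min < plateau_start <= 3.3`.
#' @param shoulder optional `c(xi, depth)`: a compact-support bump
#'   subtracted from the rising flank so that
#'   \eqn{U(\xi_s) = U_{base}(\xi_s) - depth}.  Must lie strictly inside
#'   `(bound_min, plateau_start)`.
#' @param domain numeric length-2, the reaction-coordinate domain in nm.
#'   Defaults to `c(bound_min - 0.2, max(3.3, plateau_start) + 0.2)`.
#' @param n_knots number of spline knots on the rising flank.
#' @return an object of class `model_landscape`.
#' @seealso [landscape_energy()], [landscape_force()], [simulate_overdamped()]
#' @examples
#' ls64 <- make_unbinding_landscape(64, bound_min = 1.0, plateau_start = 2.3)
#' landscape_energy(ls64, c(1.0, 2.0, 3.3))
#' @export
make_unbinding_landscape <- function(barrier, bound_min = 1.0,
                                     plateau_start = 2.3, shoulder = NULL,
                                     domain = NULL, n_knots = 21L) {
  stopifnot(is.numeric(barrier), length(barrier) == 1L, barrier >= 0)
  if (!(bound_min < plateau_start)) {
    stop("'bound_min' must be smaller than 'plateau_start'")
  }
  if (plateau_start > 3.3) {
    stop("'plateau_start' must not exceed 3.3 nm (free-state distance)")
  }
  if (is.null(domain)) domain <- c(bound_min - 0.2, max(3.3, plateau_start) + 0.2)
  stopifnot(length(domain) == 2L, domain[1] < bound_min, domain[2] >= plateau_start)

  xs <- seq(bound_min, plateau_start, length.out = n_knots)
  u <- (xs - bound_min) / (plateau_start - bound_min)
  # quintic smoothstep: monotone, zero slope and curvature at both ends
  Us <- barrier * (u^3 * (10 - 15 * u + 6 * u^2))
  spl <- if (barrier > 0) {
    stats::splinefun(xs, Us, method = "hyman")
  } else {
    function(x, deriv = 0) rep(0, length(x))
  }

  if (!is.null(shoulder)) {
    stopifnot(is.numeric(shoulder), length(shoulder) == 2L)
    if (shoulder[1] <= bound_min || shoulder[1] >= plateau_start) {
      stop("shoulder position must lie strictly inside (bound_min, plateau_start)")
    }
    if (shoulder[2] <= 0) stop("shoulder depth must be positive")
  }

  obj <- list(
    knots = data.frame(xi = xs, U = Us),
    barrier = barrier, bound_min = bound_min, plateau_start = plateau_start,
    shoulder = shoulder, domain = domain, spline = spl
  )
  class(obj) <- "model_landscape"
  obj
}

# compact-support bump of height `depth` at xi_s: exactly zero outside
# (xi_s - w, xi_s + w), so the plateau and bound-shelf invariants hold.
.shoulder_bump <- function(landscape, xi, deriv = 0) {
  sh <- landscape$shoulder
  if (is.null(sh)) return(rep(0, length(xi)))
  w <- min(0.1, sh[1] - landscape$bound_min, landscape$plateau_start - sh[1])
  u <- (xi - sh[1]) / w
  out <- numeric(length(xi))
  inside <- abs(u) < 1
  if (any(inside)) {
    ui <- u[inside]
    g <- exp(1 - 1 / (1 - ui^2))
    if (deriv == 0) {
      out[inside] <- sh[2] * g
    } else {
      out[inside] <- sh[2] * g * (-2 * ui / (1 - ui^2)^2) / w
    }
  }
  out
}

#' Evaluate a model landscape
#'
#' @param landscape a [make_unbinding_landscape()] object.
#' @param xi positions in nm (vectorised).
#' @return free energy U(xi) in kJ/mol.
#' @export
landscape_energy <- function(landscape, xi) {
  stopifnot(inherits(landscape, "model_landscape"))
  base <- ifelse(xi <= landscape$bound_min, 0,
                 ifelse(xi >= landscape$plateau_start, landscape$barrier,
                        landscape$spline(pmin(pmax(xi, landscape$bound_min),
                                              landscape$plateau_start))))
  base - .shoulder_bump(landscape, xi, deriv = 0)
}

#' Landscape force -dU/dxi
#'
#' @inheritParams landscape_energy
#' @return force in kJ/mol/nm.
#' @export
landscape_force <- function(landscape, xi) {
  stopifnot(inherits(landscape, "model_landscape"))
  mid <- xi > landscape$bound_min & xi < landscape$plateau_start
  dbase <- numeric(length(xi))
  if (any(mid) && landscape$barrier > 0) {
    dbase[mid] <- landscape$spline(xi[mid], deriv = 1)
  }
  -(dbase - .shoulder_bump(landscape, xi, deriv = 1))
}

#' @export
print.model_landscape <- function(x, ...) {
  cat("Model unbinding landscape\n")
  cat(sprintf("  barrier        : %.3g kJ/mol\n", x$barrier))
  cat(sprintf("  bound minimum  : %.3g nm (U = 0)\n", x$bound_min))
  cat(sprintf("  plateau from   : %.3g nm (U = barrier)\n", x$plateau_start))
  if (!is.null(x$shoulder)) {
    cat(sprintf("  shoulder       : dip of %.3g kJ/mol at %.3g nm\n",
                x$shoulder[2], x$shoulder[1]))
  }
  cat(sprintf("  domain         : [%.3g, %.3g] nm\n", x$domain[1], x$domain[2]))
  invisible(x)
}
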