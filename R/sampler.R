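#' Langevin sampler parameters
#'
#' Parameters of the overdamped (Brownian) dynamics used to sample model
#' landscapes.  Thermal energy is computed internally as
#' k_B T with k_B = 0.0083145 kJ/mol/K.
#'
#' @param temperature temperature in K (default 310, body temperature).
#' @param diffusion diffusion coefficient D in nm^2/ns; `0` switches off
#'   thermal noise while keeping unit-mobility drift, giving a
#'   deterministic gradient descent to the nearest minimum.
#' @param timestep integration timestep dt in ns.
#' @param n_steps number of integration steps.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 310, diffusion = 1.0,
                            timestep = 1e-5, n_steps = 1e5, seed = NULL) {
  stopifnot(temperature > 0, diffusion >= 0, timestep > 0, n_steps >= 1)
  structure(list(temperature = temperature, diffusion = diffusion,
                 timestep = timestep, n_steps = as.numeric(n_steps),
                 seed = seed, kT = kT_kJ_mol(temperature)),
            class = "langevin_params")
}

#' Harmonic bias specification
#'
#' Defines the bias potential acting on the reaction coordinate: none, a
#' fixed umbrella restraint `w(xi) = k/2 (xi - center)^2`, or a spring whose
#' anchor moves at constant velocity, `center(t) = center + v t`
#' (constant-velocity pulling).  Defaults follow the umbrella spring
#' k = 1000 kJ/mol/nm^2 and the pulling spring k = 100 kJ/mol/nm^2 at
#' v = 0.01 nm/ns.
#'
#' @param kind one of `"none"`, `"umbrella"`, `"moving_spring"`.
#' @param center spring centre in nm (anchor start for a moving spring).
#' @param spring_k spring constant in kJ/mol/nm^2 (default 1000 for
#'   umbrella, 100 for moving spring, 0 for none).
#' @param velocity anchor velocity in nm/ns (moving spring only,
#'   default 0.01).
#' @return object of class `bias_spec`.
#' @export
bias_spec <- function(kind = c("none", "umbrella", "moving_spring"),
                      center = NA_real_, spring_k = NULL, velocity = 0.01) {
  kind <- match.arg(kind)
  if (is.null(spring_k)) {
    spring_k <- switch(kind, none = 0, umbrella = 1000, moving_spring = 100)
  }
  if (spring_k < 0) stop("'spring_k' must be >= 0")
  if (kind != "none" && !is.finite(center)) {
    stop("a ", kind, " bias requires a finite 'center'")
  }
  structure(list(kind = kind, center = center, spring_k = spring_k,
                 velocity = velocity), class = "bias_spec")
}

# tabulate the landscape force for the C++ integrator
.force_table <- function(landscape, h = 0.001) {
  grid <- seq(landscape$domain[1], landscape$domain[2], by = h)
  list(grid_min = grid[1], h = h, force = landscape_force(landscape, grid),
       grid = grid)
}

# startup stability checks (see package vignette): the expected step
# displacement must stay below 0.1 nm and dt below 0.1 kT / (D max|U''|).
.check_stability <- function(landscape, bias, params, tab) {
  D <- max(params$diffusion, 1)  # D = 0 keeps unit-mobility drift
  dt <- params$timestep; kT <- params$kT
  fmax <- max(abs(tab$force)) + bias$spring_k *
    max(abs(landscape$domain - if (is.finite(bias$center)) bias$center else mean(landscape$domain)))
  step <- sqrt(2 * D * dt) + D / kT * fmax * dt
  if (step > 0.1) {
    stop(sprintf(paste0("unstable integration: expected step size %.3g nm ",
                        "exceeds 0.1 nm; reduce 'timestep' or 'diffusion'"), step))
  }
  curv <- max(abs(diff(tab$force))) / tab$h + bias$spring_k
  if (curv > 0 && dt > 0.1 * kT / (D * curv)) {
    warning(sprintf(paste0("timestep %.3g ns exceeds stability guideline ",
                           "0.1 kT/(D max|U''|) = %.3g ns"), dt,
                    0.1 * kT / (D * curv)))
  }
  invisible(TRUE)
}

#' Overdamped Langevin sampling of a model landscape
#'
#' Euler--Maruyama integration of
#' \eqn{\xi_{t+dt} = \xi_t - (D/k_BT)\,\partial_\xi(U + w_{bias})\,dt +
#' \sqrt{2 D dt}\,\eta}, with reflecting boundaries at the landscape domain
#' edges.  Identical seeds give bitwise-identical trajectories.
#'
#' @param landscape a [make_unbinding_landscape()] object.
#' @param bias a [bias_spec()] (default: no bias).
#' @param params a [langevin_params()] object.
#' @param xi0 starting position (nm); defaults to the bias centre, or the
#'   bound minimum for unbiased runs.
#' @param sample_every record every `sample_every`-th step.
#' @return object of class `xi_series` with elements `time` (ns), `xi`
#'   (nm), and for biased runs `force_pN` (instantaneous spring force) and
#'   `f_max_pN`.
#' @export
simulate_overdamped <- function(landscape, bias = bias_spec("none"),
                                params = langevin_params(), xi0 = NULL,
                                sample_every = 1L) {
  stopifnot(inherits(landscape, "model_landscape"), inherits(bias, "bias_spec"),
            inherits(params, "langevin_params"), sample_every >= 1)
  if (is.null(xi0)) {
    xi0 <- if (bias$kind == "none") landscape$bound_min else bias$center
  }
  if (xi0 < landscape$domain[1] || xi0 > landscape$domain[2]) {
    stop("initial position lies outside the landscape domain")
  }
  tab <- .force_table(landscape)
  .check_stability(landscape, bias, params, tab)
  if (!is.null(params$seed)) set.seed(params$seed)
  kind <- match(bias$kind, c("none", "umbrella", "moving_spring")) - 1L
  # D = 0 is the noiseless (zero-temperature) limit: thermal kicks are
  # switched off but the drift keeps unit mobility, so the trajectory is
  # a deterministic gradient descent
  D_mob <- if (params$diffusion > 0) params$diffusion else 1
  mob <- D_mob / params$kT * params$timestep
  noise <- sqrt(2 * params$diffusion * params$timestep)
  res <- langevin_cpp(xi0, params$n_steps, params$timestep, mob,
                      noise, tab$grid_min, tab$h, tab$force, kind,
                      bias$spring_k, bias$center,
                      if (kind == 2L) bias$velocity else 0,
                      as.integer(sample_every),
                      landscape$domain[1], landscape$domain[2])
  n_rec <- length(res$xi)
  out <- list(time = params$timestep * sample_every * seq_len(n_rec),
              xi = res$xi, bias = bias, params = params)
  if (kind != 0L) {
    out$force_pN <- res$f_bias * PN_PER_KJ_MOL_NM
    out$f_max_pN <- res$f_max * PN_PER_KJ_MOL_NM
    out$t_f_max <- res$t_f_max
  }
  class(out) <- "xi_series"
  out
}

#' Constant-velocity pulling (enforced unbinding)
#'
#' Drags a harmonic spring across the landscape at constant velocity and
#' records the force--extension trace.  The peak spring force is the
#' rupture ("unbinding") force; its median over seeds increases with
#' pulling velocity.
#'
#' @param landscape a [make_unbinding_landscape()] object.
#' @param bias a [bias_spec()] of kind `"moving_spring"`; its `center` is
#'   the anchor start (defaults to the bound minimum when `NA`).
#' @param params a [langevin_params()]; `n_steps` is derived from the pull
#'   distance and ignored if supplied.
#' @param target final anchor position in nm (default 3.3, the free state).
#' @param sample_every record every `sample_every`-th step.
#' @param smooth_nm anchor-displacement window (nm) over which the
#'   recorded force trace is smoothed (running mean) before the rupture
#'   force is read off (default 0.05).  The instantaneous spring force
#'   fluctuates thermally with an amplitude of tens of pN; without
#'   smoothing the trace maximum measures the trace length (extreme-value
#'   statistics) rather than the rupture event.
#' @return object of class `force_extension_trace`: `time` (ns), `xi` (nm),
#'   `force_pN` (raw), `force_smooth_pN`, `f_max_pN` (rupture force: max
#'   of the smoothed trace), `f_max_raw_pN` (max instantaneous force over
#'   all steps), `t_f_max` (ns).
#' @export
run_constant_velocity_pull <- function(landscape,
                                       bias = bias_spec("moving_spring",
                                                        center = NA_real_),
                                       params = langevin_params(),
                                       target = 3.3, sample_every = 100L,
                                       smooth_nm = 0.05) {
  stopifnot(inherits(bias, "bias_spec"))
  if (bias$kind != "moving_spring") {
    stop("'bias' must have kind \"moving_spring\"")
  }
  if (!is.finite(bias$center)) bias$center <- landscape$bound_min
  if (target > landscape$domain[2]) {
    stop("spring target lies beyond the landscape domain (spring detaches)")
  }
  if (bias$velocity <= 0) stop("pulling velocity must be positive")
  t_total <- (target - bias$center) / bias$velocity
  params$n_steps <- ceiling(t_total / params$timestep)
  out <- simulate_overdamped(landscape, bias, params, xi0 = bias$center,
                             sample_every = sample_every)
  out$f_max_raw_pN <- out$f_max_pN
  w <- max(1L, round(smooth_nm / bias$velocity /
                       (params$timestep * sample_every)))
  w <- min(w, length(out$force_pN))
  sm <- as.numeric(stats::filter(out$force_pN, rep(1 / w, w), sides = 2))
  out$force_smooth_pN <- sm
  out$f_max_pN <- max(sm, na.rm = TRUE)
  out$t_f_max <- out$time[which.max(sm)]
  class(out) <- c("force_extension_trace", "xi_series")
  out
}

#' Generate a synthetic umbrella-sampling dataset
#'
#' Runs one umbrella-biased Langevin simulation per window centre,
#' discards a burn-in fraction, and returns the retained reaction
#' coordinate samples.  Per-window seeds are derived deterministically
#' from `params$seed` (seed + window index - 1).  Adjacent windows are
#' checked for histogram overlap and a warning names any gap.
#'
#' @param landscape a [make_unbinding_landscape()] object.
#' @param centers strictly increasing umbrella centres (nm).
#' @param spring_k umbrella spring constant, kJ/mol/nm^2 (default 1000).
#' @param params a [langevin_params()]; its `n_steps` is derived from
#'   `n_samples`, `sample_every` and `burn_in`.
#' @param n_samples retained samples per window.
#' @param sample_every record every `sample_every`-th step.  The default
#'   (`NULL`) spaces retained samples one harmonic relaxation time of the
#'   biased window apart (`tau = k_BT / (D k)` in integrator steps), the
#'   usual spacing at which successive samples are treated as
#'   statistically independent.
#' @param burn_in fraction of recorded samples discarded as equilibration
#'   (default 0.1).
#' @param dir optional directory: writes one pullx-dialect `.xvg` file per
#'   window plus `manifest.tsv` (filename, center, spring_k).
#' @param overlap_min warn when the histogram intersection of adjacent
#'   windows falls below this value (default 0.01).
#' @return object of class `umbrella_dataset`: a list of
#'   `umbrella_window` objects (fields `center`, `spring_k`, `samples`,
#'   `n_samples`).
#' @export
generate_umbrella_dataset <- function(landscape, centers, spring_k = 1000,
                                      params = langevin_params(seed = 1),
                                      n_samples = 1e5, sample_every = NULL,
                                      burn_in = 0.1, dir = NULL,
                                      overlap_min = 0.01) {
  stopifnot(length(centers) >= 1, spring_k >= 0, n_samples >= 1,
            burn_in >= 0, burn_in < 1)
  if (is.null(sample_every)) {
    tau_steps <- if (spring_k > 0 && params$diffusion > 0) {
      params$kT / (params$diffusion * spring_k) / params$timestep
    } else 100
    sample_every <- max(1L, as.integer(ceiling(tau_steps)))
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("'centers' must be strictly increasing")
  }
  n_rec <- ceiling(n_samples / (1 - burn_in))
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    p <- params
    p$n_steps <- n_rec * sample_every
    if (!is.null(params$seed)) p$seed <- params$seed + i - 1L
    tr <- simulate_overdamped(landscape,
                              bias_spec("umbrella", center = centers[i],
                                        spring_k = spring_k),
                              p, xi0 = centers[i], sample_every = sample_every)
    n_drop <- n_rec - n_samples
    keep <- if (n_drop > 0) tr$xi[-seq_len(n_drop)] else tr$xi
    windows[[i]] <- structure(list(center = centers[i], spring_k = spring_k,
                                   samples = keep, n_samples = length(keep)),
                              class = "umbrella_window")
  }
  ds <- structure(windows, class = "umbrella_dataset",
                  temperature = params$temperature)
  .check_window_overlap(ds, overlap_min)
  if (!is.null(dir)) write_umbrella_dataset(ds, dir)
  ds
}

# histogram-intersection overlap of adjacent windows on a common grid
.window_overlap <- function(a, b, bin = 0.01) {
  rng <- range(c(a$samples, b$samples))
  brk <- seq(rng[1] - bin, rng[2] + bin, by = bin)
  ha <- hist(a$samples, breaks = brk, plot = FALSE)$counts / a$n_samples
  hb <- hist(b$samples, breaks = brk, plot = FALSE)$counts / b$n_samples
  sum(pmin(ha, hb))
}

.check_window_overlap <- function(ds, overlap_min) {
  if (length(ds) < 2) return(invisible(NULL))
  for (i in seq_len(length(ds) - 1)) {
    ov <- .window_overlap(ds[[i]], ds[[i + 1]])
    if (ov < overlap_min) {
      warning(sprintf(paste0("umbrella windows %d and %d (centers %.3g and ",
                             "%.3g nm) do not overlap (intersection %.3g)"),
                      i, i + 1, ds[[i]]$center, ds[[i + 1]]$center, ov))
    }
  }
  invisible(NULL)
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  cat(sprintf("Umbrella dataset: %d windows, centers %.3g..%.3g nm, k = %.3g kJ/mol/nm^2\n",
              length(x), x[[1]]$center, x[[length(x)]]$center, x[[1]]$spring_k))
  cat(sprintf("  samples per window: %s\n",
              paste(unique(vapply(x, `[[`, 1, "n_samples")), collapse = ", ")))
  invisible(x)
}
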