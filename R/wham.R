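#' WHAM configuration
#'
#' @param bin_width histogram bin width in nm (default 0.01).
#' @param tolerance convergence tolerance on the window free-energy
#'   constants f_i, kJ/mol (default 1e-6).
#' @param max_iterations iteration cap (default 1e5).
#' @param temperature temperature in K (default 310).
#' @param n_bootstrap bootstrap replicates for [bootstrap_pmf_error()]
#'   (default 200).
#' @param seed RNG seed for the bootstrap.
#' @param min_count gauge anchor threshold: the W = 0 shift uses only
#'   bins holding at least this many counts (default 50).  Anchoring the
#'   gauge on sparsely sampled bins would add their order-kT noise as a
#'   global offset to every bin (and to every bootstrap replicate).
#' @return object of class `wham_config`.
#' @export
wham_config <- function(bin_width = 0.01, tolerance = 1e-6,
                        max_iterations = 1e5, temperature = 310,
                        n_bootstrap = 200, seed = 1, min_count = 50) {
  stopifnot(bin_width > 0, tolerance > 0, max_iterations >= 1,
            temperature > 0, n_bootstrap >= 0, min_count >= 0)
  structure(list(bin_width = bin_width, tolerance = tolerance,
                 max_iterations = max_iterations, temperature = temperature,
                 n_bootstrap = n_bootstrap, seed = seed,
                 min_count = min_count, kT = kT_kJ_mol(temperature)),
            class = "wham_config")
}

# align a profile on reliably sampled bins: subtract the minimum over
# bins holding at least min_count counts (falls back to all populated
# bins).  Used to put bootstrap replicates into a common frame so that
# the order-kT noise of sparse bins does not enter every bin as a global
# offset.
.gauge_shift <- function(W, Cb, min_count) {
  anchor <- is.finite(W) & Cb >= min_count
  if (!any(anchor)) anchor <- is.finite(W)
  W - min(W[anchor])
}

#' Histogram umbrella windows on a common grid
#'
#' Bins every window's samples on one shared grid spanning the minimum and
#' maximum of all samples.  Counts are conserved: each row of the
#' histogram matrix sums to the window's sample count.
#'
#' @param windows an `umbrella_dataset` (or list of `umbrella_window`).
#' @param config a [wham_config()].
#' @return object of class `wham_histograms`: `bin_centers`, `counts`
#'   (n_windows x n_bins), `centers`, `spring_k`, `n_samples`, and
#'   `overlap` (adjacent-window histogram intersections).
#' @export
build_histograms <- function(windows, config = wham_config()) {
  stopifnot(length(windows) >= 1)
  for (i in seq_along(windows)) {
    if (length(windows[[i]]$samples) == 0) {
      stop("umbrella window ", i, " is empty")
    }
  }
  all_x <- unlist(lapply(windows, `[[`, "samples"))
  bw <- config$bin_width
  lo <- floor(min(all_x) / bw) * bw
  hi <- ceiling(max(all_x) / bw) * bw
  breaks <- seq(lo, hi + bw / 2, by = bw)
  centers <- breaks[-length(breaks)] + bw / 2
  counts <- t(vapply(windows, function(w) {
    tabulate(findInterval(w$samples, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(centers))
  }, numeric(length(centers))))
  nsamp <- vapply(windows, function(w) length(w$samples), numeric(1))
  stopifnot(all(rowSums(counts) == nsamp))
  ov <- if (nrow(counts) > 1) {
    vapply(seq_len(nrow(counts) - 1), function(i) {
      sum(pmin(counts[i, ] / nsamp[i], counts[i + 1, ] / nsamp[i + 1]))
    }, numeric(1))
  } else numeric(0)
  structure(list(bin_centers = centers, counts = counts,
                 centers = vapply(windows, `[[`, 1, "center"),
                 spring_k = vapply(windows, `[[`, 1, "spring_k"),
                 n_samples = nsamp, overlap = ov),
            class = "wham_histograms")
}

# Boltzmann factors of the harmonic biases on the common grid
.bias_matrix <- function(h, kT) {
  nb <- length(h$bin_centers)
  B <- matrix(0, nrow = nrow(h$counts), ncol = nb)
  for (i in seq_len(nrow(B))) {
    w <- 0.5 * h$spring_k[i] * (h$bin_centers - h$centers[i])^2
    B[i, ] <- exp(-w / kT)
  }
  B
}

# windows (with multiplicity > 0) must form a connected chain: adjacent
# retained windows share at least one bin where both have counts
.check_chain <- function(h, wmult = rep(1, nrow(h$counts))) {
  idx <- which(wmult > 0)
  if (length(idx) < 2) return(TRUE)
  for (k in seq_len(length(idx) - 1)) {
    i <- idx[k]; j <- idx[k + 1]
    if (!any(h$counts[i, ] > 0 & h$counts[j, ] > 0)) {
      return(sprintf("histogram chain broken between windows %d (center %.4g nm) and %d (center %.4g nm)",
                     i, h$centers[i], j, h$centers[j]))
    }
  }
  TRUE
}

#' Solve WHAM for the potential of mean force
#'
#' Self-consistent iteration of the unbiased bin probabilities
#' \eqn{P(\xi_b) = \sum_i h_i(b) / \sum_i N_i e^{(f_i - w_i(\xi_b))/k_BT}}
#' and window constants
#' \eqn{f_i = -k_BT \log \sum_b P(\xi_b) e^{-w_i(\xi_b)/k_BT}}
#' until the largest change in any \eqn{f_i} falls below the tolerance.
#' The PMF is \eqn{W = -k_BT \log P}, gauge-shifted so its minimum over
#' populated bins is exactly 0; bins without counts get `W = Inf`.
#'
#' @param x an `umbrella_dataset` or a `wham_histograms` object.
#' @param config a [wham_config()].
#' @param f0 optional starting window constants (warm start).
#' @return object of class `pmf_profile`: `bin_centers`, `W`, `stderr`
#'   (NULL until [bootstrap_pmf_error()] is run), `f` (window constants),
#'   `n_iterations`, `converged`.
#' @export
solve_wham <- function(x, config = wham_config(), f0 = NULL) {
  h <- if (inherits(x, "wham_histograms")) x else build_histograms(x, config)
  chain <- .check_chain(h)
  if (!isTRUE(chain)) stop(chain)
  kT <- config$kT
  B <- .bias_matrix(h, kT)
  if (is.null(f0)) f0 <- numeric(nrow(h$counts))
  res <- wham_cpp(h$counts, B, h$n_samples, rep(1, nrow(h$counts)), kT,
                  config$tolerance, config$max_iterations, f0)
  if (!res$converged) {
    warning("WHAM did not converge within ", config$max_iterations,
            " iterations")
  }
  W <- ifelse(res$P > 0, -kT * log(res$P), Inf)
  W <- W - min(W[is.finite(W)])
  structure(list(bin_centers = h$bin_centers, W = W, stderr = NULL,
                 f = res$f, n_iterations = res$n_iterations,
                 converged = res$converged, histograms = h, config = config),
            class = "pmf_profile")
}

#' Window-level bootstrap errors for a WHAM profile
#'
#' Resamples complete windows (histograms as independent data points) with
#' replacement, re-solves WHAM for each replicate (warm-started from the
#' full solution), and reports the per-bin standard deviation of the
#' replicate profiles.  Replicates whose resampled chain is disconnected
#' are discarded and counted; a warning is issued if more than 20% are
#' lost.
#'
#' @param windows an `umbrella_dataset`.
#' @param config a [wham_config()]; `n_bootstrap` and `seed` control the
#'   resampling.
#' @param profile optional pre-computed [solve_wham()] result for the full
#'   dataset (recomputed if missing).
#' @return the `pmf_profile` with `stderr` filled in (per bin, kJ/mol) and
#'   attributes `n_discarded` and `n_bootstrap`.
#' @export
bootstrap_pmf_error <- function(windows, config = wham_config(),
                                profile = NULL) {
  stopifnot(length(windows) >= 2)
  if (is.null(profile)) profile <- solve_wham(windows, config)
  h <- profile$histograms
  kT <- config$kT
  B <- .bias_matrix(h, kT)
  nw <- nrow(h$counts)
  nb <- length(h$bin_centers)
  if (!is.null(config$seed)) set.seed(config$seed)
  reps <- matrix(NA_real_, nrow = config$n_bootstrap, ncol = nb)
  discarded <- 0L
  for (r in seq_len(config$n_bootstrap)) {
    pick <- sample.int(nw, nw, replace = TRUE)
    wmult <- tabulate(pick, nbins = nw)
    if (!isTRUE(.check_chain(h, wmult))) {
      discarded <- discarded + 1L
      next
    }
    res <- wham_cpp(h$counts, B, h$n_samples, wmult, kT, config$tolerance,
                    config$max_iterations, profile$f)
    Cb <- as.numeric(wmult %*% h$counts)
    W <- ifelse(Cb > 0 & res$P > 0, -kT * log(res$P), NA_real_)
    W[is.na(W)] <- Inf
    W <- .gauge_shift(W, Cb, config$min_count)
    W[!is.finite(W)] <- NA_real_
    reps[r, ] <- W
  }
  if (discarded > 0.2 * config$n_bootstrap) {
    warning(discarded, " of ", config$n_bootstrap,
            " bootstrap replicates had a disconnected histogram chain and were discarded")
  }
  profile$stderr <- apply(reps, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) >= 2) stats::sd(col) else if (length(col) >= 1) 0 else NA_real_
  })
  # bins never populated keep an undefined error
  profile$stderr[!is.finite(profile$W)] <- NA_real_
  attr(profile, "n_discarded") <- discarded
  attr(profile, "n_bootstrap") <- config$n_bootstrap
  profile
}

#' Summarise a PMF profile
#'
#' Reports the unbinding free energy (mean PMF over the terminal plateau),
#' the barrier (maximum PMF over populated bins), the position of the
#' minimum, and the onset of the plateau.  The plateau is the longest
#' terminal stretch where the local slope |dW/dxi| stays below
#' `slope_max`; when none of at least `min_length` nm exists, the summary
#' falls back to `dG_unbind = max(W)` and sets `no_plateau = TRUE`.
#'
#' @param profile a `pmf_profile`.
#' @param slope_max plateau slope threshold, kJ/mol/nm (default 10).
#' @param min_length minimum plateau length in nm (default 0.2).
#' @param slope_scale separation (nm) over which the local slope is
#'   estimated (default 0.1; coarser than one bin so per-bin noise does
#'   not masquerade as slope).
#' @param min_count bins with fewer total counts than this are ignored by
#'   the summary (default 50): sparsely visited edge bins carry
#'   free-energy noise of order kT that would otherwise dominate the
#'   barrier and slope estimates.
#' @return list with `dG_unbind`, `barrier` (kJ/mol), `xi_min`,
#'   `xi_plateau` (nm), `no_plateau` (flag).
#' @export
pmf_summary <- function(profile, slope_max = 10, min_length = 0.2,
                        slope_scale = 0.1, min_count = 50) {
  stopifnot(inherits(profile, "pmf_profile"))
  ok <- is.finite(profile$W)
  if (!is.null(profile$histograms)) {
    ok <- ok & colSums(profile$histograms$counts) >= min_count
  }
  xi <- profile$bin_centers[ok]
  W <- profile$W[ok]
  if (length(W) < 3) stop("profile has fewer than 3 populated bins")
  barrier <- max(W)
  xi_min <- xi[which.min(W)]
  m <- max(1L, min(round(slope_scale / mean(diff(xi))), length(W) - 1L))
  ii <- seq_len(length(W) - m)
  slope <- abs((W[ii + m] - W[ii]) / (xi[ii + m] - xi[ii]))
  # walk back from the end while the coarse slope stays flat
  i <- length(slope)
  while (i >= 1 && slope[i] <= slope_max) i <- i - 1
  plateau_idx <- if (i < length(slope)) (i + 1):length(W) else integer(0)
  # measure relative to the well-sampled minimum, not the gauge zero:
  # the global minimum may sit in a sparse bin carrying order-kT noise
  W0 <- min(W)
  if (length(plateau_idx) >= 2 &&
      (xi[max(plateau_idx)] - xi[min(plateau_idx)]) >= min_length) {
    list(dG_unbind = mean(W[plateau_idx]) - W0, barrier = barrier - W0,
         xi_min = xi_min, xi_plateau = xi[min(plateau_idx)],
         no_plateau = FALSE)
  } else {
    list(dG_unbind = barrier - W0, barrier = barrier - W0, xi_min = xi_min,
         xi_plateau = NA_real_, no_plateau = TRUE)
  }
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$W)
  cat(sprintf("PMF profile: %d bins (%d populated), xi %.3g..%.3g nm\n",
              length(x$W), sum(ok), min(x$bin_centers), max(x$bin_centers)))
  cat(sprintf("  WHAM: %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              as.integer(x$n_iterations)))
  cat(sprintf("  max W: %.2f kJ/mol", max(x$W[ok])))
  if (!is.null(x$stderr)) {
    cat(sprintf(", median stderr: %.3f kJ/mol",
                stats::median(x$stderr, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
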