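# Independent brute-force WHAM oracle: plain-R fixed-point iteration of
# the self-consistency equations on given histogram counts, run to a
# much tighter tolerance than the implementation under test.  Shares no
# code with solve_wham()/wham_cpp().
brute_force_wham <- function(counts, bin_centers, centers, spring_k,
                             n_samples, kT, tol = 1e-12, max_iter = 1e6) {
  nw <- nrow(counts)
  nb <- ncol(counts)
  Cb <- colSums(counts)
  w <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    w[i, ] <- 0.5 * spring_k[i] * (bin_centers - centers[i])^2
  }
  f <- rep(0, nw)
  for (it in seq_len(max_iter)) {
    P <- numeric(nb)
    for (b in seq_len(nb)) {
      if (Cb[b] == 0) next
      denom <- 0
      for (i in seq_len(nw)) {
        denom <- denom + n_samples[i] * exp((f[i] - w[i, b]) / kT)
      }
      P[b] <- Cb[b] / denom
    }
    P <- P / sum(P)
    fnew <- numeric(nw)
    for (i in seq_len(nw)) {
      fnew[i] <- -kT * log(sum(P * exp(-w[i, ] / kT)))
    }
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  W <- ifelse(P > 0, -kT * log(P), Inf)
  W - min(W[is.finite(W)])
}

# hand-built two-window toy dataset with four populated bins
toy_two_window_dataset <- function() {
  w1 <- structure(list(center = 1.00, spring_k = 1000,
                       samples = c(rep(1.001, 5), rep(1.011, 3), rep(1.021, 2)),
                       n_samples = 10L), class = "umbrella_window")
  w2 <- structure(list(center = 1.02, spring_k = 1000,
                       samples = c(rep(1.011, 2), rep(1.021, 4), rep(1.031, 4)),
                       n_samples = 10L), class = "umbrella_window")
  structure(list(w1, w2), class = "umbrella_dataset", temperature = 310)
}

# small structure from bare coordinates (one residue per atom)
coords_structure <- function(xyz, name = "CA", element = "C") {
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = name, element = element, resid = "GLY",
    resno = seq_len(n), chain = "A", insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
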