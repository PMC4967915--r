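test_that("umbrella-biased sampling of a flat landscape is the harmonic Boltzmann distribution", {
  fl <- make_unbinding_landscape(0)
  tr <- simulate_overdamped(fl, bias_spec("umbrella", center = 2, spring_k = 1000),
                            langevin_params(n_steps = 3e6, seed = 7),
                            sample_every = 100)
  kT <- kT_kJ_mol(310)
  expect_equal(mean(tr$xi), 2.0, tolerance = 0.005)
  expect_equal(var(tr$xi), kT / 1000, tolerance = 0.1)
})

test_that("flat-landscape umbrella samples pass a chi-squared normality screen across seeds", {
  # variance k_BT/k Gaussian, 10 equiprobable bins, alpha = 0.01;
  # samples spaced six relaxation times apart so they are effectively
  # independent
  fl <- make_unbinding_landscape(0)
  kT <- kT_kJ_mol(310)
  brk <- qnorm(seq(0.1, 0.9, by = 0.1), 2, sqrt(kT / 1000))
  crit <- qchisq(0.99, df = 9)
  stride <- 6 * ceiling(kT / 1000 / 1e-5)
  passes <- 0
  for (s in 1:100) {
    tr <- simulate_overdamped(fl, bias_spec("umbrella", center = 2, spring_k = 1000),
                              langevin_params(n_steps = 2000 * stride, seed = s),
                              sample_every = stride)
    cnt <- hist(tr$xi, breaks = c(-Inf, brk, Inf), plot = FALSE)$counts
    if (sum((cnt - 200)^2 / 200) < crit) passes <- passes + 1
  }
  expect_gte(passes, 95)
})

test_that("long unbiased double-well run reproduces Boltzmann well occupancies", {
  dw <- make_unbinding_landscape(6, bound_min = 1.0, plateau_start = 2.0,
                                 shoulder = c(1.5, 5.5))
  kT <- kT_kJ_mol(310)
  grid <- seq(dw$domain[1], dw$domain[2], by = 1e-3)
  U <- landscape_energy(dw, grid)
  Z <- sum(exp(-U / kT))
  pA_th <- sum(exp(-U[grid <= 1.25] / kT)) / Z
  pB_th <- sum(exp(-U[grid > 1.25 & grid <= 1.8] / kT)) / Z
  tr <- simulate_overdamped(dw, params = langevin_params(n_steps = 1e8, seed = 5),
                            xi0 = 1.2, sample_every = 100)
  pA <- mean(tr$xi <= 1.25)
  pB <- mean(tr$xi > 1.25 & tr$xi <= 1.8)
  expect_lt(abs(pA / pA_th - 1), 0.05)
  expect_lt(abs(pB / pB_th - 1), 0.05)
})

test_that("sampling is deterministic under a fixed seed and noiseless at D = 0", {
  ls64 <- make_unbinding_landscape(64)
  p <- langevin_params(n_steps = 1e4, seed = 42)
  a <- simulate_overdamped(ls64, params = p, xi0 = 1.5)
  b <- simulate_overdamped(ls64, params = p, xi0 = 1.5)
  expect_identical(a$xi, b$xi)
  # D = 0: deterministic descent to the nearest minimum (the bound shelf)
  d0 <- simulate_overdamped(ls64, params = langevin_params(diffusion = 0,
                                                           n_steps = 1e6),
                            xi0 = 1.8, sample_every = 100)
  expect_true(all(diff(d0$xi) <= 1e-12))
  # approach to the shelf is asymptotic (the flank slope vanishes there)
  expect_lt(tail(d0$xi, 1), 1.005)
})

test_that("initial positions outside the domain and unstable steps are rejected", {
  ls64 <- make_unbinding_landscape(64)
  expect_error(simulate_overdamped(ls64, params = langevin_params(n_steps = 10),
                                   xi0 = 5), "domain")
  expect_error(simulate_overdamped(ls64, bias_spec("umbrella", center = 2,
                                                   spring_k = 1000),
                                   langevin_params(timestep = 1e-2, n_steps = 10)),
               "unstable")
})

test_that("rupture force grows with pulling velocity and vanishes for a free spring", {
  ls64 <- make_unbinding_landscape(64)
  med <- vapply(c(0.1, 1.0), function(v) {
    median(vapply(1:3, function(s) {
      run_constant_velocity_pull(ls64,
        bias_spec("moving_spring", center = 1, velocity = v),
        langevin_params(seed = 200 + s))$f_max_pN
    }, numeric(1)))
  }, numeric(1))
  expect_lt(med[1], med[2])
  # k = 0: no spring force at all
  tr0 <- run_constant_velocity_pull(ls64,
    bias_spec("moving_spring", center = 1, spring_k = 0, velocity = 1),
    langevin_params(seed = 1))
  expect_equal(tr0$f_max_raw_pN, 0)
  expect_true(all(tr0$force_pN == 0))
})

test_that("near-zero pulling velocity on a flat landscape gives a friction-limited force", {
  fl <- make_unbinding_landscape(0)
  tr <- run_constant_velocity_pull(fl,
    bias_spec("moving_spring", center = 1, velocity = 0.001),
    langevin_params(seed = 9), target = 1.02)
  expect_lt(tr$f_max_pN, 10)
})

test_that("pulling beyond the landscape domain is refused", {
  ls64 <- make_unbinding_landscape(64)
  expect_error(run_constant_velocity_pull(ls64,
    bias_spec("moving_spring", center = 1, velocity = 1),
    langevin_params(seed = 1), target = 4.0), "domain")
  expect_error(run_constant_velocity_pull(ls64, bias_spec("umbrella", center = 1),
                                          langevin_params(seed = 1)),
               "moving_spring")
})

test_that("umbrella datasets have the requested geometry and warn on non-overlap", {
  fl <- make_unbinding_landscape(0)
  ds <- generate_umbrella_dataset(fl, c(1.0, 1.05, 1.1),
                                  params = langevin_params(seed = 3),
                                  n_samples = 2000)
  expect_length(ds, 3)
  expect_true(all(vapply(ds, function(w) w$n_samples, numeric(1)) == 2000))
  # single window is a valid dataset
  one <- generate_umbrella_dataset(fl, 2.0, params = langevin_params(seed = 3),
                                   n_samples = 500)
  expect_length(one, 1)
  # widely spaced windows on a steep landscape do not overlap
  ls64 <- make_unbinding_landscape(64)
  expect_warning(generate_umbrella_dataset(ls64, c(1.0, 2.0),
                                           params = langevin_params(seed = 3),
                                           n_samples = 1000),
                 "do not overlap")
  expect_error(generate_umbrella_dataset(fl, c(1.0, 1.0),
                                         params = langevin_params(seed = 3)),
               "increasing")
})

test_that("pullx files round-trip through the xvg dialect", {
  ds <- generate_umbrella_dataset(make_unbinding_landscape(0), c(1.0, 1.05),
                                  params = langevin_params(seed = 3),
                                  n_samples = 200, dir = withr::local_tempdir())
  dir <- withr::local_tempdir()
  man <- write_umbrella_dataset(ds, dir)
  back <- read_umbrella_dataset(man)
  expect_equal(back[[1]]$center, ds[[1]]$center)
  expect_equal(back[[2]]$samples, ds[[2]]$samples, tolerance = 1e-7)
})
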