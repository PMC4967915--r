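test_that("histogramming conserves counts and matches direct counting", {
  ds <- toy_two_window_dataset()
  h <- build_histograms(ds, wham_config())
  expect_equal(rowSums(h$counts), c(10, 10))
  # hand-counted fixture: samples were placed at known bin positions
  expect_equal(h$counts[1, ], c(5, 3, 2, 0))
  expect_equal(h$counts[2, ], c(0, 2, 4, 4))
  # all samples in one bin
  one <- structure(list(structure(list(center = 1, spring_k = 1000,
                                       samples = rep(1.001, 7),
                                       n_samples = 7L),
                                  class = "umbrella_window")),
                   class = "umbrella_dataset")
  h1 <- build_histograms(one, wham_config())
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(sum(h1$counts), 7)
  # empty windows are rejected by index
  bad <- structure(list(structure(list(center = 1, spring_k = 1000,
                                       samples = numeric(0), n_samples = 0L),
                                  class = "umbrella_window")),
                   class = "umbrella_dataset")
  expect_error(build_histograms(bad, wham_config()), "window 1")
})

test_that("WHAM matches an independent brute-force fixed point on a 4-bin toy", {
  ds <- toy_two_window_dataset()
  cfg <- wham_config(tolerance = 1e-10)
  h <- build_histograms(ds, cfg)
  prof <- solve_wham(ds, cfg)
  W_oracle <- brute_force_wham(h$counts, h$bin_centers, h$centers,
                               h$spring_k, h$n_samples, cfg$kT)
  expect_true(prof$converged)
  expect_equal(prof$W, W_oracle, tolerance = 1e-6)
})

test_that("a single harmonic window on a flat landscape yields a flat PMF", {
  fl <- make_unbinding_landscape(0)
  ds <- generate_umbrella_dataset(fl, 2.0, params = langevin_params(seed = 21),
                                  n_samples = 5e5)
  prof <- solve_wham(ds, wham_config())
  # flatness holds up to Poisson count noise, so look at bins whose
  # free-energy noise kT/sqrt(n) is well below the 0.2 kJ/mol band
  ok <- is.finite(prof$W) & colSums(prof$histograms$counts) >= 5000
  expect_true(prof$converged)
  expect_lt(diff(range(prof$W[ok])), 0.2)
})

test_that("WHAM is gauge invariant in the starting constants", {
  ds <- toy_two_window_dataset()
  cfg <- wham_config()
  a <- solve_wham(ds, cfg, f0 = c(0, 0))
  b <- solve_wham(ds, cfg, f0 = c(7.3, 7.3))
  expect_lt(max(abs(a$W - b$W)), cfg$tolerance * 10)
})

test_that("a disconnected histogram chain is reported with the break location", {
  w1 <- structure(list(center = 1.0, spring_k = 1000,
                       samples = rep(1.0, 50), n_samples = 50L),
                  class = "umbrella_window")
  w2 <- structure(list(center = 3.0, spring_k = 1000,
                       samples = rep(3.0, 50), n_samples = 50L),
                  class = "umbrella_window")
  ds <- structure(list(w1, w2), class = "umbrella_dataset")
  expect_error(solve_wham(ds, wham_config()), "chain broken")
})

test_that("WHAM recovers model barriers of 20, 40 and 75 kJ/mol within 2 kJ/mol", {
  centers <- seq(1, 3.3, by = 0.05)
  for (b in c(20, 40, 75)) {
    lsb <- make_unbinding_landscape(b)
    ds <- generate_umbrella_dataset(lsb, centers,
                                    params = langevin_params(seed = 11),
                                    n_samples = 1e5)
    sm <- pmf_summary(solve_wham(ds, wham_config()))
    expect_lt(abs(sm$dG_unbind - b), 2)
    expect_lt(abs(sm$barrier - b), 2)
  }
})

test_that("bootstrap degenerate cases behave as documented", {
  fl <- make_unbinding_landscape(0)
  ds <- generate_umbrella_dataset(fl, c(1.0, 1.05),
                                  params = langevin_params(seed = 4),
                                  n_samples = 2000)
  # a single replicate has zero spread
  p1 <- bootstrap_pmf_error(ds, wham_config(n_bootstrap = 1, seed = 2))
  expect_true(all(p1$stderr[!is.na(p1$stderr)] == 0))
  # seeded and reproducible
  p2 <- bootstrap_pmf_error(ds, wham_config(n_bootstrap = 25, seed = 5))
  p3 <- bootstrap_pmf_error(ds, wham_config(n_bootstrap = 25, seed = 5))
  expect_identical(p2$stderr, p3$stderr)
  expect_error(bootstrap_pmf_error(ds[1], wham_config()))
})

test_that("pmf_summary flags profiles without a terminal plateau", {
  ramp <- structure(list(bin_centers = seq(1, 2, by = 0.01),
                         W = seq(0, 50, length.out = 101),
                         stderr = NULL, histograms = NULL,
                         n_iterations = 1, converged = TRUE),
                    class = "pmf_profile")
  sm <- pmf_summary(ramp)
  expect_true(sm$no_plateau)
  expect_equal(sm$dG_unbind, 50)
  flat <- structure(list(bin_centers = seq(1, 2, by = 0.01),
                         W = rep(0, 101), stderr = NULL, histograms = NULL,
                         n_iterations = 1, converged = TRUE),
                    class = "pmf_profile")
  smf <- pmf_summary(flat)
  expect_false(smf$no_plateau)
  expect_equal(smf$dG_unbind, 0)
})

test_that("PMF profiles write and re-read as TSV", {
  ds <- toy_two_window_dataset()
  prof <- solve_wham(ds, wham_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf_tsv(prof, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$xi, prof$bin_centers)
  expect_equal(back$W, prof$W, tolerance = 1e-12)
})
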