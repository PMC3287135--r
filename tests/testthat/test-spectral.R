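make_series <- function(x, dt = 1) {
  sampled_series(matrix(x, ncol = 1, dimnames = list(NULL, "A")),
                 sampling_config(length(x), dt))
}

test_that("sampling grid arithmetic is exact", {
  sc <- sampling_config(4000, 1)
  expect_identical(sc$freq_resolution * sc$N * sc$dt, 1)
  expect_identical(sc$f_max * 2 * sc$dt, 1)
  sc2 <- sampling_config(250, 0.2)
  expect_equal(sc2$window, 50)
  expect_equal(sc2$freq_resolution, 1 / 50)
  expect_equal(sc2$f_max, 2.5)
})

test_that("resample takes the last value at or before each sample time", {
  tr <- structure(list(times = c(0, 1.4),
                       states = matrix(c(5, 6), 2, 1,
                                       dimnames = list(NULL, "A")),
                       species = "A", seed = 0, n_events = 1,
                       terminated_reason = "t_max reached"),
                  class = "trajectory")
  s <- resample(tr, sampling_config(3, 1))
  expect_equal(unname(s$values[, 1]), c(5, 5, 6))
  # single event at t=0: constant series (final value carried forward)
  tr0 <- tr; tr0$times <- 0; tr0$states <- tr$states[1, , drop = FALSE]
  expect_equal(unname(resample(tr0, sampling_config(4, 1))$values[, 1]),
               rep(5, 4))
  # random event trajectory agrees with a naive per-sample scan
  set.seed(3)
  times <- c(0, sort(runif(200, 0, 20)))
  states <- matrix(cumsum(c(10, sample(c(-1, 1), 200, replace = TRUE))),
                   ncol = 1, dimnames = list(NULL, "A"))
  trr <- tr; trr$times <- times; trr$states <- states
  sc <- sampling_config(40, 0.5)
  got <- resample(trr, sc)$values[, 1]
  naive <- vapply(0:39 * 0.5, function(tt)
    states[max(which(times <= tt)), 1], 0.0)
  expect_equal(unname(got), unname(naive))
})

test_that("amplitude spectrum matches DFT closed forms and brute force", {
  N <- 64
  # constant series: all mass in the DC bin
  sp <- amplitude_spectrum(make_series(rep(3, N)))
  expect_equal(unname(sp$amplitudes[1, 1]), N * 3)
  expect_lt(max(sp$amplitudes[-1, 1]), 1e-9 * N)
  # cosine at an exact bin: N/2 in that bin only
  for (k in c(1, 5, 31)) {
    x <- cos(2 * pi * k * (0:(N - 1)) / N)
    sp <- amplitude_spectrum(make_series(x))
    expect_equal(unname(sp$amplitudes[k + 1, 1]), N / 2, tolerance = 1e-9)
    expect_lt(max(sp$amplitudes[-(k + 1), 1]), 1e-9 * N)
  }
  # frequency grid
  sp <- amplitude_spectrum(make_series(rnorm(100), dt = 2))
  expect_equal(sp$freq, (0:50) / 200)
  expect_error(amplitude_spectrum(make_series(c(1, NA, 2, 3))),
               "non-finite")
})

test_that("FFT path equals direct O(N^2) DFT on random inputs", {
  set.seed(42)
  for (rep in 1:100) {
    N <- sample(4:64, 1)
    x <- sample(0:50, N, replace = TRUE)
    z <- one_sided(dft_brute(x))
    sp <- amplitude_spectrum(make_series(x))
    expect_equal(sp$amplitudes[, 1], Mod(z), tolerance = 1e-9)
    ph <- phase_spectrum(make_series(x))
    keep <- !ph$undefined[, 1]
    expect_lt(max(phase_diff(ph$phase[keep, 1], Arg(z)[keep]), 0), 1e-9)
  }
})

test_that("phase spectrum has the four-quadrant angles", {
  N <- 32; k <- 3
  n <- 0:(N - 1)
  cosx <- phase_spectrum(make_series(cos(2 * pi * k * n / N)))
  expect_equal(unname(cosx$phase[k + 1, 1]), 0, tolerance = 1e-9)
  sinx <- phase_spectrum(make_series(sin(2 * pi * k * n / N)))
  expect_equal(unname(sinx$phase[k + 1, 1]), -pi / 2, tolerance = 1e-9)
  # zero-amplitude bins are flagged undefined
  expect_true(all(cosx$undefined[-(k + 1), 1] |
                    abs(cosx$phase[-(k + 1), 1]) >= 0))
  expect_true(cosx$undefined[2, 1])
})

test_that("Parseval holds for every transform", {
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(c(16, 31, 64, 100), 1)
    x <- rnorm(N, 50, 10)
    two_sided <- Mod(stats::fft(x))
    expect_equal(sum(two_sided^2), N * sum(x^2), tolerance = 1e-9)
    # one-sided package spectrum reconstructs the two-sided energy
    sp <- amplitude_spectrum(make_series(x))$amplitudes[, 1]
    inner <- 2:(ceiling(N / 2))   # bins with a mirror image
    energy <- sp[1]^2 + sum(2 * sp[inner]^2) +
      if (N %% 2 == 0) sp[N / 2 + 1]^2 else 0
    expect_equal(energy, N * sum(x^2), tolerance = 1e-9)
  }
})

test_that("average spectrum is the term-wise mean, batch or incremental", {
  sA <- amplitude_spectrum(make_series(c(0, 2, 0, 2)))
  sB <- amplitude_spectrum(make_series(c(2, 0, 2, 0)))
  avg <- average_spectrum(list(sA, sB))
  expect_equal(avg$mean, (sA$amplitudes + sB$amplitudes) / 2)
  expect_equal(avg$K, 2L)
  # K identical spectra average to themselves
  same <- average_spectrum(list(sA, sA, sA))
  expect_equal(same$mean, sA$amplitudes)
  # incremental = batch to 1e-12 relative on 100 random spectra
  set.seed(8)
  specs <- lapply(1:100, function(i)
    amplitude_spectrum(make_series(rnorm(32, 20, 5))))
  batch <- Reduce(`+`, lapply(specs, `[[`, "amplitudes")) / 100
  inc <- average_spectrum(specs[1])
  for (i in 2:100) inc <- update_average_spectrum(inc, specs[[i]])
  expect_equal(inc$mean, batch, tolerance = 1e-12)
  expect_error(update_average_spectrum(
    inc, amplitude_spectrum(make_series(rnorm(16)))), "grids")
})

test_that("K-S distance matches hand cumulative sums and its invariants", {
  as_avg <- function(v) {
    structure(list(mean = matrix(v, ncol = 1,
                                 dimnames = list(NULL, "A")),
                   m2 = matrix(0, length(v), 1), K = 1L,
                   freq = seq_along(v) - 1, N = 2 * (length(v) - 1),
                   dt = 1, species = "A"),
              class = "average_spectrum")
  }
  expect_equal(unname(ks_distance(as_avg(c(1, 1, 2)),
                                  as_avg(c(2, 1, 1)))$D), 0.25)
  expect_equal(unname(ks_distance(as_avg(c(1, 0)), as_avg(c(0, 1)))$D), 1)
  expect_equal(unname(ks_distance(as_avg(c(3, 1, 4)),
                                  as_avg(c(3, 1, 4)))$D), 0)
  expect_error(ks_distance(as_avg(c(0, 0)), as_avg(c(1, 1))), "all-zero")
  # symmetry, range and brute-force agreement on 1000 random pairs
  set.seed(13)
  for (i in 1:1000) {
    a <- runif(8); b <- runif(8)
    d1 <- unname(ks_distance(as_avg(a), as_avg(b))$D)
    d2 <- unname(ks_distance(as_avg(b), as_avg(a))$D)
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(d1, ks_brute(a, b))
  }
})

test_that("procedure A averages per species and supports extension", {
  net <- birth_death(kb = 50, kd = 1)
  sc <- sampling_config(256, 1)
  # K = 1: the average is the single run's spectrum
  avg1 <- procedure_A(net, sc, K = 1, base_seed = 5)
  run1 <- simulate_network(net, sim_config(sc$window,
                                           seed = derive_seed(5, 1),
                                           record = "grid"), sampling = sc)
  expect_equal(avg1$mean, amplitude_spectrum(run1)$amplitudes)
  # determinism
  expect_equal(procedure_A(net, sc, K = 10, base_seed = 5),
               procedure_A(net, sc, K = 10, base_seed = 5))
  # incremental extension reproduces the one-shot ensemble
  a10 <- procedure_A(net, sc, K = 10, base_seed = 5)
  a4 <- procedure_A(net, sc, K = 4, base_seed = 5)
  a10b <- procedure_A(net, sc, K = 6, base_seed = 5, previous = a4)
  expect_equal(a10b$mean, a10$mean, tolerance = 1e-12)
  expect_equal(a10b$K, 10L)
  # relaxation spectrum: DC dominant, high-frequency tail flat and low
  avg <- procedure_A(net, sc, K = 30, base_seed = 6)
  expect_equal(unname(which.max(avg$mean[, 1])), 1)
  tail_band <- avg$mean[100:129, 1]
  expect_lt(mean(tail_band), 0.05 * avg$mean[1, 1])
})

test_that("procedure B measures null differences small and real ones large", {
  net <- birth_death(kb = 50, kd = 1)
  fast <- birth_death(kb = 200, kd = 4)   # same mean, 4x faster relaxation
  sc <- sampling_config(256, 1)
  null <- procedure_B(net, net, sc, K = 40, base_seed = 3)
  diff <- procedure_B(net, fast, sc, K = 40, base_seed = 3)
  expect_lt(unname(null$D["A"]), unname(diff$D["A"]))
  # renaming a species does not change the dynamics: under shared seeds
  # the traces are identical and D = 0 exactly on the common species
  two <- reaction_network(c(A = 0, B = 0), list(
    reaction(character(), "A", mass_action(50)),
    reaction("A", character(), mass_action(1)),
    reaction("A", c("A", "B"), mass_action(0.2)),
    reaction("B", character(), mass_action(0.5))), "count")
  renamed <- two
  names(renamed$species)[2] <- "Z"
  renamed$reactions <- lapply(renamed$reactions, function(r) {
    names(r$reactants) <- sub("^B$", "Z", names(r$reactants))
    names(r$products) <- sub("^B$", "Z", names(r$products))
    r
  })
  shared <- procedure_B(two, renamed, sc, K = 5, base_seed = 3,
                        shared_seeds = TRUE)
  expect_identical(unname(shared$D["A"]), 0)
  expect_equal(unname(shared$spectrum_a$mean),
               unname(shared$spectrum_b$mean))
  expect_error(procedure_B(net, fast, sc, 2, 1, species = "missing"),
               "missing")
})

test_that("coefficient-of-variation convergence criterion", {
  sA <- amplitude_spectrum(make_series(c(1, 1, 1, 1)))
  same <- average_spectrum(list(sA, sA, sA))
  cc <- convergence_cov(same)
  expect_true(all(cc$cov[same$mean > cc$floor] == 0))
  expect_true(all(cc$pass))
  # two one-bin spectra [1] and [3]: mean 2, sd sqrt(2), CoV of mean 0.5
  one_bin <- function(v)
    structure(list(amplitudes = matrix(v, 1, 1,
                                       dimnames = list(NULL, "A")),
                   freq = 0, N = 2, dt = 1, species = "A"),
              class = "amplitude_spectrum")
  avg <- average_spectrum(list(one_bin(1), one_bin(3)))
  cc <- convergence_cov(avg)
  expect_equal(unname(cc$cov[1, 1]), 0.5)
  expect_false(cc$pass[["A"]])
  expect_true(convergence_cov(avg, threshold = 0.5)$pass[["A"]])
})

test_that("CoV of spectral means decays like 1 / sqrt(K)", {
  net <- birth_death(kb = 50, kd = 1)
  sc <- sampling_config(128, 1)
  Ks <- c(8, 16, 32, 64)
  mean_cov <- vapply(Ks, function(K) {
    avg <- procedure_A(net, sc, K = K, base_seed = 21)
    cc <- convergence_cov(avg)
    mean(cc$cov[avg$mean[, 1] > cc$floor, 1])
  }, 0.0)
  slope <- coef(lm(log(mean_cov) ~ log(Ks)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("amplitude averaging preserves structure that time averaging loses", {
  # K unit sinusoids with random phase on a DC pedestal: the mean amplitude
  # spectrum keeps the oscillatory peak at full strength while the spectrum
  # of the time-domain mean decays like |sum of unit phasors| / K
  N <- 512; k <- 20; K <- 50
  n <- 0:(N - 1)
  set.seed(1)
  ds <- replicate(9, {
    xs <- lapply(1:K, function(i)
      0.5 + cos(2 * pi * k * n / N + runif(1, 0, 2 * pi)))
    avg_amp <- average_spectrum(lapply(xs, function(x)
      amplitude_spectrum(make_series(x))))
    time_mean <- amplitude_spectrum(make_series(Reduce(`+`, xs) / K))
    tm_avg <- structure(list(mean = time_mean$amplitudes,
                             m2 = time_mean$amplitudes * 0, K = 1L,
                             freq = avg_amp$freq, N = N, dt = 1,
                             species = "A"),
                        class = "average_spectrum")
    unname(ks_distance(avg_amp, tm_avg)$D)
  })
  expect_gt(median(ds), 0.3)
})
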