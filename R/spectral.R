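# Frequency-domain characterisation of stochastic trajectories:
# regular-grid resampling, DFT amplitude spectra, ensemble averages and the
# Kolmogorov-Smirnov behavioural distance.

#' Sampling configuration
#'
#' `N` samples at spacing `dt` observe the system for `N * dt` minutes, give
#' a frequency resolution of `1 / (N * dt)` and a maximum observable
#' frequency of `1 / (2 * dt)` (cycles/min). The defaults (N = 4000,
#' dt = 1 min) resolve 0.00025 cycles/min up to 0.5 cycles/min.
#'
#' @param N number of samples (>= 2).
#' @param dt sampling interval, minutes.
#' @return A `sampling_config` with derived fields `window`,
#'   `freq_resolution` and `f_max`.
#' @export
sampling_config <- function(N = 4000, dt = 1) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2, N == round(N),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  N <- as.integer(N)
  structure(list(N = N, dt = dt, window = N * dt,
                 freq_resolution = 1 / (N * dt), f_max = 1 / (2 * dt)),
            class = "sampling_config")
}

#' @export
print.sampling_config <- function(x, ...) {
  cat(sprintf(paste0("<sampling_config> N=%d, dt=%g min; window %g min, ",
                     "resolution %g cycles/min, max frequency %g cycles/min\n"),
              x$N, x$dt, x$window, x$freq_resolution, x$f_max))
  invisible(x)
}

#' Regularly sampled series
#'
#' Container for per-species series on the regular grid `0, dt, ...,
#' (N-1) dt`; usually produced by [resample()] or grid-recording
#' simulation.
#'
#' @param values numeric matrix, N rows, one column per species.
#' @param config a [sampling_config()].
#' @return A `sampled_series`.
#' @export
sampled_series <- function(values, config) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  stopifnot(inherits(config, "sampling_config"), nrow(values) == config$N)
  structure(list(values = values, config = config,
                 species = colnames(values)),
            class = "sampled_series")
}

#' Resample an event trajectory onto a regular grid
#'
#' Last-value sampling: `x_n` is the state recorded at the latest event time
#' at or before `n * dt` (last observation carried forward). Trajectories
#' that terminate before the end of the grid have their final value carried
#' forward.
#'
#' @param traj a `trajectory` from [simulate_network()].
#' @param cfg a [sampling_config()].
#' @param species optional character vector selecting species.
#' @return A [sampled_series].
#' @export
resample <- function(traj, cfg, species = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "sampling_config"))
  if (length(traj$times) == 0L) stop("empty trajectory")
  if (is.null(species)) species <- traj$species
  missing <- setdiff(species, traj$species)
  if (length(missing))
    stop("species not in trajectory: ", paste(missing, collapse = ", "))
  grid <- (seq_len(cfg$N) - 1) * cfg$dt
  idx <- findInterval(grid, traj$times)  # last event time <= grid time
  vals <- traj$states[idx, species, drop = FALSE]
  rownames(vals) <- NULL
  sampled_series(vals, cfg)
}

#' DFT amplitude spectrum
#'
#' Computes the discrete Fourier transform of each sampled series (via the
#' FFT, no windowing, detrending or normalization) and returns the moduli
#' of the one-sided spectrum: bins `0 .. floor(N/2)` at frequencies
#' `w / (N dt)` cycles/min. Real signals are conjugate-symmetric, so the
#' one-sided spectrum carries all amplitude information without
#' double-counting mirrored mass. The DC bin is retained: low-frequency
#' transients are part of the behavioural signature.
#'
#' @param series a [sampled_series].
#' @return An `amplitude_spectrum` with fields `amplitudes` (bins x
#'   species), `freq`, `N`, `dt`.
#' @export
amplitude_spectrum <- function(series) {
  stopifnot(inherits(series, "sampled_series"))
  if (!all(is.finite(series$values))) stop("non-finite values in series")
  N <- series$config$N
  FT <- stats::mvfft(series$values)
  bins <- seq_len(N %/% 2 + 1)
  amp <- Mod(FT)[bins, , drop = FALSE]
  structure(list(amplitudes = amp,
                 freq = (bins - 1) / (N * series$config$dt),
                 N = N, dt = series$config$dt,
                 species = series$species),
            class = "amplitude_spectrum")
}

#' Phase spectrum
#'
#' Four-quadrant phase angle (in (-pi, pi]) of each one-sided DFT component.
#' Bins whose modulus falls below `tol` (relative to `N * max|x|`) carry no
#' phase information and are flagged undefined.
#'
#' @param series a [sampled_series].
#' @param tol relative modulus tolerance below which phase is undefined.
#' @return A `phase_spectrum` with fields `phase`, `undefined`, `freq`.
#' @export
phase_spectrum <- function(series, tol = 1e-9) {
  stopifnot(inherits(series, "sampled_series"))
  N <- series$config$N
  FT <- stats::mvfft(series$values)
  bins <- seq_len(N %/% 2 + 1)
  modulus <- Mod(FT)[bins, , drop = FALSE]
  scale <- pmax(N * apply(abs(series$values), 2, max), .Machine$double.xmin)
  undef <- sweep(modulus, 2, tol * scale, "<")
  ph <- Arg(FT)[bins, , drop = FALSE]
  ph[undef] <- NA_real_
  structure(list(phase = ph, undefined = undef,
                 freq = (bins - 1) / (N * series$config$dt),
                 N = N, dt = series$config$dt, species = series$species),
            class = "phase_spectrum")
}

empty_average <- function(template) {
  z <- template$amplitudes * 0
  structure(list(mean = z, m2 = z, K = 0L, freq = template$freq,
                 N = template$N, dt = template$dt,
                 species = template$species),
            class = "average_spectrum")
}

same_grid <- function(a, b) {
  isTRUE(a$N == b$N) && isTRUE(all.equal(a$dt, b$dt)) &&
    identical(dim(a$amplitudes %||% a$mean), dim(b$amplitudes %||% b$mean))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Ensemble-average amplitude spectrum
#'
#' Term-wise arithmetic mean of K amplitude spectra. Averaging the
#' amplitudes (rather than the complex spectra) is essential: the DFT is
#' linear, so averaging complex spectra equals transforming the time-domain
#' average, in which oscillatory structure cancels as run phases decohere.
#' Per-bin variance is accumulated (Welford) so ensembles can be extended
#' incrementally with [update_average_spectrum()], bit-consistent with the
#' batch mean.
#'
#' @param spectra list of [amplitude_spectrum()] objects on a common grid.
#' @return An `average_spectrum` with fields `mean`, `m2` (sum of squared
#'   deviations), `K`, `freq`.
#' @export
average_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  update_average_spectrum(empty_average(spectra[[1]]), spectra)
}

#' @rdname average_spectrum
#' @param avg an existing `average_spectrum` to extend.
#' @export
update_average_spectrum <- function(avg, spectra) {
  stopifnot(inherits(avg, "average_spectrum"))
  if (inherits(spectra, "amplitude_spectrum")) spectra <- list(spectra)
  for (sp in spectra) {
    stopifnot(inherits(sp, "amplitude_spectrum"))
    if (!same_grid(avg, sp)) stop("spectra are on different sampling grids")
    avg$K <- avg$K + 1L
    delta <- sp$amplitudes - avg$mean
    avg$mean <- avg$mean + delta / avg$K
    avg$m2 <- avg$m2 + delta * (sp$amplitudes - avg$mean)
  }
  avg
}

#' @export
print.average_spectrum <- function(x, ...) {
  cat(sprintf("<average_spectrum> %d species, %d bins, K=%d runs\n",
              ncol(x$mean), nrow(x$mean), x$K))
  invisible(x)
}

#' Kolmogorov-Smirnov behavioural distance between spectra
#'
#' Each average amplitude spectrum is normalized to unit sum to form a
#' probability distribution over frequency bins; D is the maximum absolute
#' difference between the two cumulative distributions, per species. D lies
#' in [0, 1], with 0 for identical spectra; it is used as a behavioural
#' distance, not as a test statistic.
#'
#' @param a,b [average_spectrum()] (or [amplitude_spectrum()]) objects on
#'   the same frequency grid.
#' @return A `ks_result`: `D` (named per-species vector), `F1`, `F2`
#'   (cumulative distributions), `freq`.
#' @export
ks_distance <- function(a, b) {
  get_amp <- function(x) {
    if (inherits(x, "average_spectrum")) x$mean
    else if (inherits(x, "amplitude_spectrum")) x$amplitudes
    else stop("expected an amplitude_spectrum or average_spectrum")
  }
  A <- get_amp(a); B <- get_amp(b)
  if (!same_grid(a, b)) stop("spectra are on different frequency grids")
  norm_cum <- function(M) {
    tot <- colSums(M)
    if (any(tot <= 0)) stop("all-zero spectrum has no distribution ",
                            "(species: ",
                            paste(colnames(M)[tot <= 0], collapse = ", "),
                            ")")
    apply(sweep(M, 2, tot, "/"), 2, cumsum)
  }
  F1 <- norm_cum(A); F2 <- norm_cum(B)
  D <- apply(abs(F1 - F2), 2, max)
  names(D) <- colnames(A)
  structure(list(D = D, F1 = F1, F2 = F2, freq = a$freq),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("<ks_result> per-species D:\n")
  print(round(x$D, 4))
  invisible(x)
}

#' Procedure A: ensemble-average spectra of a model
#'
#' Runs `K` seeded simulations of `net` over the sampling window, resamples
#' each trajectory onto the regular grid, transforms to amplitude spectra
#' and accumulates their term-wise mean per species. Pass a `previous`
#' result to add further runs to an existing average (runs continue from
#' index `previous$K + 1`, so extension is reproducible).
#'
#' @param net a count-mode [reaction_network()].
#' @param sampling a [sampling_config()].
#' @param K number of simulation runs to add.
#' @param base_seed ensemble seed.
#' @param species optional species subset.
#' @param t_max simulation horizon; defaults to the observation window
#'   `N * dt`.
#' @param previous an `average_spectrum` from an earlier call to extend.
#' @param stream integer sub-stream label for seed derivation.
#' @return An [average_spectrum()] (one column per species).
#' @export
procedure_A <- function(net, sampling, K, base_seed, species = NULL,
                        t_max = NULL, previous = NULL, stream = 0L) {
  stopifnot(inherits(net, "reaction_network"),
            inherits(sampling, "sampling_config"), K >= 1)
  if (is.null(species)) species <- names(net$species)
  missing <- setdiff(species, names(net$species))
  if (length(missing))
    stop("species not in network: ", paste(missing, collapse = ", "))
  if (is.null(t_max)) t_max <- sampling$window
  avg <- previous
  k0 <- if (is.null(avg)) 0L else avg$K
  for (i in k0 + seq_len(K)) {
    cfg <- sim_config(t_max, seed = derive_seed(base_seed, i, stream),
                      record = "grid")
    ser <- simulate_network(net, cfg, sampling = sampling)
    ser <- sampled_series(ser$values[, species, drop = FALSE], sampling)
    sp <- amplitude_spectrum(ser)
    avg <- if (is.null(avg)) average_spectrum(list(sp))
           else update_average_spectrum(avg, sp)
  }
  avg
}

#' Procedure B: behavioural distance between two models
#'
#' Runs paired ensembles of two models (pair `i` shares its index but uses
#' independent seed streams), forms the ensemble-average amplitude spectrum
#' of each side and computes the K-S distance D per species. This is the
#' measurement used throughout the crosstalk analysis: D between a coupled
#' and an uncoupled system quantifies how much the coupling perturbs each
#' species' behaviour.
#'
#' @inheritParams procedure_A
#' @param net_a,net_b count-mode networks sharing the species of interest.
#' @param previous a previous `procedure_B` result to extend with `K` more
#'   pairs.
#' @param shared_seeds if `TRUE`, both sides of pair `i` use the same seed
#'   (a determinism diagnostic: structurally identical models then produce
#'   identical traces and D = 0); by default the sides use independent seed
#'   streams.
#' @return A `procedure_B_result`: `D` (named vector), `ks`, `spectrum_a`,
#'   `spectrum_b`, `K`.
#' @export
procedure_B <- function(net_a, net_b, sampling, K, base_seed,
                        species = NULL, t_max = NULL, previous = NULL,
                        shared_seeds = FALSE) {
  if (is.null(species))
    species <- intersect(names(net_a$species), names(net_b$species))
  for (side in list(c("a", "first"), c("b", "second"))) {
    net <- if (side[1] == "a") net_a else net_b
    missing <- setdiff(species, names(net$species))
    if (length(missing))
      stop("species missing from ", side[2], " network: ",
           paste(missing, collapse = ", "))
  }
  avg_a <- procedure_A(net_a, sampling, K, base_seed, species, t_max,
                       previous = previous$spectrum_a, stream = 1L)
  avg_b <- procedure_A(net_b, sampling, K, base_seed, species, t_max,
                       previous = previous$spectrum_b,
                       stream = if (shared_seeds) 1L else 2L)
  ks <- ks_distance(avg_a, avg_b)
  structure(list(D = ks$D, ks = ks, spectrum_a = avg_a, spectrum_b = avg_b,
                 K = avg_a$K),
            class = "procedure_B_result")
}

#' @export
print.procedure_B_result <- function(x, ...) {
  cat(sprintf("<procedure_B_result> K=%d pairs; per-species D:\n", x$K))
  print(round(x$D, 4))
  invisible(x)
}

#' Convergence check: coefficient of variation of spectral means
#'
#' The stopping criterion for iterative ensemble extension: the coefficient
#' of variation of each spectral-component mean, `(sd / sqrt(K)) / mean`.
#' The ensemble is accepted when every bin whose mean exceeds a floor
#' (negligible-mass bins carry no information) satisfies `CoV <= threshold`.
#'
#' @param avg an [average_spectrum()] with `K >= 2`.
#' @param threshold maximum acceptable CoV of the mean.
#' @param floor per-bin mean below which bins are ignored; defaults to
#'   `1e-3 * max(mean)` per species.
#' @return A `convergence_cov` result: `cov` (bins x species), `pass`
#'   (per species), `threshold`, `floor`.
#' @export
convergence_cov <- function(avg, threshold = 0.05, floor = NULL) {
  stopifnot(inherits(avg, "average_spectrum"), avg$K >= 2)
  sd <- sqrt(avg$m2 / (avg$K - 1))
  cov <- (sd / sqrt(avg$K)) / avg$mean
  if (is.null(floor)) floor <- 1e-3 * apply(avg$mean, 2, max)
  floor <- rep_len(floor, ncol(avg$mean))
  above <- sweep(avg$mean, 2, floor, ">")
  pass <- vapply(seq_len(ncol(cov)), function(j)
    all(cov[above[, j], j] <= threshold), TRUE)
  names(pass) <- colnames(avg$mean)
  structure(list(cov = cov, pass = pass, threshold = threshold,
                 floor = floor),
            class = "convergence_cov")
}
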