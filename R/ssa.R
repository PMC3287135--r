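# Exact stochastic simulation (Gillespie direct method)

#' Simulation configuration
#'
#' @param t_max positive simulated time horizon (minutes).
#' @param seed integer seed; every random draw of the run derives from it.
#' @param record `"events"` for full event recording (one row per reaction
#'   firing, required by downstream last-value resampling) or `"grid"` to
#'   record directly onto a regular sampling grid (memory-light; needs
#'   `sampling`).
#' @return A `sim_config` object.
#' @export
sim_config <- function(t_max, seed = 1L, record = c("events", "grid")) {
  record <- match.arg(record)
  stopifnot(is.numeric(t_max), length(t_max) == 1L, t_max > 0)
  structure(list(t_max = as.numeric(t_max), seed = seed, record = record),
            class = "sim_config")
}

#' Derive a per-run seed
#'
#' Hashes `(base_seed, index, stream)` with splitmix64 so that every run of
#' an ensemble gets an independent, order-invariant seed.
#'
#' @param base_seed,index,stream integers.
#' @return A numeric seed (53-bit integer value).
#' @export
derive_seed <- function(base_seed, index, stream = 0L) {
  .derive_seed_cpp(as.numeric(base_seed), as.numeric(index),
                   as.numeric(stream))
}

#' Reaction propensity
#'
#' Instantaneous firing rate of a reaction at a given state. Mass-action
#' laws use the combinatorial (falling-factorial) form: a reactant of
#' multiplicity m contributes n(n-1)...(n-m+1)/m!, so e.g. a
#' homodimerization 2A -> B has propensity k n(n-1)/2. Modifiers multiply
#' the propensity as plain counts. Custom laws evaluate their expression at
#' the state and must be non-negative.
#'
#' @param r a [reaction()].
#' @param state named numeric vector of molecule counts.
#' @return Non-negative propensity.
#' @export
propensity <- function(r, state) {
  stopifnot(inherits(r, "reaction"))
  if (r$kinetics$form == "mass_action") {
    a <- r$kinetics$rate_constant
    for (i in seq_along(r$reactants)) {
      n <- state[[names(r$reactants)[i]]]
      m <- r$reactants[[i]]
      ff <- prod(n - seq_len(m) + 1) / factorial(m)
      a <- a * max(ff, 0)
    }
    for (mod in r$modifiers) a <- a * state[[mod]]
    return(a)
  }
  env <- as.list(state)
  a <- eval(parse(text = r$kinetics$rate_expression)[[1]], env)
  if (!is.finite(a))
    stop("custom rate '", r$kinetics$rate_expression,
         "' is non-finite at the current state")
  if (a < 0)
    stop("custom rate '", r$kinetics$rate_expression,
         "' evaluated negative (", a, ")")
  a
}

#' All reaction propensities of a network at a state
#'
#' @param net a count-mode [reaction_network()].
#' @param state named numeric vector of counts (defaults to the initial
#'   amounts).
#' @return Numeric vector, one propensity per reaction.
#' @export
propensities <- function(net, state = net$species) {
  vapply(net$reactions, propensity, 0.0, state = state)
}

# lower the network onto the C++ argument layout (0-based indices)
lower_network <- function(net) {
  sp <- names(net$species)
  list(reactant_idx = lapply(net$reactions, function(r)
         match(names(r$reactants), sp) - 1L),
       reactant_mult = lapply(net$reactions, function(r)
         as.integer(unname(r$reactants))),
       modifier_idx = lapply(net$reactions, function(r)
         match(r$modifiers, sp) - 1L),
       k = vapply(net$reactions, function(r) r$kinetics$rate_constant, 0.0),
       stoich = stoichiometry(net))
}

#' Stochastic simulation of a reaction network
#'
#' Exact Gillespie direct method: waiting times are Exponential in the total
#' propensity and the firing channel is chosen by cumulative-sum search with
#' strict inequality, so trajectories are bit-reproducible from the seed.
#' Pure mass-action networks (and quasi-deterministic conversions of them)
#' run in compiled code; networks with custom kinetic expressions use an R
#' implementation of the same method.
#'
#' @param net a valid count-mode [reaction_network()].
#' @param cfg a [sim_config()].
#' @param sampling a [sampling_config()]; required when
#'   `cfg$record == "grid"`.
#' @param max_events abort guard on the number of firings.
#' @return With `record = "events"` a `trajectory` (fields `times`,
#'   `states`, `species`, `seed`, `n_events`, `terminated_reason`); with
#'   `record = "grid"` a [sampled_series] on the sampling grid.
#' @export
simulate_network <- function(net, cfg, sampling = NULL, max_events = 1e9) {
  stopifnot(inherits(net, "reaction_network"), inherits(cfg, "sim_config"))
  if (net$units_mode != "count")
    stop("simulate_network() expects a count-mode network (see discretize())")
  if (cfg$record == "grid" && is.null(sampling))
    stop("grid recording requires a sampling_config")
  src <- attr(net, "qd_source")
  qd <- !is.null(src)
  cnet <- if (qd) src else net
  if (all_mass_action(cnet)) {
    lw <- lower_network(cnet)
    res <- .ssa_cpp(as.numeric(net$species), lw$stoich, lw$reactant_idx,
                    lw$reactant_mult, lw$modifier_idx, lw$k,
                    cfg$t_max, as.numeric(cfg$seed),
                    if (qd) 1L else 0L,
                    if (cfg$record == "grid") 1L else 0L,
                    if (is.null(sampling)) 0L else sampling$N,
                    if (is.null(sampling)) 0 else sampling$dt,
                    max_events)
  } else {
    res <- ssa_r(net, cfg$t_max, cfg$seed, max_events)
  }
  if (cfg$record == "grid") {
    if (!is.null(res$grid)) {
      colnames(res$grid) <- names(net$species)
      return(sampled_series(res$grid, sampling))
    }
    traj <- make_trajectory(res, net, cfg$seed)
    return(resample(traj, sampling))
  }
  make_trajectory(res, net, cfg$seed)
}

make_trajectory <- function(res, net, seed) {
  colnames(res$states) <- names(net$species)
  structure(list(times = res$times, states = res$states,
                 species = names(net$species), seed = seed,
                 n_events = res$n_events,
                 terminated_reason = if (res$reason == "t_max")
                   "t_max reached" else "no reaction possible"),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d species, %d events, t in [0, %g] (%s)\n",
              length(x$species), as.integer(x$n_events),
              x$times[length(x$times)], x$terminated_reason))
  invisible(x)
}

# R fallback for networks with custom kinetic expressions (direct method,
# R RNG; used at test scale only)
ssa_r <- function(net, t_max, seed, max_events) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  S <- stoichiometry(net)
  exprs <- lapply(net$reactions, function(r)
    parse(text = propensity_expr(r))[[1]])
  x <- net$species
  t <- 0
  times <- numeric(1024); states <- matrix(0, 1024, length(x))
  times[1] <- 0; states[1, ] <- x
  n <- 1L
  reason <- "t_max"
  repeat {
    env <- as.list(x)
    a <- vapply(exprs, function(e) eval(e, env), 0.0)
    if (any(a < 0)) stop("negative propensity in reaction ",
                         which(a < 0)[1], " at t=", t)
    a0 <- sum(a)
    if (!is.finite(a0)) stop("non-finite total propensity at t=", t,
                             "; state: ", paste(x, collapse = " "))
    if (a0 <= 0) { reason <- "no_reaction"; break }
    t_next <- t + stats::rexp(1, a0)
    if (t_next > t_max) break
    j <- which(cumsum(a) > stats::runif(1) * a0)[1]
    x <- x + S[, j]
    t <- t_next
    n <- n + 1L
    if (n > nrow(states)) {
      states <- rbind(states, matrix(0, nrow(states), ncol(states)))
      times <- c(times, numeric(length(times)))
    }
    times[n] <- t; states[n, ] <- x
    if (n >= max_events) stop("event budget exceeded at t=", t)
  }
  list(times = times[seq_len(n)], states = states[seq_len(n), , drop = FALSE],
       n_events = n - 1, reason = reason)
}

#' Simulate a seeded ensemble
#'
#' Run `K` independent simulations with identical initial conditions; run
#' `i` uses the seed `derive_seed(base_seed, i, stream)`, so results do not
#' depend on execution order and ensembles can be extended reproducibly.
#'
#' @inheritParams simulate_network
#' @param K number of runs.
#' @param base_seed ensemble seed.
#' @param stream integer sub-stream label (used to keep paired ensembles
#'   independent).
#' @return List of `K` trajectories (or [sampled_series] under grid
#'   recording).
#' @export
simulate_ensemble <- function(net, cfg, K, base_seed, stream = 0L,
                              sampling = NULL) {
  stopifnot(K >= 1)
  lapply(seq_len(K), function(i) {
    cfg$seed <- derive_seed(base_seed, i, stream)
    tryCatch(simulate_network(net, cfg, sampling = sampling),
             error = function(e)
               stop("run ", i, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Trajectory CSV serialization
#'
#' One row per event: a `time` column followed by one column per species.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a `trajectory` (seed unknown, recorded as `NA`).
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df) || nrow(df) == 0)
    stop("not a trajectory CSV: ", path)
  states <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  structure(list(times = df$time, states = states,
                 species = colnames(states), seed = NA,
                 n_events = nrow(df) - 1,
                 terminated_reason = "unknown"),
            class = "trajectory")
}
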