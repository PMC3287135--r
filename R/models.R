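# Model library: tunable stochastic oscillators with distinct characteristic
# frequencies, a coupling mechanism, and the standard three-subsystem
# crosstalk fixture (two oscillators driving a signalling cascade).

#' Oscillator specification
#'
#' Describes a delayed negative-feedback oscillator: an activator species X
#' with weak autocatalysis drives a chain of intermediates whose terminal
#' species catalyses the degradation of X. The chain delay plus the
#' bilinear feedback yields a limit cycle (or, at low feedback strength, a
#' strongly damped oscillation that intrinsic noise keeps re-igniting); all
#' kinetics are elemental mass action.
#'
#' @param n_species total species count (activator + chain), >= 2.
#' @param feedback_strength multiplier on the feedback rate constant.
#' @param degradation chain degradation/transfer rate before period
#'   rescaling (1/min); sets the pre-calibration timescale only.
#' @param target_period desired oscillation period, minutes.
#' @param scale steady-state molecule count of the activator (sets the
#'   noise level: smaller counts, stronger intrinsic fluctuations).
#' @return An `oscillator_spec`.
#' @export
oscillator_spec <- function(n_species = 4, feedback_strength = 1,
                            degradation = 0.02, target_period = 500,
                            scale = 100) {
  stopifnot(n_species >= 2, feedback_strength > 0, degradation > 0,
            target_period > 0, scale > 0)
  structure(list(n_species = as.integer(n_species),
                 feedback_strength = feedback_strength,
                 degradation = degradation,
                 target_period = target_period, scale = scale),
            class = "oscillator_spec")
}

# fraction of the feedback loss rate restored by autocatalysis; close to 1
# puts the system just past the Hopf bifurcation (design constant)
OSC_AUTOCATALYSIS_FRACTION <- 0.97

#' Build an oscillator network
#'
#' Constructs the count-mode network for an [oscillator_spec()] and
#' calibrates its period: the rate constants are uniformly rescaled in time
#' so that the imaginary part of the dominant oscillatory eigenvalue of the
#' deterministic Jacobian (at the steady state) matches
#' `2 * pi / target_period`. Uniform time rescaling is exact for the
#' nonlinear dynamics, so the realized period tracks the target to within
#' the (small) nonlinear shift of the limit cycle.
#'
#' @param spec an [oscillator_spec()].
#' @param name_prefix prefix for species names (e.g. `"slow"` gives
#'   `slow_X`, `slow_Y1`, ...).
#' @return A count-mode [reaction_network()], started at the deterministic
#'   steady state.
#' @export
make_oscillator <- function(spec, name_prefix = "osc") {
  stopifnot(inherits(spec, "oscillator_spec"))
  m <- spec$n_species - 1L          # chain length
  d <- spec$degradation
  xstar <- spec$scale
  ystar <- xstar                     # ka = kc = kd = d gives a flat chain
  ka <- d; kc <- d; kd <- d
  kf <- spec$feedback_strength * d / ystar
  kp <- OSC_AUTOCATALYSIS_FRACTION * kf * ystar
  k0 <- xstar * (kf * ystar - kp)

  # dominant oscillatory eigenvalue of the Jacobian at the steady state
  n <- m + 1L
  J <- matrix(0, n, n)
  J[1, 1] <- kp - kf * ystar
  J[1, n] <- -kf * xstar
  J[2, 1] <- ka; J[2, 2] <- -kc
  if (m >= 2) for (i in 2:m) {
    J[i + 1L, i] <- kc
    J[i + 1L, i + 1L] <- if (i == m) -kd else -kc
  }
  ev <- eigen(J, only.values = TRUE)$values
  osc <- ev[Im(ev) > 1e-12]
  if (length(osc) == 0L)
    stop("oscillator_spec admits no oscillatory mode (no complex ",
         "eigenvalue); increase n_species or feedback_strength")
  lambda <- osc[which.max(Re(osc))]
  scale_t <- (2 * pi / Im(lambda)) / spec$target_period

  nm <- function(s) paste0(name_prefix, "_", s)
  X <- nm("X")
  Y <- nm(paste0("Y", seq_len(m)))
  species <- stats::setNames(rep(round(xstar), n), c(X, Y))
  rx <- list(
    reaction(character(), X, mass_action(k0 * scale_t)),
    reaction(X, c(X, X), mass_action(kp * scale_t)),
    reaction(X, c(X, Y[1]), mass_action(ka * scale_t)))
  if (m >= 2) for (i in seq_len(m - 1L))
    rx <- c(rx, list(reaction(Y[i], Y[i + 1L], mass_action(kc * scale_t))))
  rx <- c(rx, list(
    reaction(Y[m], character(), mass_action(kd * scale_t)),
    reaction(c(X, Y[m]), Y[m], mass_action(kf * scale_t))))
  net <- reaction_network(species, rx, "count")
  d <- validate_network(net)
  if (length(d)) stop("oscillator network invalid: ",
                      paste(d, collapse = "; "))
  net
}

#' Coupling specification
#'
#' Declares a catalytic coupling reaction `source -> source + target`: the
#' source species (in one network) activates production of the target
#' species (in the other). The strength multiplier scales only the coupling
#' reaction's rate constant; multiplier 0 removes the coupling entirely, so
#' the coupled network is exactly the disjoint union.
#'
#' @param source species name in the driving network.
#' @param target species name in the driven network.
#' @param rate base rate constant of the coupling reaction (per molecule of
#'   source per minute).
#' @param multiplier coupling-strength multiplier (e.g. 0, 1, 2, 10).
#' @return A `coupling_spec`.
#' @export
coupling_spec <- function(source, target, rate, multiplier = 1) {
  stopifnot(is.character(source), is.character(target), rate > 0,
            multiplier >= 0)
  structure(list(source = source, target = target, rate = rate,
                 multiplier = multiplier),
            class = "coupling_spec")
}

#' Couple two reaction networks
#'
#' Forms the union of two networks with disjoint species namespaces and
#' adds the declared coupling reactions, their rate constants scaled by the
#' strength multiplier.
#'
#' @param net_a,net_b count-mode [reaction_network()]s with disjoint
#'   species names.
#' @param coupling a [coupling_spec()] or list of them; each source must
#'   live in `net_a` and each target in `net_b`.
#' @return The coupled [reaction_network()].
#' @export
couple <- function(net_a, net_b, coupling) {
  stopifnot(inherits(net_a, "reaction_network"),
            inherits(net_b, "reaction_network"))
  clash <- intersect(names(net_a$species), names(net_b$species))
  if (length(clash))
    stop("species namespace collision: ", paste(clash, collapse = ", "))
  if (inherits(coupling, "coupling_spec")) coupling <- list(coupling)
  rx <- c(net_a$reactions, net_b$reactions)
  for (cp in coupling) {
    stopifnot(inherits(cp, "coupling_spec"))
    if (!cp$source %in% names(net_a$species))
      stop("coupling source '", cp$source, "' not in first network")
    if (!cp$target %in% names(net_b$species))
      stop("coupling target '", cp$target, "' not in second network")
    if (cp$multiplier > 0)
      rx <- c(rx, list(reaction(cp$source, c(cp$source, cp$target),
                                mass_action(cp$rate * cp$multiplier))))
  }
  reaction_network(c(net_a$species, net_b$species), rx, "count")
}

# the signalling cascade of the standard fixture: a 7-species chain with a
# resonant negative-feedback subloop (C3..C6) tuned near the fast
# oscillator's frequency, so susceptibility to perturbation is frequency
# dependent rather than a monotone function of network distance. C2 is a
# fast-turnover relay: its high flux buffers the mean shift from coupling
# while passing oscillatory drive downstream with little attenuation.
make_cascade <- function() {
  dc <- 0.02     # slow stages
  dr <- 0.1      # fast-turnover relay stage (C2)
  dl <- 0.0726   # resonant-loop stage rate: resonance ~0.009 cycles/min
  g <- 4         # loop feedback gain (Q ~ 1.7)
  cf <- g * dl / 50
  a23 <- (1 + g) * dl
  C <- paste0("C", 1:7)
  rx <- list(
    reaction(character(), "C1", mass_action(1)),
    reaction("C1", character(), mass_action(dc)),
    reaction("C1", c("C1", "C2"), mass_action(dr)),
    reaction("C2", character(), mass_action(dr)),
    reaction("C2", c("C2", "C3"), mass_action(a23)),
    reaction("C3", character(), mass_action(dl)),
    reaction(c("C3", "C6"), "C6", mass_action(cf)),
    reaction("C3", c("C3", "C4"), mass_action(dl)),
    reaction("C4", character(), mass_action(dl)),
    reaction("C4", c("C4", "C5"), mass_action(dl)),
    reaction("C5", character(), mass_action(dl)),
    reaction("C5", c("C5", "C6"), mass_action(dl)),
    reaction("C6", character(), mass_action(dl)),
    reaction("C6", c("C6", "C7"), mass_action(dc)),
    reaction("C7", character(), mass_action(dc)))
  reaction_network(stats::setNames(rep(50, 7), C), rx, "count")
}

#' The standard crosstalk fixture
#'
#' A desk-scale analogue of a multi-pathway signalling system: a slow
#' oscillator (period 500 min, dominant mode ~0.002 cycles/min), a fast
#' oscillator (period 100 min, ~0.01 cycles/min, five times faster), and a
#' seven-species signalling cascade containing a resonant subloop near the
#' fast oscillator's frequency. The slow oscillator couples into `C1`, the
#' fast one into `C2`; cascade species sit at graph distances 1..5 and
#' beyond from the coupling points, so network-distance heuristics can be
#' scored against the measured spectral perturbation.
#'
#' @param slow_multiplier,fast_multiplier coupling-strength multipliers
#'   (0 removes the corresponding coupling).
#' @return A list: `slow`, `fast`, `cascade` (component networks),
#'   `couplings` (named list of [coupling_spec()]s at the given
#'   multipliers), `uncoupled` (the disjoint union) and `coupled` (union
#'   plus coupling reactions). The networks are deterministic functions of
#'   the arguments.
#' @export
standard_fixture <- function(slow_multiplier = 1, fast_multiplier = 1) {
  slow <- make_oscillator(oscillator_spec(target_period = 500), "slow")
  fast <- make_oscillator(oscillator_spec(target_period = 100), "fast")
  cascade <- make_cascade()
  oscillators <- couple(slow, fast, list())   # disjoint union of drivers
  couplings <- list(
    slow = coupling_spec("slow_X", "C1", rate = 0.01,
                         multiplier = slow_multiplier),
    fast = coupling_spec("fast_X", "C2", rate = 0.01,
                         multiplier = fast_multiplier))
  list(slow = slow, fast = fast, cascade = cascade,
       couplings = couplings,
       uncoupled = couple(oscillators, cascade, list()),
       coupled = couple(oscillators, cascade, couplings))
}
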