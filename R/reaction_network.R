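#' @useDynLib oscspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- constructors ----------------------------------------------------------

#' Kinetic laws
#'
#' `mass_action(k)` declares elemental mass-action kinetics with rate constant
#' `k` (units depend on the reaction order). `custom_rate(expr)` declares an
#' arbitrary kinetic function given as an arithmetic expression over species
#' counts, e.g. `"0.5 * A / (10 + A)"`; it must evaluate to a non-negative
#' value at any non-negative state.
#'
#' @param k positive rate constant.
#' @param expr character scalar, arithmetic expression over species names.
#' @return A kinetic-law object.
#' @export
mass_action <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  structure(list(form = "mass_action", rate_constant = as.numeric(k),
                 rate_expression = NULL),
            class = "kinetic_law")
}

#' @rdname mass_action
#' @export
custom_rate <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  parse(text = expr)  # fail early on syntax errors
  structure(list(form = "custom", rate_constant = NA_real_,
                 rate_expression = expr),
            class = "kinetic_law")
}

# normalize "A","A","B" or c(A = 2, B = 1) to a named integer multiset
as_multiset <- function(x) {
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.character(x)) {
    tab <- table(x)
    out <- stats::setNames(as.integer(tab), names(tab))
    # preserve first-appearance order
    out[unique(x)]
  } else {
    stopifnot(!is.null(names(x)), all(x >= 1))
    stats::setNames(as.integer(x), names(x))
  }
}

#' Define a reaction
#'
#' Reactants and products are multisets of species names (character vectors
#' with repetition, or named integer vectors of multiplicities). Modifiers
#' are species that scale the rate without net consumption (enzymes,
#' catalysts); they contribute zero to the stoichiometry.
#'
#' @param reactants,products multisets of species names (may be empty).
#' @param kinetics a [mass_action()] or [custom_rate()] law.
#' @param modifiers character vector of modifier species names.
#' @return A `reaction` object.
#' @examples
#' reaction(c("A", "B"), "C", mass_action(0.01))
#' reaction("A", "B", mass_action(0.1), modifiers = "E")
#' @export
reaction <- function(reactants, products, kinetics, modifiers = character()) {
  stopifnot(inherits(kinetics, "kinetic_law"), is.character(modifiers))
  structure(list(reactants = as_multiset(reactants),
                 products  = as_multiset(products),
                 modifiers = modifiers,
                 kinetics  = kinetics),
            class = "reaction")
}

#' Define a reaction network
#'
#' The species order is fixed and defines the state-vector indexing used by
#' the simulator and by [stoichiometry()]. Networks are either in
#' `"concentration"` mode (initial amounts in mol/l, prior to
#' alpha-discretization) or `"count"` mode (integer molecule numbers,
#' simulable).
#'
#' @param species named numeric vector of initial amounts.
#' @param reactions list of [reaction()] objects.
#' @param units_mode `"count"` or `"concentration"`.
#' @return A `reaction_network` object.
#' @seealso [validate_network()], [discretize()], [simulate_network()]
#' @export
reaction_network <- function(species, reactions,
                             units_mode = c("count", "concentration")) {
  units_mode <- match.arg(units_mode)
  stopifnot(is.numeric(species), !is.null(names(species)))
  structure(list(species = species,
                 reactions = reactions,
                 units_mode = units_mode),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions [%s mode]\n",
              length(x$species), length(x$reactions), x$units_mode))
  invisible(x)
}

species_names <- function(net) names(net$species)

# ---- validation ------------------------------------------------------------

#' Validate a reaction network
#'
#' Checks the structural invariants of a network and returns diagnostics
#' rather than raising: unique species names, non-negative initial amounts
#' (integers in count mode), all referenced species declared, positive
#' mass-action rate constants, and no species acting as both reactant and
#' modifier of the same reaction.
#'
#' @param net a [reaction_network()].
#' @return Character vector of diagnostics; empty iff the network is valid.
#' @export
validate_network <- function(net) {
  diag <- character()
  sp <- names(net$species)
  if (anyDuplicated(sp))
    diag <- c(diag, sprintf("duplicate species name '%s'",
                            sp[duplicated(sp)]))
  bad <- net$species < 0
  if (any(bad))
    diag <- c(diag, sprintf("species '%s' has negative initial amount",
                            sp[bad]))
  if (net$units_mode == "count") {
    noni <- net$species != round(net$species)
    if (any(noni))
      diag <- c(diag, sprintf(
        "species '%s' has non-integer initial amount in count mode",
        sp[noni]))
  }
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    refs <- c(names(r$reactants), names(r$products), r$modifiers)
    unk <- setdiff(refs, sp)
    if (length(unk))
      diag <- c(diag, sprintf("reaction %d references unknown species '%s'",
                              j, unk))
    both <- intersect(names(r$reactants), r$modifiers)
    if (length(both))
      diag <- c(diag, sprintf(
        "reaction %d: species '%s' is both reactant and modifier", j, both))
    if (any(r$reactants < 1) || any(r$products < 1))
      diag <- c(diag, sprintf("reaction %d has multiplicity < 1", j))
    if (r$kinetics$form == "mass_action" &&
        !(is.finite(r$kinetics$rate_constant) &&
          r$kinetics$rate_constant > 0))
      diag <- c(diag, sprintf(
        "reaction %d: mass-action rate constant must be > 0", j))
  }
  diag
}

# ---- stoichiometry ---------------------------------------------------------

#' Net stoichiometry matrix
#'
#' @param net a [reaction_network()].
#' @return Integer matrix, species x reactions; entry (i, j) is the net
#'   change of species i when reaction j fires. Modifiers contribute zero.
#' @export
stoichiometry <- function(net) {
  sp <- names(net$species)
  S <- matrix(0L, nrow = length(sp), ncol = length(net$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    S[names(r$products), j]  <- S[names(r$products), j] + r$products
  }
  S
}

# ---- alpha-discretization --------------------------------------------------

#' Discretize a concentration-mode network to molecule counts
#'
#' Multiplies every initial concentration by `alpha` (units l/mol, rounded
#' half-to-even to an integer count) and rescales rate constants so that the
#' propensity in count units equals `alpha` times the reaction rate in
#' concentration units: a mass-action constant of total kinetic order m
#' (reactant multiplicities plus modifiers) becomes `k / alpha^(m-1)`, and a
#' custom rate expression `r(c)` becomes `alpha * r(n / alpha)`.
#'
#' @param net a [reaction_network()] in concentration mode.
#' @param alpha positive discretization constant (l/mol).
#' @return A count-mode [reaction_network()].
#' @export
discretize <- function(net, alpha) {
  stopifnot(inherits(net, "reaction_network"))
  if (net$units_mode != "concentration")
    stop("discretize() expects a concentration-mode network")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a positive real")
  species <- round(net$species * alpha)  # round half to even: unbiased
  reactions <- lapply(net$reactions, function(r) {
    if (r$kinetics$form == "mass_action") {
      m <- sum(r$reactants) + length(r$modifiers)
      r$kinetics$rate_constant <- r$kinetics$rate_constant / alpha^(m - 1)
    } else {
      r$kinetics$rate_expression <-
        rescale_expression(r$kinetics$rate_expression,
                           names(net$species), alpha)
    }
    r
  })
  out <- reaction_network(species, reactions, "count")
  d <- validate_network(out)
  if (length(d)) stop("discretized network invalid: ",
                      paste(d, collapse = "; "))
  out
}

# substitute each species symbol v by (v / alpha) and scale by alpha
rescale_expression <- function(expr, species, alpha) {
  e <- parse(text = expr)[[1]]
  subs <- lapply(species, function(s) call("/", as.name(s), alpha))
  names(subs) <- species
  e2 <- eval(call("substitute", e, subs))
  paste0(format(alpha, digits = 17), " * (",
         paste(deparse(e2), collapse = " "), ")")
}

# ---- propensity expressions & quasi-deterministic conversion ---------------

# count-mode propensity of one reaction as an expression string
propensity_expr <- function(r) {
  if (r$kinetics$form == "custom") return(r$kinetics$rate_expression)
  terms <- character()
  for (i in seq_along(r$reactants)) {
    n <- names(r$reactants)[i]
    m <- r$reactants[[i]]
    ff <- paste(vapply(seq_len(m) - 1L, function(d)
      if (d == 0) n else sprintf("(%s - %d)", n, d), ""), collapse = " * ")
    terms <- c(terms, sprintf("(%s) / %d", ff, factorial(m)))
  }
  for (m in r$modifiers) terms <- c(terms, m)
  paste(c(format(r$kinetics$rate_constant, digits = 17), terms),
        collapse = " * ")
}

#' Convert to a quasi-deterministic model
#'
#' Combines the kinetic functions for production and consumption of each
#' species into a single resultant (net-rate) function, then simulates that
#' resultant stochastically: each species gets a +1 channel with propensity
#' `max(r_i, 0)` and a -1 channel with propensity `max(-r_i, 0)`, where
#' `r_i` is the species' net drift in the source network. At every state the
#' expected instantaneous drift of every species is identical to the source
#' network's, but the intrinsic noise is greatly reduced (single-molecule
#' steps driven by the net rate only). Splitting into two one-directional
#' channels keeps all propensities non-negative, as the stochastic
#' simulation algorithm requires.
#'
#' @param net a valid count-mode [reaction_network()].
#' @return A count-mode network of 2 x n_species resultant channels. When
#'   the source network is pure mass action it is attached so simulation can
#'   use the fast compiled path.
#' @export
to_quasi_deterministic <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (net$units_mode != "count")
    stop("to_quasi_deterministic() expects a count-mode network")
  S <- stoichiometry(net)
  aexpr <- vapply(net$reactions, propensity_expr, "")
  channels <- list()
  for (sp in names(net$species)) {
    terms <- character()
    for (j in seq_along(net$reactions)) {
      s <- S[sp, j]
      if (s != 0)
        terms <- c(terms, sprintf("%s%d * (%s)",
                                  if (s > 0) "+" else "-", abs(s), aexpr[j]))
    }
    drift <- if (length(terms)) paste(terms, collapse = " ") else "0"
    channels[[length(channels) + 1L]] <-
      reaction(character(), sp, custom_rate(sprintf("max(0, %s)", drift)))
    channels[[length(channels) + 1L]] <-
      reaction(sp, character(), custom_rate(sprintf("max(0, -(%s))", drift)))
  }
  out <- reaction_network(net$species, channels, "count")
  if (all_mass_action(net)) attr(out, "qd_source") <- net
  out
}

all_mass_action <- function(net) {
  all(vapply(net$reactions, function(r) r$kinetics$form == "mass_action",
             TRUE))
}

# ---- native text dialect ---------------------------------------------------

#' Read and write reaction networks
#'
#' The native dialect is a diffable plain-text format, UTF-8, `#` comments:
#' a `units:` line, one `species NAME = AMOUNT` line per species, and one
#' reaction per line, `A + 2 B -> C [k=0.1]`, with the empty multiset
#' written `0`, optional `{modifiers: E, F}` before the bracket, and
#' `[rate="expr"]` for custom kinetics. `write_network()` followed by
#' `read_network()` is the identity.
#'
#' @param path file path.
#' @param dialect `"native"` or `"sbml"` (SBML Level 3 import of species and
#'   mass-action reactions; unsupported features are reported by name).
#' @param net a [reaction_network()].
#' @return `read_network()` returns a [reaction_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path, dialect = c("native", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "sbml") return(read_sbml(path))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  units_mode <- NULL
  species <- numeric()
  reactions <- list()
  saw_any <- FALSE
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    saw_any <- TRUE
    if (grepl("^units:", s)) {
      units_mode <- trimws(sub("^units:", "", s))
      if (!units_mode %in% c("count", "concentration"))
        stop(sprintf("line %d: unknown units mode '%s'", ln, units_mode))
    } else if (grepl("^species\\s", s)) {
      m <- regmatches(s, regexec(
        "^species\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(\\S+)$", s))[[1]]
      if (length(m) != 3)
        stop(sprintf("line %d: malformed species line", ln))
      amt <- suppressWarnings(as.numeric(m[3]))
      if (is.na(amt)) stop(sprintf("line %d: bad amount '%s'", ln, m[3]))
      species[m[2]] <- amt
    } else if (grepl("->", s, fixed = TRUE)) {
      reactions[[length(reactions) + 1L]] <- parse_reaction_line(s, ln)
    } else {
      stop(sprintf("line %d: cannot parse '%s'", ln, s))
    }
  }
  if (!saw_any) stop("empty network file: ", path)
  if (is.null(units_mode)) units_mode <- "count"
  if (length(species) == 0L) stop("no species declared in ", path)
  reaction_network(species, reactions, units_mode)
}

parse_reaction_line <- function(s, ln) {
  kin <- NULL
  bm <- regmatches(s, regexec("\\[\\s*(k\\s*=\\s*([^]\"]+)|rate\\s*=\\s*\"([^\"]*)\")\\s*\\]", s))[[1]]
  if (length(bm) == 0)
    stop(sprintf("line %d: missing [k=...] or [rate=\"...\"] bracket", ln))
  if (nzchar(bm[3])) {
    k <- suppressWarnings(as.numeric(trimws(bm[3])))
    if (is.na(k)) stop(sprintf("line %d: bad rate constant", ln))
    kin <- mass_action(k)
  } else {
    kin <- custom_rate(bm[4])
  }
  s <- sub("\\[[^]]*\\]\\s*$", "", s)
  modifiers <- character()
  mm <- regmatches(s, regexec("\\{\\s*modifiers:\\s*([^}]*)\\}", s))[[1]]
  if (length(mm)) {
    modifiers <- trimws(strsplit(mm[2], ",")[[1]])
    modifiers <- modifiers[nzchar(modifiers)]
    s <- sub("\\{[^}]*\\}", "", s)
  }
  sides <- strsplit(s, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop(sprintf("line %d: malformed reaction", ln))
  reaction(parse_side(sides[1], ln), parse_side(sides[2], ln), kin,
           modifiers = modifiers)
}

parse_side <- function(side, ln) {
  side <- trimws(side)
  if (side == "0" || side == "") return(character())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- integer()
  for (tm in terms) {
    m <- regmatches(tm, regexec(
      "^(?:([0-9]+)\\s+)?([A-Za-z_][A-Za-z0-9_.]*)$", tm))[[1]]
    if (length(m) != 3)
      stop(sprintf("line %d: cannot parse species term '%s'", ln, tm))
    mult <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    out[m[3]] <- (if (m[3] %in% names(out)) out[[m[3]]] else 0L) + mult
  }
  out
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  fmt_side <- function(ms) {
    if (length(ms) == 0L) return("0")
    paste(ifelse(ms == 1L, names(ms), paste(ms, names(ms))), collapse = " + ")
  }
  lines <- c(sprintf("units: %s", net$units_mode),
             sprintf("species %s = %s", names(net$species),
                     vapply(net$species, format, "", digits = 17)))
  for (r in net$reactions) {
    mods <- if (length(r$modifiers))
      sprintf(" {modifiers: %s}", paste(r$modifiers, collapse = ", "))
    else ""
    kin <- if (r$kinetics$form == "mass_action")
      sprintf("[k=%s]", format(r$kinetics$rate_constant, digits = 17))
    else sprintf("[rate=\"%s\"]", r$kinetics$rate_expression)
    lines <- c(lines, sprintf("%s -> %s%s %s", fmt_side(r$reactants),
                              fmt_side(r$products), mods, kin))
  }
  writeLines(lines, path)
  invisible(path)
}

# minimal SBML Level 3 import: species and reactions with a (local or
# global) parameter named 'k' interpreted as a mass-action constant
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  for (feat in c("listOfRules", "listOfEvents", "listOfFunctionDefinitions",
                 "listOfConstraints"))
    if (length(xml2::xml_find_all(doc, paste0("//", feat))))
      stop("unsupported SBML feature: ", feat)
  sp_nodes <- xml2::xml_find_all(doc, "//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("no species in SBML file ", path)
  ids <- xml2::xml_attr(sp_nodes, "id")
  amt <- xml2::xml_attr(sp_nodes, "initialAmount")
  conc <- xml2::xml_attr(sp_nodes, "initialConcentration")
  units_mode <- if (all(is.na(amt)) && !all(is.na(conc))) "concentration"
                else "count"
  vals <- ifelse(is.na(amt), conc, amt)
  vals <- as.numeric(ifelse(is.na(vals), "0", vals))
  species <- stats::setNames(vals, ids)
  global_k <- NULL
  gp <- xml2::xml_find_all(doc, "//model/listOfParameters/parameter")
  if (length(gp)) {
    gk <- xml2::xml_attr(gp, "id") == "k"
    if (any(gk)) global_k <- as.numeric(xml2::xml_attr(gp[gk][[1]], "value"))
  }
  rx_nodes <- xml2::xml_find_all(doc, "//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    side <- function(xp) {
      refs <- xml2::xml_find_all(nd, xp)
      if (length(refs) == 0L) return(character())
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- as.integer(ifelse(is.na(st), "1", st))
      stats::setNames(st, xml2::xml_attr(refs, "species"))
    }
    mods <- xml2::xml_attr(
      xml2::xml_find_all(nd, "listOfModifiers/modifierSpeciesReference"),
      "species")
    lp <- xml2::xml_find_all(
      nd, "kineticLaw//localParameter | kineticLaw//parameter")
    k <- global_k
    if (length(lp)) {
      lk <- xml2::xml_attr(lp, "id") == "k"
      if (any(lk)) k <- as.numeric(xml2::xml_attr(lp[lk][[1]], "value"))
    }
    if (is.null(k) || is.na(k))
      stop("unsupported SBML feature: kineticLaw without parameter 'k' ",
           "(only mass-action laws are imported)")
    reaction(side("listOfReactants/speciesReference"),
             side("listOfProducts/speciesReference"),
             mass_action(k), modifiers = mods)
  })
  reaction_network(species, reactions, units_mode)
}
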