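test_that("validate_network returns diagnostics for each broken invariant", {
  ok <- reaction_network(c(A = 10, B = 0),
                         list(reaction("A", "B", mass_action(0.1))), "count")
  expect_identical(validate_network(ok), character(0))
  # idempotent and side-effect free
  expect_identical(validate_network(ok), validate_network(ok))

  unknown <- reaction_network(c(A = 10),
                              list(reaction("A", "X", mass_action(1))),
                              "count")
  d <- validate_network(unknown)
  expect_length(d, 1)
  expect_match(d, "X")

  neg <- reaction_network(c(A = -3),
                          list(reaction("A", "A", mass_action(1))), "count")
  d <- validate_network(neg)
  expect_length(d, 1)
  expect_match(d, "A")

  both <- reaction_network(c(A = 1, E = 1),
                           list(reaction("A", "A", mass_action(1),
                                         modifiers = "A")), "count")
  expect_match(validate_network(both), "both reactant and modifier")

  frac <- reaction_network(c(A = 1.5),
                           list(reaction("A", "A", mass_action(1))),
                           "count")
  expect_match(validate_network(frac), "non-integer")
})

test_that("stoichiometry has net changes with modifiers contributing zero", {
  net <- reaction_network(c(A = 1, B = 1, C = 0, E = 1), list(
    reaction(c("A", "B"), "C", mass_action(1)),
    reaction("A", "B", mass_action(1), modifiers = "E"),
    reaction(c("A", "A"), "B", mass_action(1))), "count")
  S <- stoichiometry(net)
  expect_identical(S[, 1], c(A = -1L, B = -1L, C = 1L, E = 0L))
  expect_identical(S[, 2], c(A = -1L, B = 1L, C = 0L, E = 0L))
  expect_identical(S[, 3], c(A = -2L, B = 1L, C = 0L, E = 0L))
})

test_that("discretize scales amounts and rate constants by reaction order", {
  net <- reaction_network(
    c(A = 0.5, B = 0.2, E = 0.1),
    list(reaction("A", "B", mass_action(0.1)),                 # order 1
         reaction(c("A", "B"), "A", mass_action(0.002)),       # order 2
         reaction(character(), "A", mass_action(3e-4)),        # order 0
         reaction("A", "B", mass_action(0.05), modifiers = "E")),
    "concentration")
  dn <- discretize(net, 1000)
  expect_identical(dn$units_mode, "count")
  expect_equal(unname(dn$species), c(500, 200, 100))
  expect_equal(dn$reactions[[1]]$kinetics$rate_constant, 0.1)
  expect_equal(dn$reactions[[2]]$kinetics$rate_constant, 2e-6)
  expect_equal(dn$reactions[[3]]$kinetics$rate_constant, 0.3)
  # modifier counts towards the kinetic order
  expect_equal(dn$reactions[[4]]$kinetics$rate_constant, 5e-5)
  expect_error(discretize(net, -1), "positive")
  expect_error(discretize(dn, 10), "concentration-mode")
})

test_that("discretization makes count propensity = alpha * concentration rate", {
  # holds exactly for order <= 1; combinatorial correction vanishes as
  # alpha grows for higher orders
  net <- reaction_network(
    c(A = 0.5, B = 0.2),
    list(reaction(c("A", "B"), "A", mass_action(0.002)),
         reaction("A", "B", custom_rate("0.4 * A / (0.1 + A)"))),
    "concentration")
  conc_rate_ma <- 0.002 * 0.5 * 0.2
  conc_rate_custom <- 0.4 * 0.5 / (0.1 + 0.5)
  for (alpha in c(1e3, 1e6)) {
    dn <- discretize(net, alpha)
    a <- propensities(dn)
    expect_equal(a[1], alpha * conc_rate_ma, tolerance = 10 / alpha)
    expect_equal(a[2], alpha * conc_rate_custom, tolerance = 1e-12)
  }
})

test_that("quasi-deterministic conversion preserves drift at random states", {
  fix <- standard_fixture()
  net <- fix$coupled
  qd <- to_quasi_deterministic(net)
  S_src <- stoichiometry(net)
  S_qd <- stoichiometry(qd)
  set.seed(11)
  for (i in 1:50) {
    st <- stats::setNames(sample(0:300, length(net$species), replace = TRUE),
                          names(net$species))
    drift_src <- as.vector(S_src %*% propensities(net, st))
    drift_qd <- as.vector(S_qd %*% propensities(qd, st))
    expect_lt(max(abs(drift_src - drift_qd) /
                    pmax(abs(drift_src), 1e-100)), 1e-12)
  }
  # production 10, consumption 4 -> one +1 channel at 6, -1 channel at 0
  toy <- reaction_network(c(A = 0), list(
    reaction(character(), "A", mass_action(10)),
    reaction("A", character(), mass_action(2))), "count")
  tq <- to_quasi_deterministic(toy)
  a <- propensities(tq, c(A = 2))
  expect_equal(unname(a), c(6, 0))
  # production = consumption -> frozen
  expect_equal(unname(propensities(tq, c(A = 5))), c(0, 0))
})

test_that("native dialect round-trips and reports parse errors by line", {
  net <- random_network(20, 30, seed = 7)
  path <- withr::local_tempfile(fileext = ".osc")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back, net)

  # custom kinetics and modifiers survive the round trip
  net2 <- reaction_network(c(A = 3, B = 0, E = 1), list(
    reaction("A", "B", custom_rate("0.5 * A / (1 + A)")),
    reaction(c("A", "A"), "B", mass_action(0.25), modifiers = "E")),
    "count")
  write_network(net2, path)
  expect_equal(read_network(path), net2)

  writeLines(character(0), path)
  expect_error(read_network(path), "empty")
  writeLines(c("units: count", "species A = 1", "A -> B"), path)
  expect_error(read_network(path), "line 3")
  writeLines(c("units: count", "species A ="), path)
  expect_error(read_network(path), "line 2")
})

test_that("SBML import reads species and mass-action reactions", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="toy">',
    '<listOfSpecies>',
    '<species id="A" initialAmount="10"/>',
    '<species id="B" initialAmount="0"/>',
    '<species id="E" initialAmount="5"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="r1"><listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<listOfModifiers><modifierSpeciesReference species="E"/></listOfModifiers>',
    '<kineticLaw><listOfLocalParameters><localParameter id="k" value="0.4"/></listOfLocalParameters></kineticLaw>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- read_network(path, dialect = "sbml")
  expect_equal(net$species, c(A = 10, B = 0, E = 5))
  expect_length(net$reactions, 1)
  r <- net$reactions[[1]]
  expect_identical(r$reactants, c(A = 2L))
  expect_identical(r$modifiers, "E")
  expect_equal(r$kinetics$rate_constant, 0.4)

  # unsupported features are reported by name
  bad <- sub("<listOfReactions>", "<listOfRules/><listOfReactions>",
             paste(sbml, collapse = "\n"))
  writeLines(bad, path)
  expect_error(read_network(path, dialect = "sbml"), "listOfRules")
})
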