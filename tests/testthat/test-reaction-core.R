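# Reaction parsing, balance checking, completion and composition.

lib <- load_reaction_library()

test_that("reaction strings parse to exact canonical coefficients", {
  r <- parse_reaction("2 S2O3^2- + 0.5 O2 + 2 H+ -> S4O6^2- + H2O")
  expect_equal(coef_of(r, "S2O3^2-", "reactants"), 2)
  expect_equal(coef_of(r, "O2", "reactants"), 0.5)
  expect_equal(coef_of(r, "H+", "reactants"), 2)
  expect_equal(coef_of(r, "S4O6^2-", "products"), 1)
  expect_equal(coef_of(r, "H2O", "products"), 1)
  # the half coefficient is stored as the exact fraction 1/2
  i <- match("O2", r$reactants$species)
  expect_identical(r$reactants$coef[i]$n, 1)
  expect_identical(r$reactants$coef[i]$d, 2)

  r2 <- parse_reaction("4 S3O3^2- -> 8 S0 + 4 SO3^2-")
  expect_equal(coef_of(r2, "S3O3^2-", "reactants"), 4)
  expect_equal(coef_of(r2, "S0", "products"), 8)
  expect_equal(coef_of(r2, "SO3^2-", "products"), 4)

  # identity cancels to the empty reaction
  expect_true(thiostoich:::reaction_is_empty(parse_reaction("S0 -> S0")))
  # duplicate terms merge
  r3 <- parse_reaction("S0 + S0 -> S2O3^2- + S0")
  expect_equal(coef_of(r3, "S0", "reactants"), 1)
})

test_that("parser reports unknown species and malformed input", {
  expect_error(parse_reaction("S0 -> SO9^2-"), "SO9\\^2-")
  expect_error(parse_reaction("S0 + -> SO3^2-"), "parse error")
  expect_error(parse_reaction("S0 SO3^2- -> S2O3^2-"), "parse error")
  expect_error(parse_reaction("S0 -> SO3^2- -> SO4^2-"), "arrow")
  expect_error(parse_reaction("0 S0 -> SO3^2-"), "positive")
})

test_that("check_balance closes the balanced library reactions exactly", {
  r <- parse_reaction("S4O6^2- + 3.5 O2 + 3 H2O -> 4 SO4^2- + 6 H+")
  rep <- check_balance(r)
  expect_true(rep$balanced)
  expect_true(all(vapply(rep[c("residual_S", "residual_O", "residual_H",
                               "residual_charge")],
                         function(x) as.double(x) == 0, logical(1))))
  # empty reaction is trivially balanced
  expect_true(check_balance(parse_reaction("S0 -> S0"))$balanced)
})

test_that("net observed S0 reaction carries the charge misfit, not an element one", {
  # 6 S0 -> 2 SO4^2- + 4 S_OtherSOI + 5 H+ with free O2/H2O: products carry
  # 2(-2) + (-2) + 5(+1) = -1 charge that no free species can remove
  e1 <- observed_net_reactions()$net.S0.d0d5
  rep <- check_balance(e1, free_species = c("O2", "H2O"))
  expect_false(rep$balanced)
  expect_equal(as.double(rep$residual_charge), -1)
  expect_equal(as.double(rep$residual_S), 0)
  expect_equal(as.double(rep$residual_O), 0)
  expect_equal(as.double(rep$residual_H), 0)
})

test_that("balance decision agrees with the brute-force rational oracle", {
  for (rxn in lib) {
    expect_identical(
      check_balance(rxn, free_species = rxn$free_species)$balanced,
      oracle_balanced(rxn, rxn$free_species),
      info = rxn$id)
  }
  # also on the free-species grant path and on deliberately broken inputs
  e1 <- observed_net_reactions()$net.S0.d0d5
  expect_identical(check_balance(e1, free_species = c("O2", "H2O"))$balanced,
                   oracle_balanced(e1, c("O2", "H2O")))
  broken <- parse_reaction("S0 -> SO4^2-")
  expect_identical(check_balance(broken, free_species = c("O2", "H2O"))$balanced,
                   oracle_balanced(broken, c("O2", "H2O")))
  expect_identical(check_balance(broken)$balanced, oracle_balanced(broken))
})

test_that("completion regenerates every library reaction from its skeleton", {
  skeletons <- list(
    T3.eq2  = "S0 + x O2 + y H2O -> SO3^2- + z H+",
    T3.eq3  = "SO3^2- + x O2 -> SO4^2-",
    T3.eq5  = "2 S2O3^2- + x O2 + z H+ -> S4O6^2- + y H2O",
    T3.eq6  = "S4O6^2- + x O2 + y H2O -> 4 SO4^2- + z H+",
    T3.eq9  = "SO3^2- + y H2O -> SO4^2- + z H+",
    T3.eq10 = "S4O6^2- + y H2O -> S3O3^2- + SO4^2- + z H+",
    T3.eq11 = "4 S3O3^2- -> 8 S0 + 4 SO3^2-"
  )
  for (id in names(skeletons)) {
    ref <- lib[[id]]
    done <- complete_reaction(skeletons[[id]], free_species = ref$free_species)
    for (side in c("reactants", "products")) {
      for (k in seq_along(ref[[side]]$species)) {
        sp <- ref[[side]]$species[k]
        expect_equal(coef_of(done, sp, side), coef_of(ref, sp, side),
                     info = paste(id, side, sp))
      }
    }
  }
})

test_that("completion flips negatively solved species to the other side", {
  # H+ guessed on the product side must come out as 2 H+ among the reactants
  r <- complete_reaction("2 S2O3^2- + 0.5 O2 -> S4O6^2- + H2O + z H+")
  expect_equal(coef_of(r, "H+", "reactants"), 2)
  expect_equal(coef_of(r, "H+", "products"), 0)
})

test_that("completion reports unsolvable and ambiguous skeletons", {
  expect_error(complete_reaction("S0 + z H+ -> SO4^2-"), "no balanced completion")
  expect_error(complete_reaction("SO3^2- + x O2 + y O2 -> SO4^2-"),
               "underdetermined|null-space")
  expect_error(complete_reaction("S0 + x S2O3^2- -> SO3^2- + 2 H+"),
               "restricted to")
  # no unknowns: parsed reaction comes back as-is
  r <- complete_reaction("SO3^2- + 0.5 O2 -> SO4^2-")
  expect_equal(coef_of(r, "O2", "reactants"), 0.5)
})

test_that("composition reproduces the oxidative-array net reaction", {
  net <- compose_reactions(list(
    list(lib[["T3.eq2"]], 4), list(lib[["T3.eq3"]], 2),
    list(lib[["T3.eq4f"]], 2), list(lib[["T3.eq5"]], 1)))
  # 6 S0 + 5.5 O2 + 3 H2O -> 2 SO4^2- + S4O6^2- + 6 H+
  expect_equal(coef_of(net, "S0", "reactants"), 6)
  expect_equal(coef_of(net, "O2", "reactants"), 5.5)
  expect_equal(coef_of(net, "H2O", "reactants"), 3)
  expect_equal(coef_of(net, "SO4^2-", "products"), 2)
  expect_equal(coef_of(net, "S4O6^2-", "products"), 1)
  expect_equal(coef_of(net, "H+", "products"), 6)
  # intermediates cancelled completely
  for (sp in c("SO3^2-", "S2O3^2-")) {
    expect_equal(coef_of(net, sp, "reactants"), 0)
    expect_equal(coef_of(net, sp, "products"), 0)
  }
})

test_that("composition is linear and cancels shared intermediates", {
  n1 <- compose_reactions(list(list(lib[["T3.eq2"]], 1), list(lib[["T3.eq4f"]], 1)))
  # SO3^2- cancels: 2 S0 + O2 + H2O -> S2O3^2- + 2 H+
  expect_equal(coef_of(n1, "S0", "reactants"), 2)
  expect_equal(coef_of(n1, "S2O3^2-", "products"), 1)
  expect_equal(coef_of(n1, "SO3^2-", "products"), 0)
  # compose(A, m) + compose(A, n) == compose(A, m + n), species-wise
  for (m in c(1, 2)) {
    for (n in c(0.5, 3)) {
      a <- compose_reactions(list(list(lib[["T3.eq5"]], m + n)))
      b <- compose_reactions(list(list(lib[["T3.eq5"]], m),
                                  list(lib[["T3.eq5"]], n)))
      for (sp in c("S2O3^2-", "O2", "H+", "S4O6^2-", "H2O")) {
        expect_equal(coef_of(a, sp, "reactants"), coef_of(b, sp, "reactants"))
        expect_equal(coef_of(a, sp, "products"), coef_of(b, sp, "products"))
      }
    }
  }
  # zero multiplier and empty list give the empty reaction
  expect_true(thiostoich:::reaction_is_empty(
    compose_reactions(list(list(lib[["T3.eq2"]], 0)))))
  expect_true(thiostoich:::reaction_is_empty(compose_reactions(list())))
})

test_that("library loads balanced, rejects unbalanced, conserves sulfur", {
  expect_gte(length(lib), 9)
  expect_true(all(c("T3.eq2", "T3.eq3", "T3.eq4f", "T3.eq4r", "T3.eq5",
                    "T3.eq6", "T3.eq9", "T3.eq10", "T3.eq11") %in% names(lib)))
  reg <- species_registry()
  for (rxn in lib) {
    s_l <- sum(vapply(seq_along(rxn$reactants$species), function(i) {
      as.double(rxn$reactants$coef[i]) *
        reg$n_S[reg$name == rxn$reactants$species[i]]
    }, numeric(1)))
    s_r <- sum(vapply(seq_along(rxn$products$species), function(i) {
      as.double(rxn$products$coef[i]) *
        reg$n_S[reg$name == rxn$products$species[i]]
    }, numeric(1)))
    expect_equal(s_l, s_r, info = rxn$id)
  }
  # a library containing an unbalanced elementary reaction is rejected
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(id = "bad", equation = "S0 -> SO4^2-",
                                 source = "table3")),
                       bad, auto_unbox = TRUE)
  expect_error(load_reaction_library(bad), "O=4")
  # empty library: warning, zero reactions
  empty <- tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_warning(l0 <- load_reaction_library(empty), "empty")
  expect_length(l0, 0)
})

test_that("libraries round-trip through the JSON schema", {
  p <- tempfile(fileext = ".json")
  write_reaction_library(lib, p)
  lib2 <- load_reaction_library(p)
  expect_identical(names(lib2), names(lib))
  for (id in names(lib)) {
    expect_equal(reaction_string(lib2[[id]]), reaction_string(lib[[id]]))
    expect_identical(lib2[[id]]$source, lib[[id]]$source)
  }
})
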