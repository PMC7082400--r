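# Net-reaction normalisation, nonnegative extent fitting, model comparison.

lib <- load_reaction_library()

test_that("normalising the day-5 pools to 6 S atoms gives the 2:4 split", {
  d <- delta_vector(c(0, 5),
                    d_species = c("SO4^2-" = 13.7, "S0" = -39),
                    d_proton = 31.52, d_other_soi = 25.3)
  nr <- normalize_net_reaction(d, 6)
  expect_equal(coef_of(nr$reaction, "SO4^2-", "products"), 2)
  expect_equal(coef_of(nr$reaction, "S_OtherSOI", "products"), 4)
  expect_equal(coef_of(nr$reaction, "S0", "reactants"), 6)
  expect_equal(nr$proton_coef, 5)
  expect_true(all(nr$rounding_residuals < 0.5))
})

test_that("equal produced pools normalise to 2,2,2 over 6 S atoms", {
  d <- delta_vector(c(0, 4),
                    d_species = c("S0" = 5, "SO4^2-" = 5, "S2O3^2-" = -15),
                    d_proton = 2.5, d_other_soi = 5)
  nr <- normalize_net_reaction(d, 6)
  expect_equal(coef_of(nr$reaction, "S0", "products"), 2)
  expect_equal(coef_of(nr$reaction, "SO4^2-", "products"), 2)
  expect_equal(coef_of(nr$reaction, "S_OtherSOI", "products"), 2)
  # 15 mM-S thiosulfate consumed = 7.5 mM molecules, scaled by 6/15 -> 3
  expect_equal(coef_of(nr$reaction, "S2O3^2-", "reactants"), 3)
  expect_equal(nr$proton_coef, 1)
})

test_that("normalisation is scale invariant and handles edge cases", {
  d <- delta_vector(c(0, 5), d_species = c("SO4^2-" = 13.7, "S0" = -39),
                    d_other_soi = 25.3)
  for (k in c(0.1, 1, 17)) {
    dk <- d
    dk$d_species <- dk$d_species * k
    dk$d_other_soi <- dk$d_other_soi * k
    nrk <- normalize_net_reaction(dk, 6)
    expect_equal(coef_of(nrk$reaction, "SO4^2-", "products"), 2)
    expect_equal(coef_of(nrk$reaction, "S_OtherSOI", "products"), 4)
  }
  # single product pool takes the whole target
  d1 <- delta_vector(c(0, 1), d_species = c("SO4^2-" = 3, "S0" = -3))
  expect_equal(coef_of(normalize_net_reaction(d1, 6)$reaction,
                       "SO4^2-", "products"), 6)
  # nothing produced is a domain error
  expect_error(normalize_net_reaction(
    delta_vector(c(0, 1), d_species = c("S0" = -1))), "no produced")
  # auto mode picks a small consistent target for a clean 1:2 split
  auto <- normalize_net_reaction(d)
  expect_lte(auto$s_total_target, 6)
  expect_lt(max(auto$rounding_residuals), 0.15)
})

test_that("noiseless construct-and-recover is exact for identifiable subsets", {
  ids <- c("T3.eq2", "T3.eq3", "T3.eq4f", "T3.eq5")
  sub <- lib_subset(lib, ids)
  M <- stoich_matrix(sub)
  set.seed(42)
  for (rep in 1:20) {
    x0 <- stats::setNames(stats::runif(length(ids), 0, 10), ids)
    dvec <- as.numeric(M %*% x0)
    names(dvec) <- rownames(M)
    d <- delta_vector(c(0, 1),
                      d_species = dvec[setdiff(names(dvec), c("OtherSOI", "H+"))],
                      d_proton = dvec[["H+"]],
                      d_other_soi = dvec[["OtherSOI"]])
    fit <- fit_extents(d, sub)
    expect_lt(sqrt(sum(fit$residual^2)), 1e-8 * max(1, sqrt(sum(dvec^2))))
    expect_lt(max(abs(fit$extents - x0)), 1e-6 * max(1, sqrt(sum(dvec^2))))
    expect_equal(fit$nullspace_dim, 0)
  }
})

test_that("full-library fits flag the null space but still drive residuals to zero", {
  ids <- c("T3.eq2", "T3.eq3", "T3.eq4f", "T3.eq5")
  M <- stoich_matrix(lib_subset(lib, ids))
  x0 <- stats::setNames(c(26.35, 13.7, 12.65, 6.325), ids)
  dvec <- as.numeric(M %*% x0); names(dvec) <- rownames(M)
  d <- delta_vector(c(0, 5),
                    d_species = dvec[setdiff(names(dvec), c("OtherSOI", "H+"))],
                    d_proton = dvec[["H+"]], d_other_soi = dvec[["OtherSOI"]])
  fit <- fit_extents(d, lib)
  expect_gt(fit$nullspace_dim, 0)
  expect_false(all(fit$identifiable))
  expect_lt(sqrt(sum(fit$residual^2)), 1e-8 * sqrt(sum(dvec^2)))
})

test_that("an L1 penalty recovers a sparse generating pair", {
  # tetrathionate formation + oxidation is the minimum-turnover explanation
  # of its own signature; the penalised fit must find exactly that pair
  sub_ids <- c("T3.eq5", "T3.eq6")
  M2 <- stoich_matrix(lib_subset(lib, sub_ids))
  dvec <- as.numeric(M2 %*% c(1, 1)); names(dvec) <- rownames(M2)
  d <- delta_vector(c(0, 1),
                    d_species = dvec[setdiff(names(dvec), c("OtherSOI", "H+"))],
                    d_proton = dvec[["H+"]], d_other_soi = dvec[["OtherSOI"]])
  fit <- fit_extents(d, lib, l1 = "auto")
  on <- names(fit$extents)[fit$extents > 1e-4]
  expect_setequal(on, sub_ids)
  expect_equal(unname(fit$extents[sub_ids]), c(1, 1), tolerance = 1e-2)
})

test_that("zero observations give zero extents and objective", {
  d <- delta_vector(c(0, 1),
                    d_species = c("SO4^2-" = 0, "S0" = 0, "S2O3^2-" = 0,
                                  "SO3^2-" = 0, "S^2-" = 0),
                    d_proton = 0, d_other_soi = 0)
  fit <- fit_extents(d, lib)
  expect_true(all(fit$extents == 0))
  expect_equal(fit$objective, 0)
})

test_that("proton prediction matches the composed stoichiometry", {
  # oxidative array: +6 mM H+ per 6 mM S0 at the 4:2:2:1 basis
  expect_equal(predict_proton(c(T3.eq2 = 4, T3.eq3 = 2, T3.eq4f = 2,
                                T3.eq5 = 1), lib), 6)
  # tetrathionate formation consumes acid
  expect_equal(predict_proton(c(T3.eq5 = 1), lib), -2)
  expect_equal(predict_proton(stats::setNames(numeric(0), character(0)), lib), 0)
  expect_error(predict_proton(c(nope = 1), lib), "unknown reaction")
})

test_that("sulfur closure: library columns sum to zero over all S rows", {
  M <- stoich_matrix(lib)
  s_rows <- setdiff(rownames(M), "H+")
  expect_true(all(abs(colSums(M[s_rows, ])) < 1e-12))
  # consequence: any nonnegative extents conserve sulfur
  set.seed(7)
  x <- stats::runif(ncol(M), 0, 5)
  expect_lt(abs(sum((M %*% x)[s_rows, ])), 1e-10)
})

test_that("oxidative-only extents never consume net acid", {
  set.seed(11)
  for (rep in 1:50) {
    x <- stats::setNames(stats::runif(4, 0, 10),
                         c("T3.eq2", "T3.eq3", "T3.eq6", "T3.eq9"))
    expect_gte(predict_proton(x, lib), 0)
  }
})

test_that("disproportionation reactions win on the late thiosulfate signature", {
  sc <- batch_scenarios()
  sim <- simulate_batch(sc$thiosulfate_days0to4)
  d <- deltas(sim$series, 2, 4)
  # the observed pattern: unresolved SOI down, S0 up, sulfate flat, acid down
  expect_lt(d$d_other_soi, 0)
  expect_gt(d$d_species[["S0"]], 0)
  expect_equal(d$d_species[["SO4^2-"]], 0, tolerance = 1e-9)
  expect_lt(d$d_proton, 0)
  cm <- compare_models(d, list(
    oxidative = c("T3.eq5", "T3.eq6", "T3.eq9"),
    dispro = c("T3.eq5", "T3.eq6", "T3.eq9", "T3.eq10", "T3.eq11", "T3.eq4f")),
    lib, include_proton = FALSE)
  expect_equal(cm$ranking$subset[1], "T3.eq5+T3.eq6+T3.eq9+T3.eq10+T3.eq11+T3.eq4f")
  expect_true(cm$disproportionation$supported)
  # oxidative-only cannot make S0: its S0-row residual equals the full change
  oxi <- cm$fits[[match("T3.eq5+T3.eq6+T3.eq9", cm$ranking$subset)]]
  expect_equal(oxi$residual[["S0"]], -d$d_species[["S0"]], tolerance = 1e-6)
})

test_that("parsimony breaks ties when the small subset explains the data", {
  ids <- c("T3.eq2", "T3.eq3")
  M <- stoich_matrix(lib_subset(lib, ids))
  dvec <- as.numeric(M %*% c(2, 1)); names(dvec) <- rownames(M)
  d <- delta_vector(c(0, 1),
                    d_species = dvec[setdiff(names(dvec), c("OtherSOI", "H+"))],
                    d_proton = dvec[["H+"]], d_other_soi = dvec[["OtherSOI"]])
  cm <- compare_models(d, list(small = ids, big = names(lib)), lib)
  expect_equal(cm$ranking$n_reactions[1], 2)
  cm1 <- compare_models(d, list(only = ids), lib)
  expect_equal(nrow(cm1$ranking), 1)
  expect_error(compare_models(d, list(), lib), "no candidate")
})

test_that("noisy deltas still recover extents to better than 15% median error", {
  ids <- c("T3.eq2", "T3.eq3", "T3.eq4f", "T3.eq5")
  sub <- lib_subset(lib, ids)
  sc <- batch_scenarios()
  sim <- simulate_batch(sc$S0_days0to5)
  d0 <- deltas(sim$series, 0, 5)
  truth <- colSums(sim$true_extents)[ids]
  set.seed(20200313)
  med_errs <- replicate(200, {
    fit <- fit_extents(perturb_delta(d0, 0.05), sub, include_proton = FALSE)
    stats::median(abs(fit$extents[ids] - truth) / truth)
  })
  expect_lt(stats::median(med_errs), 0.15)
})
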