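# Batch-culture simulator: conservation, calibration, determinism, recovery.

lib <- load_reaction_library()
scen <- batch_scenarios()

test_that("noiseless simulation deltas equal the scheduled stoichiometry", {
  sim <- simulate_batch(scen$thiosulfate_days0to4)
  M <- stoich_matrix(lib)
  for (w in 1:2) {
    iv <- scen$thiosulfate_days0to4$schedule[[w]]
    d <- deltas(sim$series, iv$interval[1], iv$interval[2])
    pred <- as.numeric(M %*% sim$true_extents[w, ])
    names(pred) <- rownames(M)
    scale <- max(1, max(abs(pred)))
    for (s in names(d$d_species)) {
      expect_equal(d$d_species[[s]], pred[[s]], tolerance = 1e-9 * scale,
                   info = s)
    }
    expect_equal(d$d_other_soi, pred[["OtherSOI"]], tolerance = 1e-9 * scale)
  }
})

test_that("sulfur is conserved across all pools in noiseless runs", {
  for (nm in names(scen)) {
    sim <- simulate_batch(scen[[nm]])
    reg <- species_registry()
    st <- sim$state
    n_s <- vapply(setdiff(names(st), c("day", "H+")), function(s) {
      if (s == "S0_particulate") 1 else reg$n_S[reg$name == s]
    }, numeric(1))
    tot <- as.matrix(st[, names(n_s)]) %*% n_s
    expect_lt(max(abs(tot - tot[1])) / tot[length(tot)], 1e-9)
  }
})

test_that("the S0 scenario reproduces its calibrated endpoints", {
  sim <- simulate_batch(scen$S0_days0to5)
  df <- sim$series$data
  last <- nrow(df)
  expect_equal(df[["SO4^2-"]][last], 13.7, tolerance = 1e-9)
  expect_equal(other_soi(sim$series)[last], 25.3, tolerance = 1e-9)
  expect_equal(df$pH[last], 1.5)
  expect_equal(df$pH[df$day == 3], 2.5)  # exponential-phase sampling point
  # ~1% m/v substrate loading in sulfur atoms
  expect_equal(df$S0_particulate[1], 311.9, tolerance = 1e-3)
  # the observed proton rise normalises to 5 H+ per 6 S0 (not the model's 6)
  d <- deltas(sim$series, 0, 5)
  nr <- normalize_net_reaction(d, 6)
  expect_equal(nr$proton_coef, 5)
  expect_equal(coef_of(nr$reaction, "SO4^2-", "products"), 2)
  expect_equal(coef_of(nr$reaction, "S_OtherSOI", "products"), 4)
})

test_that("the thiosulfate scenario reproduces its calibrated endpoints", {
  sim <- simulate_batch(scen$thiosulfate_days0to4)
  df <- sim$series$data
  # 0.2% m/v sodium thiosulfate = 12.65 mM = 25.3 mM-S, conserved throughout
  expect_equal(df[["S2O3^2-"]][1], 12.65)
  expect_true(all(abs(df$total_s - 25.3) < 1e-9))
  last <- nrow(df)
  expect_equal(df[["SO4^2-"]][last], 7.8, tolerance = 1e-9)
  expect_equal(other_soi(sim$series)[last], 6.9, tolerance = 1e-9)
  expect_equal(df$pH[last], 2.5)
  expect_lt(df[["SO3^2-"]][last], 0.5)   # sulfite stays near detection
  expect_gt(df[["S0"]][last], 0)         # elemental sulfur accumulates late
})

test_that("seeded simulations are byte-identical and noise is seed-sensitive", {
  noisy <- scen$S0_days0to5
  noisy$noise_cv <- 0.05
  a <- simulate_batch(noisy, seed = 77)
  b <- simulate_batch(noisy, seed = 77)
  expect_identical(a$series$data, b$series$data)
  c <- simulate_batch(noisy, seed = 78)
  expect_false(identical(a$series$data, c$series$data))
  # and the file form round-trips identically too
  fa <- tempfile(); fb <- tempfile()
  write_speciation_csv(a$series, fa)
  write_speciation_csv(b$series, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("detection-limit censoring zeroes and flags small values", {
  s <- scen$thiosulfate_days0to4
  s$lod <- c("S2O3^2-" = 1.0)
  sim <- simulate_batch(s)
  censored <- sim$series$data[["S2O3^2-"]] == 0 & sim$true_series$data[["S2O3^2-"]] > 0
  expect_true(any(sim$series$below_lod[["S2O3^2-"]]))
  expect_equal(which(censored), which(sim$series$below_lod[["S2O3^2-"]] &
                                        sim$true_series$data[["S2O3^2-"]] > 0))
})

test_that("infeasible schedules are clipped with a warning (or raise in strict mode)", {
  bad <- batch_scenario(
    treatment = "thiosulfate",
    initial_conc = c("S2O3^2-" = 1),
    schedule = list(list(interval = c(0, 1), extents = c(T3.eq5 = 10))),
    noise_cv = 0, initial_ph = 2)
  expect_warning(sim <- simulate_batch(bad), "clipped")
  expect_gte(min(as.matrix(sim$state[, -1])), 0)
  expect_error(simulate_batch(bad, strict = TRUE), "infeasible")
})

test_that("fitting the noiseless fixture deltas recovers the schedule", {
  sim <- simulate_batch(scen$S0_days0to5)
  ids <- c("T3.eq2", "T3.eq3", "T3.eq4f", "T3.eq5")
  d <- deltas(sim$series, 0, 5)
  fit <- fit_extents(d, lib_subset(lib, ids), include_proton = FALSE)
  truth <- colSums(sim$true_extents)[ids]
  expect_lt(sqrt(sum(fit$residual^2)), 1e-8)
  expect_equal(unname(fit$extents[ids]), unname(truth), tolerance = 1e-9)
})

test_that("simulated expression respects its target categories deterministically", {
  design <- data.frame(
    gene = c("tetH", "sqr", "sox-1", "sdo-1"),
    condition = "c1",
    category = c("very_high", "medium", "high", "none_low"))
  p1 <- simulate_expression(design, seed = 123)$c1
  p2 <- simulate_expression(design, seed = 123)$c1
  expect_identical(p1$entries, p2$entries)
  expect_gt(p1$entries$fpkm[p1$entries$gene == "tetH"], 10000)
  expect_lt(p1$entries$fpkm[p1$entries$gene == "sdo-1"], 200)
  expect_equal(as.character(categorize_fpkm(p1$entries$fpkm)),
               design$category)
  expect_error(simulate_expression(data.frame(gene = "g", condition = "c",
                                              category = "huge")),
               "unknown target")
})
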