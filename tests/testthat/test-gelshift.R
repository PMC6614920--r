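test_that("fraction dimerized from bands is the dimer share of the lane", {
  expect_equal(fraction_dimer_from_bands(1, 0), 0)
  expect_equal(fraction_dimer_from_bands(0, 1), 1)
  expect_equal(fraction_dimer_from_bands(3, 1), 0.25)
  expect_warning(out <- fraction_dimer_from_bands(c(1, 0), c(1, 0)), "zero")
  expect_equal(out, c(0.5, NA))
  expect_error(fraction_dimer_from_bands(-1, 1), "non-negative")
})

test_that("noiseless titrations return the generating parameters", {
  M0 <- gelshift_ladder()
  fD <- homodimer_fraction(M0, 100, 0.9)
  fit <- fit_homodimer(M0, fD)
  expect_true(fit$converged)
  expect_equal(fit$Kd_nM, 100, tolerance = 1e-4)
  expect_equal(fit$beta, 0.9, tolerance = 1e-4)
})

test_that("non-assembling series are flagged instead of fitted", {
  M0 <- gelshift_ladder()
  # closed-form check that this Kd keeps fD below the 0.05 call threshold
  expect_lt(max(homodimer_fraction(M0, 1e7, 1)), 0.05)
  fit <- fit_homodimer(M0, homodimer_fraction(M0, 1e7, 1))
  expect_true(fit$no_assembly)
  expect_equal(fit$Kd_nM, max(M0))  # lower bound: top of the ladder
})

test_that("fits are invariant to row shuffling and respect fix_beta", {
  M0 <- gelshift_ladder()
  sim <- simulate_gelshift(150, 1, noise_sd_fD = 0.02, n_replicates = 1,
                           seed = 11)
  perm <- sample(nrow(sim))
  f1 <- fit_homodimer(sim$M0_nM, sim$fD)
  f2 <- fit_homodimer(sim$M0_nM[perm], sim$fD[perm])
  expect_equal(f1$Kd_nM, f2$Kd_nM)
  # on exact beta = 1 data, fixing beta changes nothing
  y <- homodimer_fraction(M0, 150, 1)
  f_free <- fit_homodimer(M0, y)
  f_fix <- fit_homodimer(M0, y, fix_beta = 1)
  expect_equal(f_fix$beta, 1)
  expect_lt(abs(f_fix$Kd_nM / f_free$Kd_nM - 1), 0.01)
})

test_that("true parameters are a local optimum on noiseless data", {
  M0 <- gelshift_ladder()
  y <- homodimer_fraction(M0, 200, 0.85)
  rss <- function(Kd, beta) sum((homodimer_fraction(M0, Kd, beta) - y)^2)
  base <- rss(200, 0.85)
  for (eps in c(-0.05, 0.05)) {
    expect_lte(base, rss(200 * (1 + eps), 0.85) * (1 + 1e-6))
    expect_lte(base, rss(200, 0.85 * (1 + eps)) * (1 + 1e-6))
  }
})

test_that("parameter recovery holds across the measured Kd range", {
  # triplicate series, as measured: each replicate is fitted and the
  # estimates averaged before judging the error
  for (true_kd in c(26, 98, 1944, 3694)) {
    rel_kd <- rel_beta <- numeric(50)
    for (s in 1:50) {
      sim <- simulate_gelshift(true_kd, 0.85, noise_sd_fD = 0.02,
                               n_replicates = 3, seed = s)
      fit <- fit_gelshift_table(sim)
      rel_kd[s] <- abs(fit$Kd_nM / true_kd - 1)
      rel_beta[s] <- abs(fit$beta / 0.85 - 1)
    }
    expect_lt(median(rel_kd), 0.10)
    expect_lt(median(rel_beta), 0.05)
  }
})

test_that("replicate aggregation averages estimates and ORs flags", {
  mk <- function(kd, ...) {
    M0 <- gelshift_ladder()
    f <- fit_homodimer(M0, homodimer_fraction(M0, kd, 0.9))
    utils::modifyList(f, list(...))
  }
  fits <- list(mk(24), mk(26), mk(28))
  agg <- aggregate_replicates(fits)
  expect_equal(agg$Kd_nM, 26, tolerance = 1e-3)
  expect_equal(agg$Kd_sd_nM, 2, tolerance = 1e-3)
  expect_equal(agg$n_replicates, 3L)

  same <- aggregate_replicates(list(mk(98), mk(98), mk(98)))
  expect_equal(same$Kd_nM, 98, tolerance = 1e-3)
  expect_equal(same$Kd_sd_nM, 0, tolerance = 1e-6)

  expect_warning(single <- aggregate_replicates(list(mk(26))), "replicate")
  expect_true(is.na(single$Kd_sd_nM))

  flagged <- aggregate_replicates(list(mk(26), mk(26, no_assembly = TRUE)),
                                  warn = FALSE)
  expect_true(flagged$no_assembly)
  expect_error(aggregate_replicates(list()), "no fits")
})

test_that("heterodimer fits recover a noiseless titration exactly", {
  C <- heterodimer_ladder()
  fit <- fit_heterodimer(C, heterodimer_fraction(C, 38))
  expect_equal(fit$Kd_nM, 38, tolerance = 1e-6)
  flat <- fit_heterodimer(C, rep(0.001, length(C)))
  expect_true(flat$no_assembly)
})

test_that("the table interface groups by construct and condition", {
  sim <- rbind(simulate_gelshift(26, 0.85, construct_id = "980", seed = 1),
               simulate_gelshift(98, 0.85, construct_id = "4LVV", seed = 2))
  out <- fit_gelshift_table(sim)
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_replicates, c(3L, 3L))
  expect_lt(abs(out$Kd_nM[out$construct_id == "980"] / 26 - 1), 0.3)
  expect_lt(abs(out$Kd_nM[out$construct_id == "4LVV"] / 98 - 1), 0.3)
  expect_error(fit_gelshift_table(sim[, -1]), "missing column")
})
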