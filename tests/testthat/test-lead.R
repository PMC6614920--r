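test_that("band integration subtracts a local median baseline", {
  expect_equal(integrate_band(rep(5, 20), 8:12, 3), 0)
  spike <- rep(0, 15); spike[8] <- 7
  expect_equal(integrate_band(spike, 8, 3), 7)
  rect <- rep(2, 20); rect[9:11] <- 10
  expect_equal(integrate_band(rect, 9:11, 4), 24)   # (10 - 2) * 3
  expect_error(integrate_band(rep(1, 10), 1:3, 2), "flank")
  expect_error(integrate_band(rep(1, 10), c(4, 6), 2), "contiguous")
})

test_that("two-state normalization maps extremes onto monomer and dimer", {
  M0 <- c(10, 100, 1000, 10000)
  dec <- normalize_two_state(M0, c(1.0, 0.8, 0.4, 0.2), "decreasing")
  expect_equal(dec$fM[1], 1)   # I = Imax: full monomer
  expect_equal(dec$fM[4], 0)   # I = Imin: full dimer
  inc <- normalize_two_state(M0, c(0.2, 0.6, 0.9, 1.0), "increasing")
  expect_equal(inc$fM[1], 1)
  expect_equal(inc$fM[2], 0.5)  # midway intensity -> fM = 0.5
  expect_error(normalize_two_state(M0, rep(3, 4)), "uninformative")
})

test_that("normalized fractions stay in [0, 1] for arbitrary intensities", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(12, 5, 4)
    M0 <- sort(abs(rnorm(12, 100, 50))) + seq_len(12)
    for (dir in c("decreasing", "increasing")) {
      fM <- normalize_two_state(M0, x, dir)$fM
      expect_true(all(fM >= 0 & fM <= 1))
    }
  }
})

test_that("two-state fits invert noiseless profiles exactly", {
  for (kd in c(63, 266, 300, 1573)) {
    ld <- simulate_lead_profiles(kd, kd, noise_sd_frac = 0, seed = 1)
    d0 <- ld[ld$fa_uM == 0, ]
    fit <- fit_two_state(normalize_two_state(d0$M0_nM, d0$intensity,
                                             "decreasing"))
    expect_lt(abs(fit$Kd_nM / kd - 1), 1e-3)
  }
  # raw (unanchored) monomer fractions also invert
  M0 <- lead_ladder()
  fit <- fit_two_state(M0, 1 - homodimer_fraction(M0, 300, 1))
  expect_lt(abs(fit$Kd_nM / 300 - 1), 1e-3)
})

test_that("a monomer-only series raises the no-assembly flag", {
  fit <- fit_two_state(lead_ladder(), rep(1, 13))
  expect_true(fit$no_assembly)
  expect_equal(fit$Kd_nM, max(lead_ladder()))
})

test_that("protection calls classify ratios against the fold threshold", {
  mono <- c(A10 = 1.0, U11 = 0.9, C14 = 0.2, C18 = 1.1, G9 = 0.5)
  dimer <- c(A10 = 0.2, U11 = 0.88, C14 = 1.0, C18 = 0.3, G9 = 0.5)
  calls <- call_protections(mono, dimer, fold_threshold = 1.5)
  dir <- setNames(calls$direction, calls$position)
  expect_identical(dir[["A10"]], "PROTECTED_IN_DIMER")
  expect_identical(dir[["C18"]], "PROTECTED_IN_DIMER")
  expect_identical(dir[["C14"]], "ENHANCED_IN_DIMER")   # bulge enhancement
  expect_identical(dir[["U11"]], "UNCHANGED")
  expect_identical(dir[["G9"]], "UNCHANGED")
  expect_true(all(calls$magnitude >= 1))

  same <- call_protections(mono, mono)
  expect_true(all(same$direction == "UNCHANGED"))

  # antisymmetry: swapping the states exchanges protected and enhanced
  swapped <- call_protections(dimer, mono, fold_threshold = 1.5)
  sdir <- setNames(swapped$direction, swapped$position)
  expect_identical(sdir[["A10"]], "ENHANCED_IN_DIMER")
  expect_identical(sdir[["C14"]], "PROTECTED_IN_DIMER")

  expect_error(call_protections(mono, dimer[-1]), "position sets")
})

test_that("ligand-specific calls compare the two dimer states", {
  dimer_noFA <- c(G9 = 1.0, A10 = 1.0, C14 = 0.3)
  dimer_FA <- c(G9 = 0.4, A10 = 0.5, C14 = 0.9)
  calls <- call_protections(c(G9 = 1, A10 = 1, C14 = 0.3), dimer_noFA,
                            fa_dimer_state = dimer_FA)
  fa <- calls[calls$comparison == "fa", ]
  fdir <- setNames(fa$direction, fa$position)
  expect_identical(fdir[["G9"]], "FA_SPECIFIC_PROTECTED")
  expect_identical(fdir[["C14"]], "FA_SPECIFIC_ENHANCED")
})

test_that("the lead table interface estimates Kd per condition", {
  ld <- simulate_lead_profiles(1573, 266, seed = 5)
  out <- fit_lead_table(ld)
  expect_equal(nrow(out), 2L)
  expect_lt(abs(out$Kd_nM[out$fa_uM == 0] / 1573 - 1), 0.25)
  expect_lt(abs(out$Kd_nM[out$fa_uM == 200] / 266 - 1), 0.25)
})
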