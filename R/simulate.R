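# Synthetic-data generators: forward models of the gel-shift and lead
# cleavage assays, plus the curated loop-receptor signature set.
#
# Generator defaults encode the study conditions: gel-shift ladders span
# 5-20000 nM total RNA in two-fold steps (lead: 5 nM-20 uM), fits are
# averaged over 3 replicates, additive Gaussian noise on fraction
# dimerized has sd 0.02 and lane loading is lognormal with sdlog 0.05;
# lead intensities carry 3% multiplicative noise.

#' Default gel-shift concentration ladder (nM)
#'
#' Two-fold steps from 5 nM capped at the 20000 nM top concentration.
#' @return numeric vector, nM.
#' @export
gelshift_ladder <- function() c(5 * 2^(0:11), 20000)

#' Default lead-probing concentration ladder (nM)
#'
#' 5 nM to 20 uM in two-fold steps.
#' @return numeric vector, nM.
#' @export
lead_ladder <- function() c(5 * 2^(0:11), 20000)

#' Default equimolar heterodimer ladder (nM)
#'
#' Two-fold steps from 2 nM capped at 2000 nM per partner.
#' @return numeric vector, nM.
#' @export
heterodimer_ladder <- function() c(2 * 2^(0:9), 2000)

#' Simulate gel-shift titration data
#'
#' Forward model: the true fraction dimerized comes from
#' [homodimer_fraction()]; observed `fD` adds Gaussian noise (sd
#' `noise_sd_fD`) clipped to \[0, 1\]; band intensities are back-computed
#' as `I_D = fD`, `I_M = 1 - fD` scaled by a per-lane lognormal loading
#' factor. Identical seeds give identical tables.
#'
#' @param true_Kd_nM generating dissociation constant, nM.
#' @param true_beta generating active fraction (default 0.85).
#' @param concentrations_nM titration ladder (default [gelshift_ladder()]).
#' @param noise_sd_fD additive sd on fD (default 0.02).
#' @param n_replicates independent replicate series (default 3).
#' @param loading_sdlog lognormal sdlog of the lane loading factor.
#' @param construct_id,mg_mM,temperature_K,fa_uM condition annotation.
#' @param seed RNG seed (restored afterwards).
#' @return data.frame in the gel-shift input layout, with the generating
#'   parameters in `attr(, "truth")`.
#' @export
simulate_gelshift <- function(true_Kd_nM, true_beta = 0.85,
                              concentrations_nM = gelshift_ladder(),
                              noise_sd_fD = 0.02, n_replicates = 3L,
                              loading_sdlog = 0.05, construct_id = "sim",
                              mg_mM = 2, temperature_K = 280, fa_uM = 0,
                              seed = 1L) {
  stopifnot(true_Kd_nM > 0, true_beta > 0, true_beta <= 1, noise_sd_fD >= 0,
            n_replicates >= 1L, all(diff(concentrations_nM) > 0))
  fD_true <- homodimer_fraction(concentrations_nM, true_Kd_nM, true_beta)
  n <- length(concentrations_nM)
  df <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      fD_obs <- clip01(fD_true + stats::rnorm(n, 0, noise_sd_fD))
      load <- stats::rlnorm(n, 0, loading_sdlog)
      data.frame(construct_id = construct_id,
                 replicate_id = sprintf("rep%d", r),
                 mg_mM = mg_mM, temperature_K = temperature_K, fa_uM = fa_uM,
                 M0_nM = concentrations_nM,
                 monomer_intensity = (1 - fD_obs) * load,
                 dimer_intensity = fD_obs * load,
                 fD = fD_obs, stringsAsFactors = FALSE)
    }))
  })
  structure(df, truth = list(true_Kd_nM = true_Kd_nM, true_beta = true_beta,
                             noise_sd_fD = noise_sd_fD, seed = seed))
}

#' Simulate a +/- ligand pair of lead-cleavage profiles
#'
#' Forward model (the two-state convention): per lane the monomer fraction
#' is `fM = 1 - homodimer_fraction(M0, Kd, beta = 1)` with the condition's
#' `Kd`; each position's intensity is the linear mix
#' `fM * I_monomer + (1 - fM) * I_dimer` times `1 + N(0, noise_sd_frac)`,
#' floored at 0. The +FA condition uses `true_Kd_FA_nM`.
#'
#' @param true_Kd_noFA_nM,true_Kd_FA_nM generating dissociation constants
#'   for the ligand-free and +ligand conditions, nM (for responsive
#'   constructs `true_Kd_FA_nM <= true_Kd_noFA_nM`).
#' @param positions data.frame with `position`, `direction`
#'   (`"decreasing"`/`"increasing"`), `I_monomer`, `I_dimer`. The default
#'   is a single protected (decreasing) position with intensities 1.0
#'   (monomer) and 0.2 (dimer).
#' @param concentrations_nM ladder (default [lead_ladder()]).
#' @param noise_sd_frac multiplicative noise sd (default 0.03).
#' @param construct_id,mg_mM,temperature_K condition annotation (lead
#'   probing defaults to 293 K / 20 deg C).
#' @param seed RNG seed.
#' @return data.frame with columns `construct_id`, `mg_mM`,
#'   `temperature_K`, `fa_uM` (0 and 200), `M0_nM`, `position`,
#'   `direction`, `intensity`; generating parameters in `attr(, "truth")`.
#' @export
simulate_lead_profiles <- function(true_Kd_noFA_nM, true_Kd_FA_nM,
                                   positions = data.frame(
                                     position = "A10",
                                     direction = "decreasing",
                                     I_monomer = 1.0, I_dimer = 0.2,
                                     stringsAsFactors = FALSE),
                                   concentrations_nM = lead_ladder(),
                                   noise_sd_frac = 0.03,
                                   construct_id = "sim", mg_mM = 0.5,
                                   temperature_K = 293, seed = 1L) {
  stopifnot(true_Kd_noFA_nM > 0, true_Kd_FA_nM > 0, noise_sd_frac >= 0,
            all(diff(concentrations_nM) > 0),
            all(positions$I_monomer != positions$I_dimer))
  one_condition <- function(Kd, fa_uM) {
    fM <- 1 - homodimer_fraction(concentrations_nM, Kd, 1)
    do.call(rbind, lapply(seq_len(nrow(positions)), function(i) {
      p <- positions[i, ]
      clean <- fM * p$I_monomer + (1 - fM) * p$I_dimer
      obs <- pmax(0, clean * (1 + stats::rnorm(length(clean), 0, noise_sd_frac)))
      data.frame(construct_id = construct_id, mg_mM = mg_mM,
                 temperature_K = temperature_K, fa_uM = fa_uM,
                 M0_nM = concentrations_nM, position = p$position,
                 direction = p$direction, intensity = obs,
                 stringsAsFactors = FALSE)
    }))
  }
  df <- with_seed(seed, rbind(one_condition(true_Kd_noFA_nM, 0),
                              one_condition(true_Kd_FA_nM, 200)))
  structure(df, truth = list(true_Kd_noFA_nM = true_Kd_noFA_nM,
                             true_Kd_FA_nM = true_Kd_FA_nM,
                             noise_sd_frac = noise_sd_frac, seed = seed))
}

#' Simulate an equimolar heterodimer titration
#'
#' @param true_Kd_nM generating dissociation constant, nM.
#' @param concentrations_nM per-partner ladder (default
#'   [heterodimer_ladder()]).
#' @param noise_sd additive Gaussian sd on the bound fraction.
#' @param seed RNG seed.
#' @return data.frame `C_nM`, `fraction_bound` with `attr(, "truth")`.
#' @export
simulate_heterodimer <- function(true_Kd_nM, concentrations_nM = heterodimer_ladder(),
                                 noise_sd = 0.02, seed = 1L) {
  stopifnot(true_Kd_nM > 0, noise_sd >= 0, all(diff(concentrations_nM) > 0))
  f_true <- heterodimer_fraction(concentrations_nM, true_Kd_nM)
  df <- with_seed(seed, data.frame(
    C_nM = concentrations_nM,
    fraction_bound = clip01(f_true + stats::rnorm(length(f_true), 0, noise_sd))))
  structure(df, truth = list(true_Kd_nM = true_Kd_nM, noise_sd = noise_sd,
                             seed = seed))
}

# 23-position signature of the 980 loop-receptor used as the anchor of the
# synthetic variant set; all other variants are derived by the named point
# mutations. These sequences are synthetic stand-ins consistent with the
# described mutational relationships, not transcriptions of measured
# sequences.
signature_980 <- function() {
  stats::setNames(
    c("A", "G", "U", "A", "A", "C", "G", "G", "G", "G", "A", "U",
      "U", "U", "A", "C", "C", "A", "G", "C", "C", "C", "G"),
    as.character(1:23))
}

mutate_signature <- function(residues, ...) {
  subs <- c(...)
  if (length(subs)) residues[names(subs)] <- subs
  residues[sort_position_labels(names(residues))]
}

#' Curated synthetic loop-receptor variant set
#'
#' Builds the named 23-position signatures used throughout the package's
#' examples and tests. The set is a synthetic reconstruction anchored on
#' 980 and propagated through the documented point mutations, so it
#' reproduces the pairwise relationships of the real variant panel:
#' d(980, 3SUX) = 1 (C21U, giving the G9:U21 wobble), d(980, 593) = 2
#' (G10A/C20U), d(980, 148) = 1 (U3C), d(980, 158) = 1 (G7A),
#' d(980, 4LVV) = 8 (including the U6/C14/del17 context switch), 980.8 =
#' C22U, 894 = 593 plus the G6.1 insertion, and the 4LVV.1/.2/.3 and
#' 488.1 pairing variants (488.1 has four G:C long-range pairs with an
#' A:A mismatch at 11:19).
#'
#' @param file optional path; when given the set is also written as FASTA
#'   via [write_signature_fasta()].
#' @return named list of [thf_variant()] objects.
#' @export
make_variant_fixtures <- function(file = NULL) {
  s980 <- signature_980()
  s4lvv <- mutate_signature(s980, `6` = "U", `14` = "C", `17` = "-",
                            `10` = "A", `11` = "U", `12` = "G",
                            `18` = "C", `20` = "U")
  s593 <- mutate_signature(s980, `10` = "A", `20` = "U")
  defs <- list(
    `980` = list(res = s980, source = "natural"),
    `3SUX` = list(res = mutate_signature(s980, `21` = "U"), source = "natural"),
    `4LVV` = list(res = s4lvv, source = "natural"),
    `148` = list(res = mutate_signature(s980, `3` = "C"), source = "natural"),
    `158` = list(res = mutate_signature(s980, `7` = "A"), source = "natural"),
    `593` = list(res = s593, source = "natural"),
    `894` = list(res = mutate_signature(c(s593, `6.1` = "G")),
                 source = "natural"),
    `980.8` = list(res = mutate_signature(s980, `22` = "U"),
                   source = "artificial"),
    `980.11` = list(res = mutate_signature(s980, `8` = "C", `22` = "G"),
                    source = "artificial"),
    `4LVV.1` = list(res = mutate_signature(s4lvv, `10` = "U", `20` = "A"),
                    source = "artificial"),
    `4LVV.2` = list(res = mutate_signature(s4lvv, `11` = "A"),
                    source = "artificial"),
    `4LVV.3` = list(res = mutate_signature(s4lvv, `11` = "A", `10` = "U",
                                           `20` = "A"),
                    source = "artificial"),
    `488.1` = list(res = mutate_signature(s4lvv, `10` = "G", `20` = "C",
                                          `11` = "A"),
                   source = "artificial")
  )
  variants <- lapply(names(defs), function(id)
    thf_variant(id, defs[[id]]$res, source = defs[[id]]$source))
  names(variants) <- names(defs)
  if (!is.null(file)) write_signature_fasta(variants, file)
  variants
}
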