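# Gel-shift quantification and isotherm fitting.

#' Fraction dimerized from band intensities
#'
#' With trace labeled RNA the probability that a labeled molecule sits in a
#' dimer equals the bulk fraction of molecules dimerized, so
#' `fD = dimer / (monomer + dimer)` with no factor-of-two correction.
#' Lanes where both bands are zero are uninformative and yield `NA` with a
#' warning.
#'
#' @param monomer_intensity,dimer_intensity non-negative band intensities
#'   (vectorized).
#' @return fraction(s) dimerized in \[0, 1\].
#' @export
fraction_dimer_from_bands <- function(monomer_intensity, dimer_intensity) {
  if (any(monomer_intensity < 0, na.rm = TRUE) ||
      any(dimer_intensity < 0, na.rm = TRUE))
    stop("band intensities must be non-negative")
  total <- monomer_intensity + dimer_intensity
  out <- dimer_intensity / total
  if (any(total == 0, na.rm = TRUE)) {
    warning(sum(total == 0, na.rm = TRUE),
            " lane(s) with zero total intensity skipped (fD = NA)")
    out[total == 0] <- NA_real_
  }
  out
}

new_fit <- function(Kd_nM, beta = NA_real_, Kd_sd_nM = NA_real_,
                    beta_sd = NA_real_, rss = NA_real_, converged = FALSE,
                    below_detection = FALSE, no_assembly = FALSE,
                    noisy = FALSE, n_replicates = 1L, n_points = NA_integer_,
                    detection_limit_nM = 1, model = "homodimer") {
  structure(list(Kd_nM = Kd_nM, beta = beta, Kd_sd_nM = Kd_sd_nM,
                 beta_sd = beta_sd, rss = rss, converged = converged,
                 below_detection = below_detection, no_assembly = no_assembly,
                 noisy = noisy, n_replicates = n_replicates,
                 n_points = n_points, detection_limit_nM = detection_limit_nM,
                 model = model),
            class = "tecto_fit")
}

#' @export
print.tecto_fit <- function(x, ...) {
  flags <- c("below detection"[x$below_detection], "no assembly"[x$no_assembly],
             "noisy"[x$noisy], "not converged"[!x$converged])
  cat(sprintf("<tecto_fit %s> Kd = %.4g nM", x$model, x$Kd_nM))
  if (!is.na(x$Kd_sd_nM)) cat(sprintf(" (sd %.3g)", x$Kd_sd_nM))
  if (!is.na(x$beta)) cat(sprintf(", beta = %.3f", x$beta))
  if (length(flags)) cat("  [", paste(flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# shared bounded Levenberg-Marquardt driver with log-spaced Kd multi-starts;
# ties on RSS go to the smaller Kd
lm_multistart <- function(resid_fn, M0, free_beta, beta0, n_starts = 5L,
                          max_iter = 500L) {
  kd_starts <- 10^seq(log10(min(M0) / 10), log10(max(M0) * 10),
                      length.out = n_starts)
  lower <- c(lKd = log(1e-2)); upper <- c(lKd = log(1e8))
  if (free_beta) {
    lower <- c(lower, beta = 1e-6); upper <- c(upper, beta = 1)
  }
  best <- NULL
  for (kd0 in kd_starts) {
    par0 <- c(lKd = log(kd0), if (free_beta) c(beta = beta0))
    fit <- minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = 1e-10, ptol = 1e-10))
    rss <- sum(fit$fvec^2)
    kd <- exp(fit$par[["lKd"]])
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && kd < best$Kd)) {
      best <- list(Kd = kd,
                   beta = if (free_beta) fit$par[["beta"]] else NA_real_,
                   rss = rss, converged = fit$info %in% 1:4)
    }
  }
  best
}

#' Fit the homodimerization isotherm to a titration series
#'
#' Unweighted least-squares fit of
#' `fD(M0) = homodimer_fraction(M0, Kd, beta)` over a concentration ladder,
#' estimating `Kd` (on a log scale, bounds 1e-2 to 1e8 nM) and, unless
#' `fix_beta` is given, the active fraction `beta` in (0, 1]. Five
#' log-spaced `Kd` starting points are tried; the lowest residual sum of
#' squares wins, ties going to the smaller `Kd`. Series whose maximum
#' observed `fD` stays below 0.05 are flagged `no_assembly` with `Kd` set
#' to the highest tested concentration (a lower bound); fitted `Kd` below
#' `detection_limit_nM` sets `below_detection` (the fitted value is kept
#' and the limit is the reportable upper bound).
#'
#' @param M0_nM total RNA concentrations, nM; at least 4 points spanning a
#'   10-fold range.
#' @param fD observed fractions dimerized (same length; `NA` rows dropped).
#' @param fix_beta fix the active fraction at this value instead of
#'   estimating it (e.g. `1`).
#' @param detection_limit_nM gel-shift detection limit (default 1 nM).
#' @param seed kept for interface stability; the multi-start grid is
#'   deterministic, so fits do not consume randomness.
#' @return a `tecto_fit` object.
#' @export
fit_homodimer <- function(M0_nM, fD, fix_beta = NULL, detection_limit_nM = 1,
                          seed = NULL) {
  stopifnot(is.numeric(M0_nM), is.numeric(fD), length(M0_nM) == length(fD))
  keep <- is.finite(M0_nM) & is.finite(fD)
  M0 <- M0_nM[keep]; y <- fD[keep]
  if (length(M0) < 4L) stop("need at least 4 titration points")
  if (any(M0 <= 0)) stop("M0_nM must be positive")
  if (max(M0) / min(M0) < 10) stop("concentration ladder must span >= 10-fold")
  if (!is.null(fix_beta) && (fix_beta <= 0 || fix_beta > 1))
    stop("fix_beta must be in (0, 1]")
  if (max(y) < 0.05) {
    return(new_fit(Kd_nM = max(M0), rss = sum(y^2), converged = TRUE,
                   no_assembly = TRUE, n_points = length(M0),
                   detection_limit_nM = detection_limit_nM))
  }
  free_beta <- is.null(fix_beta)
  beta0 <- min(max(max(y), 0.05), 1)
  resid_fn <- function(par) {
    beta <- if (free_beta) par[["beta"]] else fix_beta
    homodimer_fraction(M0, exp(par[["lKd"]]), beta) - y
  }
  best <- lm_multistart(resid_fn, M0, free_beta, beta0)
  new_fit(Kd_nM = best$Kd,
          beta = if (free_beta) best$beta else fix_beta,
          rss = best$rss, converged = best$converged,
          below_detection = best$Kd < detection_limit_nM,
          n_points = length(M0), detection_limit_nM = detection_limit_nM)
}

#' Fit the equimolar heterodimer binding model
#'
#' Least-squares fit of `f(C) = heterodimer_fraction(C, Kd)` for two
#' partners titrated at equal total concentration `C`.
#'
#' @param C_nM total concentration of each partner, nM.
#' @param fraction_bound observed fraction of each partner in the dimer.
#' @param detection_limit_nM detection limit (default 1 nM).
#' @return a `tecto_fit` object with `model = "heterodimer"`.
#' @export
fit_heterodimer <- function(C_nM, fraction_bound, detection_limit_nM = 1) {
  stopifnot(is.numeric(C_nM), is.numeric(fraction_bound),
            length(C_nM) == length(fraction_bound))
  keep <- is.finite(C_nM) & is.finite(fraction_bound)
  C <- C_nM[keep]; y <- fraction_bound[keep]
  if (length(C) < 4L) stop("need at least 4 titration points")
  if (any(C <= 0)) stop("C_nM must be positive")
  if (max(y) < 0.05) {
    return(new_fit(Kd_nM = max(C), rss = sum(y^2), converged = TRUE,
                   no_assembly = TRUE, n_points = length(C),
                   detection_limit_nM = detection_limit_nM,
                   model = "heterodimer"))
  }
  resid_fn <- function(par) heterodimer_fraction(C, exp(par[["lKd"]])) - y
  best <- lm_multistart(resid_fn, C, free_beta = FALSE, beta0 = NA)
  new_fit(Kd_nM = best$Kd, rss = best$rss, converged = best$converged,
          below_detection = best$Kd < detection_limit_nM,
          n_points = length(C), detection_limit_nM = detection_limit_nM,
          model = "heterodimer")
}

#' Average fitted parameters across replicates
#'
#' Replicates are fitted individually and the estimates averaged: `Kd` and
#' `beta` become arithmetic means, the sd fields sample standard deviations
#' (n - 1), and the quality flags are OR-combined. A warning (not an error)
#' is issued below 3 replicates.
#'
#' @param fits list of `tecto_fit` objects from the same construct and
#'   condition.
#' @param warn warn when fewer than 3 replicates are supplied.
#' @return a `tecto_fit` object with `n_replicates` set.
#' @export
aggregate_replicates <- function(fits, warn = TRUE) {
  if (length(fits) == 0L) stop("no fits to aggregate")
  stopifnot(all(vapply(fits, inherits, TRUE, "tecto_fit")))
  if (warn && length(fits) < 3L)
    warning("only ", length(fits), " replicate(s); report averages of >= 3")
  kds <- vapply(fits, function(f) f$Kd_nM, 0)
  betas <- vapply(fits, function(f) f$beta, 0)
  new_fit(
    Kd_nM = mean(kds),
    beta = if (all(is.na(betas))) NA_real_ else mean(betas, na.rm = TRUE),
    Kd_sd_nM = if (length(fits) > 1L) stats::sd(kds) else NA_real_,
    beta_sd = if (length(fits) > 1L && !all(is.na(betas)))
      stats::sd(betas, na.rm = TRUE) else NA_real_,
    rss = sum(vapply(fits, function(f) f$rss, 0)),
    converged = all(vapply(fits, function(f) f$converged, TRUE)),
    below_detection = any(vapply(fits, function(f) f$below_detection, TRUE)),
    no_assembly = any(vapply(fits, function(f) f$no_assembly, TRUE)),
    noisy = any(vapply(fits, function(f) f$noisy, TRUE)),
    n_replicates = length(fits),
    n_points = sum(vapply(fits, function(f) f$n_points, 0L)),
    detection_limit_nM = fits[[1L]]$detection_limit_nM,
    model = fits[[1L]]$model
  )
}

#' Fit a gel-shift titration table
#'
#' Groups a long-format titration table by construct and condition, fits
#' each replicate with [fit_homodimer()], and aggregates the replicate
#' estimates with [aggregate_replicates()]. Rows lacking a pre-quantified
#' `fD` column get it from [fraction_dimer_from_bands()].
#'
#' @param df data.frame with columns `construct_id`, `replicate_id`,
#'   `mg_mM`, `temperature_K`, `fa_uM`, `M0_nM` and either `fD` or
#'   `monomer_intensity` + `dimer_intensity`.
#' @param fix_beta,detection_limit_nM passed to [fit_homodimer()].
#' @return data.frame, one row per construct x condition, with Kd, beta,
#'   their sds and the quality flags.
#' @export
fit_gelshift_table <- function(df, fix_beta = NULL, detection_limit_nM = 1) {
  need <- c("construct_id", "replicate_id", "mg_mM", "temperature_K",
            "fa_uM", "M0_nM")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"fD" %in% names(df)) {
    if (!all(c("monomer_intensity", "dimer_intensity") %in% names(df)))
      stop("need either fD or monomer_intensity + dimer_intensity columns")
    df$fD <- fraction_dimer_from_bands(df$monomer_intensity,
                                       df$dimer_intensity)
  }
  key <- interaction(df$construct_id, df$mg_mM, df$temperature_K, df$fa_uM,
                     drop = TRUE)
  out <- lapply(split(df, key), function(grp) {
    fits <- lapply(split(grp, grp$replicate_id, drop = TRUE), function(rep) {
      rep <- rep[order(rep$M0_nM), ]
      fit_homodimer(rep$M0_nM, rep$fD, fix_beta = fix_beta,
                    detection_limit_nM = detection_limit_nM)
    })
    agg <- aggregate_replicates(fits, warn = FALSE)
    data.frame(construct_id = grp$construct_id[1L], assay = "gelshift",
               mg_mM = grp$mg_mM[1L], temperature_K = grp$temperature_K[1L],
               fa_uM = grp$fa_uM[1L], Kd_nM = agg$Kd_nM,
               Kd_sd_nM = agg$Kd_sd_nM, beta = agg$beta,
               beta_sd = agg$beta_sd, n_replicates = agg$n_replicates,
               converged = agg$converged, below_detection = agg$below_detection,
               no_assembly = agg$no_assembly, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$construct_id, res$mg_mM, res$fa_uM), , drop = FALSE]
}
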