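# Lead(II) cleavage footprinting: band integration, two-state
# normalization, protection/enhancement calls, and apparent-Kd estimation.

#' Integrate a band from a 1-D lane profile
#'
#' Sums the trace over `window` and subtracts a local baseline estimated as
#' the median of the flanking segments of `baseline_half_width` bins on
#' each side, times the window length; negative results are floored at 0.
#'
#' @param trace ordered numeric intensity vector (one densitometry lane).
#' @param window integer indices of the band (contiguous).
#' @param baseline_half_width bins of flank used on each side (>= 1).
#' @return integrated band intensity (>= 0).
#' @export
integrate_band <- function(trace, window, baseline_half_width = 3L) {
  stopifnot(is.numeric(trace), length(window) >= 1L, baseline_half_width >= 1L)
  window <- sort(as.integer(window))
  if (any(diff(window) != 1L)) stop("window must be contiguous indices")
  left <- (window[1L] - baseline_half_width):(window[1L] - 1L)
  right <- (window[length(window)] + 1L):(window[length(window)] + baseline_half_width)
  if (min(left) < 1L || max(right) > length(trace))
    stop("window touches the trace end: no flank available for the baseline")
  baseline <- stats::median(trace[c(left, right)])
  max(0, sum(trace[window]) - baseline * length(window))
}

#' Two-state normalization of cleavage intensities
#'
#' Maps a position's band intensity linearly between its extremes over the
#' concentration ladder, which are taken to correspond to the full-monomer
#' and full-dimer states. For `"decreasing"` positions (cleavage protected
#' upon dimerization) the maximum is full monomer:
#' `fM = (I - Imin)/(Imax - Imin)`; for `"increasing"` positions (cleavage
#' enhanced in the dimer) the minimum is full monomer:
#' `fM = (Imax - I)/(Imax - Imin)`. Results are clipped to \[0, 1\].
#'
#' @param M0_nM concentration ladder, nM.
#' @param intensity band intensities at one position across the ladder.
#' @param direction `"decreasing"` or `"increasing"`.
#' @return data.frame `M0_nM`, `fM` with the direction recorded in
#'   `attr(, "direction")`.
#' @export
normalize_two_state <- function(M0_nM, intensity,
                                direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  stopifnot(length(M0_nM) == length(intensity), length(intensity) >= 2L)
  imin <- min(intensity); imax <- max(intensity)
  if (imax == imin)
    stop("uninformative position: constant intensity across the ladder")
  fM <- if (direction == "decreasing") {
    (intensity - imin) / (imax - imin)
  } else {
    (imax - intensity) / (imax - imin)
  }
  structure(data.frame(M0_nM = M0_nM, fM = clip01(fM)),
            direction = direction)
}

#' Fit the two-state monomer-fraction curve
#'
#' Least-squares fit of the two-state assembly model
#' `fM(M0) = 1 - homodimer_fraction(M0, Kd, beta = 1)` to a
#' monomer-fraction series. `beta` is fixed at 1 because the two-state
#' convention treats the intensity extremes as the full monomer and full
#' dimer states.
#'
#' When the series comes from [normalize_two_state()] (`anchored = TRUE`,
#' the default for its output), the full-monomer and full-dimer anchor
#' levels are treated as nuisance parameters: for each candidate `Kd` the
#' best affine calibration `y = a + b * fM(M0; Kd)` is profiled out by
#' linear least squares. This keeps the estimate unbiased when the ladder
#' does not fully saturate the dimer state and when the two extreme lanes
#' used as anchors carry noise; on noiseless anchored data the generating
#' `Kd` is recovered exactly. Raw (unanchored) `fM` series are fitted
#' against the model curve directly.
#'
#' Series that stay within 0.05 of full monomer everywhere are flagged
#' `no_assembly`; fits whose mean squared residual exceeds `noisy_mse`
#' are flagged `noisy` (the fit is still returned).
#'
#' @param M0_nM concentration ladder, nM (>= 4 points), or the data.frame
#'   from [normalize_two_state()].
#' @param fM relative fraction of monomer in \[0, 1\] (omit when a
#'   data.frame is given).
#' @param detection_limit_nM detection limit (default 1 nM).
#' @param noisy_mse mean-squared-residual threshold for the `noisy` flag.
#' @param anchored whether the series was min/max anchored; defaults to
#'   `TRUE` for [normalize_two_state()] output and `FALSE` for raw
#'   vectors.
#' @return a `tecto_fit` object with `model = "two_state"` and `beta = 1`.
#' @export
fit_two_state <- function(M0_nM, fM = NULL, detection_limit_nM = 1,
                          noisy_mse = 0.01, anchored = NULL) {
  if (is.data.frame(M0_nM)) {
    if (is.null(anchored)) anchored <- !is.null(attr(M0_nM, "direction"))
    fM <- M0_nM$fM; M0_nM <- M0_nM$M0_nM
  }
  anchored <- anchored %||% FALSE
  stopifnot(is.numeric(M0_nM), is.numeric(fM), length(M0_nM) == length(fM))
  keep <- is.finite(M0_nM) & is.finite(fM)
  M0 <- M0_nM[keep]; y <- fM[keep]
  if (length(M0) < 4L) stop("need at least 4 points")
  if (any(M0 <= 0)) stop("M0_nM must be positive")
  if (!anchored && 1 - min(y) < 0.05) {
    return(new_fit(Kd_nM = max(M0), beta = 1, rss = sum((1 - y)^2),
                   converged = TRUE, no_assembly = TRUE,
                   n_points = length(M0),
                   detection_limit_nM = detection_limit_nM,
                   model = "two_state"))
  }
  model_fM <- function(Kd) 1 - homodimer_fraction(M0, Kd, 1)
  resid_fn <- if (anchored) {
    function(par) {
      f <- model_fM(exp(par[["lKd"]]))
      stats::lm.fit(cbind(1, f), y)$residuals
    }
  } else {
    function(par) model_fM(exp(par[["lKd"]])) - y
  }
  best <- lm_multistart(resid_fn, M0, free_beta = FALSE, beta0 = NA)
  new_fit(Kd_nM = best$Kd, beta = 1, rss = best$rss,
          converged = best$converged,
          below_detection = best$Kd < detection_limit_nM,
          noisy = best$rss / length(M0) > noisy_mse,
          n_points = length(M0), detection_limit_nM = detection_limit_nM,
          model = "two_state")
}

#' Call per-position protections and enhancements
#'
#' Compares cleavage intensities between the monomer and dimer states: with
#' a pseudo-count of 1% of the pooled median intensity, the ratio
#' `r = I_monomer / I_dimer` classifies a position as `PROTECTED_IN_DIMER`
#' (`r >= fold_threshold`), `ENHANCED_IN_DIMER` (`r <= 1/fold_threshold`)
#' or `UNCHANGED`. When `fa_dimer_state` is supplied, a second comparison
#' of the dimer states with and without ligand yields
#' `FA_SPECIFIC_PROTECTED` / `FA_SPECIFIC_ENHANCED` calls appended as extra
#' rows with `comparison = "fa"`. Swapping the two states exchanges
#' PROTECTED and ENHANCED calls.
#'
#' @param monomer_state,dimer_state named numeric vectors of intensities;
#'   identical position sets required.
#' @param fold_threshold ratio threshold (> 1, default 1.5).
#' @param fa_dimer_state optional named vector for the +ligand dimer state.
#' @return data.frame `position`, `comparison`, `direction`, `magnitude`
#'   (fold change, >= 1).
#' @export
call_protections <- function(monomer_state, dimer_state, fold_threshold = 1.5,
                             fa_dimer_state = NULL) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  compare <- function(a, b, labels, comparison) {
    if (is.null(names(a)) || is.null(names(b)))
      stop("states must be named by position")
    if (!setequal(names(a), names(b)))
      stop("position sets differ between states")
    b <- b[names(a)]
    eps <- 0.01 * stats::median(c(a, b))
    r <- (a + eps) / (b + eps)
    direction <- ifelse(r >= fold_threshold, labels[1L],
                        ifelse(r <= 1 / fold_threshold, labels[2L],
                               "UNCHANGED"))
    data.frame(position = names(a), comparison = comparison,
               direction = unname(direction),
               magnitude = unname(pmax(r, 1 / r)),
               stringsAsFactors = FALSE)
  }
  out <- compare(monomer_state, dimer_state,
                 c("PROTECTED_IN_DIMER", "ENHANCED_IN_DIMER"), "monomer_dimer")
  if (!is.null(fa_dimer_state)) {
    out <- rbind(out, compare(dimer_state, fa_dimer_state,
                              c("FA_SPECIFIC_PROTECTED", "FA_SPECIFIC_ENHANCED"),
                              "fa"))
  }
  rownames(out) <- NULL
  out
}

#' Fit a cleavage-intensity table
#'
#' Groups a long-format cleavage table by construct, condition and
#' position, applies [normalize_two_state()] and [fit_two_state()] to each
#' series, and averages the per-position apparent Kd values within each
#' construct x condition with [aggregate_replicates()] (positions act as
#' quantification replicates of the same assembly equilibrium).
#'
#' @param df data.frame with columns `construct_id`, `mg_mM`,
#'   `temperature_K`, `fa_uM`, `M0_nM`, `position`, `intensity`,
#'   `direction`.
#' @param detection_limit_nM passed to [fit_two_state()].
#' @return data.frame, one row per construct x condition.
#' @export
fit_lead_table <- function(df, detection_limit_nM = 1) {
  need <- c("construct_id", "mg_mM", "temperature_K", "fa_uM", "M0_nM",
            "position", "intensity", "direction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  key <- interaction(df$construct_id, df$mg_mM, df$temperature_K, df$fa_uM,
                     drop = TRUE)
  out <- lapply(split(df, key), function(grp) {
    fits <- lapply(split(grp, grp$position, drop = TRUE), function(pos) {
      pos <- pos[order(pos$M0_nM), ]
      fit_two_state(normalize_two_state(pos$M0_nM, pos$intensity,
                                        pos$direction[1L]),
                    detection_limit_nM = detection_limit_nM)
    })
    agg <- aggregate_replicates(fits, warn = FALSE)
    data.frame(construct_id = grp$construct_id[1L], assay = "lead",
               mg_mM = grp$mg_mM[1L], temperature_K = grp$temperature_K[1L],
               fa_uM = grp$fa_uM[1L], Kd_nM = agg$Kd_nM,
               Kd_sd_nM = agg$Kd_sd_nM, beta = 1, beta_sd = NA_real_,
               n_replicates = agg$n_replicates, converged = agg$converged,
               below_detection = agg$below_detection,
               no_assembly = agg$no_assembly, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$construct_id, res$mg_mM, res$fa_uM), , drop = FALSE]
}
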