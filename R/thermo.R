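# Equilibrium models and the free-energy calculus.
#
# Concentrations are carried in nM throughout and converted to mol/L only
# inside delta_g(). Energies are kcal/mol with R = 1.987 cal K^-1 mol^-1.

#' Gas constant in kcal K^-1 mol^-1
#' @keywords internal
RGAS_KCAL <- 1.987e-3

#' Fraction of tectoRNA homodimerized at equilibrium
#'
#' Closed-form solution of the homodimerization equilibrium
#' 2 M \eqn{\rightleftharpoons} D with an active fraction \eqn{\beta}:
#' \deqn{f_D = \frac{(4\beta M_0 + K_d) - \sqrt{8 M_0 \beta K_d + K_d^2}}{4 M_0}}
#' evaluated through the algebraically equivalent rationalized form
#' \deqn{f_D = \beta\,\frac{\sqrt{1+x}-1}{\sqrt{1+x}+1}, \quad x = 8\beta M_0/K_d,}
#' which avoids catastrophic cancellation when \eqn{M_0 \ll K_d}.
#'
#' @param M0_nM total RNA concentration(s), nM (> 0). Vectorized.
#' @param Kd_nM dissociation constant, nM (> 0).
#' @param beta maximum fraction of molecules competent to dimerize, in (0, 1].
#' @return fraction dimerized, in \[0, beta).
#' @examples
#' homodimer_fraction(100, 100)          # exactly 0.5 at M0 = Kd, beta = 1
#' homodimer_fraction(1000, 100, 0.8)    # ~0.6234
#' @export
homodimer_fraction <- function(M0_nM, Kd_nM, beta = 1) {
  if (!is.numeric(M0_nM) || any(!is.finite(M0_nM)) || any(M0_nM <= 0))
    stop("M0_nM must be positive and finite")
  if (!is.numeric(Kd_nM) || length(Kd_nM) != 1L || !is.finite(Kd_nM) || Kd_nM <= 0)
    stop("Kd_nM must be a single positive number")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 1)
    stop("beta must be in (0, 1]")
  s <- sqrt(1 + 8 * beta * M0_nM / Kd_nM)
  beta * (s - 1) / (s + 1)
}

#' Fraction bound for an equimolar heterodimer
#'
#' For A + B \eqn{\rightleftharpoons} AB with both partners at total
#' concentration `C_nM`, the free-monomer quadratic gives the bound fraction
#' \deqn{f = \frac{\sqrt{1 + 4C/K_d} - 1}{\sqrt{1 + 4C/K_d} + 1}.}
#' At `C_nM == Kd_nM` this equals \eqn{(3-\sqrt 5)/2 \approx 0.382}.
#'
#' @param C_nM total concentration of each partner, nM (> 0). Vectorized.
#' @param Kd_nM dissociation constant, nM (> 0).
#' @return fraction of each partner in the dimer, in \[0, 1).
#' @export
heterodimer_fraction <- function(C_nM, Kd_nM) {
  if (!is.numeric(C_nM) || any(!is.finite(C_nM)) || any(C_nM <= 0))
    stop("C_nM must be positive and finite")
  if (!is.numeric(Kd_nM) || length(Kd_nM) != 1L || !is.finite(Kd_nM) || Kd_nM <= 0)
    stop("Kd_nM must be a single positive number")
  s <- sqrt(1 + 4 * C_nM / Kd_nM)
  (s - 1) / (s + 1)
}

#' Association free energy from a dissociation constant
#'
#' \eqn{\Delta G = RT \ln K_d} with \eqn{K_d} converted from nM to mol/L and
#' R = 1.987e-3 kcal K^-1 mol^-1. Negative for any sub-molar \eqn{K_d};
#' lower (more negative) means stronger assembly. This sign convention is the
#' one under which the package's \eqn{\Delta\Delta G} values
#' (`ddg()`, `ddg_fa()`) reproduce standard reported ligand-stabilization
#' energies (negative when the ligand stabilizes the dimer).
#'
#' @param Kd_nM dissociation constant(s), nM (> 0). Vectorized.
#' @param T_K absolute temperature, K. Gel-shift assays in this package
#'   default to 280 K (7 deg C); lead probing uses 293 K (20 deg C).
#' @return free energy in kcal/mol.
#' @export
delta_g <- function(Kd_nM, T_K = 280) {
  if (!is.numeric(Kd_nM) || any(!is.finite(Kd_nM)) || any(Kd_nM <= 0))
    stop("Kd_nM must be positive and finite")
  if (!is.numeric(T_K) || any(T_K <= 0)) stop("T_K must be positive")
  RGAS_KCAL * T_K * log(Kd_nM * 1e-9)
}

#' Free-energy difference between two constructs
#'
#' \eqn{\Delta\Delta G = \Delta G_n - \Delta G_o = RT \ln(K_{d,n}/K_{d,o})}.
#' Antisymmetric in its first two arguments and zero at equality.
#'
#' @param Kd_n_nM dissociation constant of the construct of interest, nM.
#' @param Kd_o_nM dissociation constant of the reference construct, nM.
#' @param T_K absolute temperature, K.
#' @return kcal/mol; negative when the construct assembles more strongly
#'   than the reference.
#' @export
ddg <- function(Kd_n_nM, Kd_o_nM, T_K = 280) {
  if (any(Kd_n_nM <= 0) || any(Kd_o_nM <= 0)) stop("Kd values must be positive")
  RGAS_KCAL * T_K * log(Kd_n_nM / Kd_o_nM)
}

#' Ligand-induced stability shift
#'
#' \eqn{\Delta\Delta G_{FA} = RT\ln(K_d^{+FA}/K_d^{-FA})}: negative when
#' folinic acid stabilizes self-assembly.
#'
#' @param Kd_plusFA_nM dissociation constant with ligand, nM.
#' @param Kd_minusFA_nM dissociation constant without ligand, nM.
#' @param T_K absolute temperature, K.
#' @return kcal/mol.
#' @export
ddg_fa <- function(Kd_plusFA_nM, Kd_minusFA_nM, T_K = 280) {
  ddg(Kd_plusFA_nM, Kd_minusFA_nM, T_K)
}

#' Fold reduction of Kd by ligand
#'
#' @param Kd_minusFA_nM dissociation constant without ligand, nM.
#' @param Kd_plusFA_nM dissociation constant with ligand, nM.
#' @return `Kd_minusFA_nM / Kd_plusFA_nM`; > 1 when the ligand strengthens
#'   assembly.
#' @export
fold_change <- function(Kd_minusFA_nM, Kd_plusFA_nM) {
  if (any(Kd_minusFA_nM <= 0) || any(Kd_plusFA_nM <= 0))
    stop("Kd values must be positive")
  Kd_minusFA_nM / Kd_plusFA_nM
}

#' Append free-energy columns to a Kd table
#'
#' Computes `dG_kcal_mol` per row and, within each condition group
#' (`mg_mM`, `temperature_K`, `fa_uM`, and `assay` if present),
#' `ddG_kcal_mol` relative to `reference_construct`.
#'
#' @param kd_table data.frame with at least `construct_id`, `Kd_nM` and
#'   `temperature_K`; optional condition columns are used for grouping.
#' @param reference_construct id of the reference construct; rows in groups
#'   where the reference is absent get `NA` ddG.
#' @return the input with `dG_kcal_mol` and `ddG_kcal_mol` columns appended.
#' @export
thermo_table <- function(kd_table, reference_construct = "4LVV") {
  stopifnot(is.data.frame(kd_table),
            all(c("construct_id", "Kd_nM", "temperature_K") %in% names(kd_table)))
  kd_table$dG_kcal_mol <- ifelse(
    is.finite(kd_table$Kd_nM) & kd_table$Kd_nM > 0,
    delta_g(pmax(kd_table$Kd_nM, .Machine$double.xmin), kd_table$temperature_K),
    NA_real_)
  group_cols <- intersect(c("assay", "mg_mM", "temperature_K", "fa_uM"),
                          names(kd_table))
  key <- if (length(group_cols))
    do.call(paste, c(kd_table[group_cols], sep = "\r")) else rep("", nrow(kd_table))
  kd_table$ddG_kcal_mol <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    ref <- idx[kd_table$construct_id[idx] == reference_construct]
    if (length(ref) == 0L) next
    dg_ref <- kd_table$dG_kcal_mol[ref[1L]]
    kd_table$ddG_kcal_mol[idx] <- kd_table$dG_kcal_mol[idx] - dg_ref
  }
  kd_table
}
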