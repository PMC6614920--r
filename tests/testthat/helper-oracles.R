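# Independent mass-action solvers used as oracles for the closed forms.

# Homodimer 2M <-> D with active fraction beta: solve
# (beta*M0 - 2D)^2 = Kd * D for the dimer concentration D by root
# bracketing followed by Newton polishing, then fD = 2D / M0. Shares no
# code with the package's rationalized closed form.
oracle_homodimer_fD <- function(M0, Kd, beta = 1) {
  g <- function(D) (beta * M0 - 2 * D)^2 - Kd * D
  gp <- function(D) -4 * (beta * M0 - 2 * D) - Kd
  D <- stats::uniroot(g, c(0, beta * M0 / 2),
                      tol = max(1e-13 * beta * M0, 1e-300))$root
  for (i in 1:4) D <- D - g(D) / gp(D)
  2 * D / M0
}

# Equimolar heterodimer A + B <-> AB: free monomer from the quadratic,
# verified against the mass balance m + m^2/Kd = C.
oracle_heterodimer_fraction <- function(C, Kd) {
  m <- (-Kd + sqrt(Kd^2 + 4 * Kd * C)) / 2
  stopifnot(abs(m + m^2 / Kd - C) < 1e-6 * C)
  1 - m / C
}

# tiny variant builder for property tests: a sequence string over a fixed
# label set
test_variant <- function(id, seq_string, labels = NULL) {
  chars <- strsplit(seq_string, "")[[1L]]
  labels <- labels %||% as.character(seq_along(chars))
  tectofit::thf_variant(id, stats::setNames(chars, labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
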