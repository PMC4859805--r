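#' Polarization of a direct fluorescence-polarization titration
#'
#' Trace-labeled 1:1 site model: a fixed, vanishingly small amount of labeled
#' peptide is titrated with hub subunit, so the free hub concentration equals
#' the total hub concentration and the bound fraction follows a simple
#' hyperbola.
#'
#' @param p_tot Total hub-subunit concentration (uM). Vectorised.
#' @param kd Dissociation constant (uM), > 0.
#' @param a_free Polarization of the free labeled peptide (dimensionless).
#' @param a_bound Polarization at saturation (dimensionless).
#' @return Polarization value(s), same length as `p_tot`.
#' @examples
#' direct_polarization(300, kd = 100, a_free = 0.05, a_bound = 0.20)  # 0.1625
#' @export
direct_polarization <- function(p_tot, kd, a_free, a_bound) {
  stopifnot(is.numeric(p_tot), is.numeric(kd), length(kd) == 1L, kd > 0,
            is.finite(a_free), is.finite(a_bound))
  if (any(p_tot < 0)) stop("'p_tot' must be non-negative")
  a_free + (a_bound - a_free) * p_tot / (p_tot + kd)
}

#' Protein-ligand complex concentration for a single 1:1 pair
#'
#' Exact mass-action equilibrium of one protein and one ligand, the positive
#' root of the quadratic in complex concentration:
#' \deqn{PL = \frac{(P_{tot} + L_{tot} + K_D) -
#'   \sqrt{(P_{tot} + L_{tot} + K_D)^2 - 4 P_{tot} L_{tot}}}{2}}
#'
#' @param p_tot Total protein concentration (uM).
#' @param l_tot Total ligand concentration (uM). Vectorised.
#' @param kd Dissociation constant (uM), >= 0.
#' @return Complex concentration (uM), never exceeding `min(p_tot, l_tot)`.
#' @export
competitor_complex <- function(p_tot, l_tot, kd) {
  stopifnot(length(p_tot) == 1L, length(kd) == 1L)
  if (p_tot < 0 || kd < 0 || any(l_tot < 0))
    stop("concentrations and kd must be non-negative")
  s <- p_tot + l_tot + kd
  disc <- s^2 - 4 * p_tot * l_tot
  # disc >= (p_tot - l_tot)^2 + kd^2 >= 0 analytically; clamp rounding error.
  # Rationalised form of (s - sqrt(disc)) / 2: immune to the catastrophic
  # cancellation that the textbook form suffers when 4 p l << s^2.
  2 * p_tot * l_tot / (s + sqrt(pmax(disc, 0)))
}

#' Polarization of a competition fluorescence-polarization assay
#'
#' Competition model for a trace-labeled peptide pre-bound to the hub and
#' displaced by unlabeled peptide of the same sequence. Assumes the labeled
#' and unlabeled peptides share one dissociation constant, and that the
#' labeled concentration (nM) is negligible next to the hub (uM):
#' \deqn{A = A_f + (A_0 - A_f)\,\frac{K_D + P_{tot}}{P_{tot}}\,
#'   \frac{[PL]}{L_{tot}}}
#' where \eqn{[PL]} is the hub/unlabeled-peptide complex from
#' [competitor_complex()]. The \eqn{L_{tot} \to 0} limit is evaluated
#' analytically, giving \eqn{A(0) = A_0}; as \eqn{L_{tot} \to \infty},
#' \eqn{A \to A_f}.
#'
#' @param l_tot Total unlabeled-peptide concentration (uM). Vectorised.
#' @param kd Shared dissociation constant (uM), > 0.
#' @param p_tot Total hub-subunit concentration (uM), > 0.
#' @param a0 Polarization at zero competitor.
#' @param af Polarization of the free labeled peptide.
#' @return Polarization value(s), monotone nonincreasing in `l_tot`.
#' @export
competition_polarization <- function(l_tot, kd, p_tot, a0, af) {
  stopifnot(length(kd) == 1L, length(p_tot) == 1L, kd > 0)
  if (p_tot <= 0) stop("'p_tot' must be positive: competition model undefined")
  if (any(l_tot < 0)) stop("'l_tot' must be non-negative")
  frac <- numeric(length(l_tot))
  pos <- l_tot > 0
  frac[pos] <- competitor_complex(p_tot, l_tot[pos], kd) / l_tot[pos]
  frac[!pos] <- p_tot / (p_tot + kd)  # analytic l_tot -> 0 limit
  af + (a0 - af) * ((kd + p_tot) / p_tot) * frac
}

#' Model-implied IC50 of a competition titration
#'
#' Total competitor concentration at which the competition polarization is
#' midway between its zero-competitor value and the free-peptide baseline.
#' Found by bracketed root-finding on [competition_polarization()]; the
#' midpoint condition does not involve the polarization end points, so the
#' result depends only on `kd` and `p_tot`.
#'
#' @param kd Shared dissociation constant (uM), > 0.
#' @param p_tot Total hub-subunit concentration (uM), > 0.
#' @return IC50 (uM).
#' @examples
#' ic50_from_model(kd = 90, p_tot = 10)  # ~105 uM
#' @export
ic50_from_model <- function(kd, p_tot) {
  stopifnot(length(kd) == 1L, length(p_tot) == 1L)
  if (kd <= 0 || p_tot <= 0) stop("'kd' and 'p_tot' must be positive")
  f <- function(l) competition_polarization(l, kd, p_tot, a0 = 1, af = 0) - 0.5
  hi <- 10 * (kd + p_tot)
  for (i in 1:40) {
    if (f(1e-12) * f(hi) < 0) break
    hi <- hi * 4
    if (i == 40) stop("no sign change found for the IC50 bracket up to ", hi)
  }
  stats::uniroot(f, c(1e-12, hi), tol = 1e-10 * (kd + p_tot))$root
}

#' Effective concentration of a tethered ligand
#'
#' One molecule confined to a sphere of the tether's reach: the concentration
#' is \eqn{1 / (N_A \cdot \frac{4}{3}\pi r^3)} with the radius converted from
#' Angstrom to litres. A 50 Angstrom reach (a flexible linker holding the
#' CaM-binding element near the hub) gives ~3.2 mM.
#'
#' @param radius_A Tether reach (Angstrom), > 0. Vectorised.
#' @return Effective concentration (mM).
#' @examples
#' effective_concentration(50)   # 3.17 mM
#' effective_concentration(100)  # 0.396 mM
#' @export
effective_concentration <- function(radius_A) {
  if (any(radius_A <= 0)) stop("'radius_A' must be positive")
  avogadro <- 6.02214076e23
  r_dm <- radius_A * 1e-9           # 1 A = 1e-9 dm
  vol_L <- (4 / 3) * pi * r_dm^3    # dm^3 = L
  1000 / (avogadro * vol_L)         # mol/L -> mmol/L
}
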