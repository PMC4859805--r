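#' Composition distribution of oligomers assembled from exchange units
#'
#' When two subunit pools (long and short) mix and oligomers of `n` subunits
#' are assembled from units of `u` subunits drawn independently with long
#' fraction `f`, the number of long subunits per oligomer is `u * B` with
#' `B ~ Binomial(n/u, f)`. Under dimer exchange (`u = 2`) every oligomer
#' carries an even number of long subunits; under monomer exchange (`u = 1`)
#' odd counts appear with substantial probability.
#'
#' @param n Subunits per oligomer; must be divisible by `u`.
#' @param u Exchange-unit size (1 = monomer, 2 = dimer).
#' @param f Fraction of long-type units in the pool, in \[0, 1\].
#' @return Named probability vector over the number of long subunits
#'   `0..n`; sums to 1.
#' @examples
#' composition_distribution(4, u = 2, f = 0.5)  # 0.25, 0, 0.5, 0, 0.25
#' @export
composition_distribution <- function(n, u, f) {
  stopifnot(length(n) == 1L, length(u) == 1L, length(f) == 1L,
            n >= 1, u >= 1, f >= 0, f <= 1)
  if (n %% u != 0)
    stop("exchange-unit size u = ", u, " does not divide n = ", n)
  m <- n %/% u
  p <- numeric(n + 1)
  p[u * (0:m) + 1] <- stats::dbinom(0:m, m, f)
  names(p) <- 0:n
  p
}

#' Fraction of oligomers with an even number of long subunits
#'
#' The parity statistic that distinguishes dimer-unit from monomer-unit
#' exchange: ideal dimer exchange from even-composition pools gives 1,
#' monomer exchange at `f = 0.5` gives about 0.5.
#'
#' @param counts Observed counts (or intensities) over the number of long
#'   subunits `0..n`; a vector whose i-th element corresponds to `i - 1`
#'   long subunits (names, if present, are used as the long-subunit count).
#' @return Fraction of the total in even-count bins, in \[0, 1\].
#' @export
parity_fraction <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts) == 0) stop("all counts are zero: parity undefined")
  k <- if (!is.null(names(counts))) as.integer(names(counts))
       else seq_along(counts) - 1L
  sum(counts[k %% 2L == 0L]) / sum(counts)
}

#' Infer the exchange unit from an observed composition distribution
#'
#' Multinomial log-likelihood-ratio test of dimer-unit versus monomer-unit
#' exchange. Bin probabilities come from [composition_distribution()] with
#' an `epsilon` floor on zero-probability bins, so a single odd-count
#' observation penalises (but does not send to minus infinity) the dimer
#' model.
#'
#' @inheritParams parity_fraction
#' @param f Mixing fraction of long units (default 0.5, equimolar mixing).
#' @param epsilon Probability floor for empty bins.
#' @return List with `loglik_dimer`, `loglik_monomer`,
#'   `log_ratio` (dimer minus monomer; positive favours dimers) and
#'   `unit` (2 or 1).
#' @export
infer_exchange_unit <- function(counts, f = 0.5, epsilon = 1e-9) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts) == 0) stop("all counts are zero: nothing to infer")
  n <- length(counts) - 1L
  if (n < 2L || n %% 2L != 0L)
    stop("counts must cover 0..n long subunits with even n >= 2")
  ll <- function(u) {
    p <- composition_distribution(n, u, f)
    sum(counts * log(pmax(p, epsilon)))
  }
  l2 <- ll(2); l1 <- ll(1)
  list(loglik_dimer = l2, loglik_monomer = l1, log_ratio = l2 - l1,
       unit = if (l2 - l1 > 0) 2L else 1L)
}

#' Dodecamer/tetradecamer interconversion by dimer gain or loss
#'
#' Assemblies change stoichiometry in steps of one dimer unit. In
#' `"closed_ring"` mode (human hub) only the 12- and 14-subunit states are
#' allowed and transitions leaving \{12, 14\} are rejected; in `"open"` mode
#' any even stoichiometry >= 2 is permitted.
#'
#' @param n Current subunit count (even).
#' @param action `"gain_dimer"` or `"lose_dimer"`.
#' @param mode `"closed_ring"` or `"open"`.
#' @return New subunit count (`n + 2` or `n - 2`).
#' @export
interconversion_step <- function(n, action = c("gain_dimer", "lose_dimer"),
                                 mode = c("closed_ring", "open")) {
  action <- match.arg(action)
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 2L)
  if (n %% 2L != 0L) stop("stoichiometry must be even (whole dimer units)")
  n_new <- if (action == "gain_dimer") n + 2L else n - 2L
  if (mode == "closed_ring" && (!n %in% c(12L, 14L) || !n_new %in% c(12L, 14L)))
    stop("closed-ring mode admits only the 12 <-> 14 transition (requested ",
         n, " -> ", n_new, ")")
  if (mode == "open" && n_new < 2L)
    stop("cannot lose a dimer from a single-dimer assembly")
  n_new
}

#' Create an oligomer population for exchange simulation
#'
#' @param long_units Integer vector: number of long-type exchange units in
#'   each oligomer (each oligomer holds `n / u` units).
#' @param n Subunits per oligomer.
#' @param u Exchange-unit size (1 or 2).
#' @return Object of class `"oligomer_population"`: list with `long_units`,
#'   `n`, `u`, `units_per_oligomer`.
#' @export
oligomer_population <- function(long_units, n, u) {
  stopifnot(n %% u == 0, u %in% c(1L, 2L))
  m <- n %/% u
  long_units <- as.integer(long_units)
  if (any(long_units < 0L) || any(long_units > m))
    stop("long-unit counts must lie in 0..", m)
  structure(list(long_units = long_units, n = as.integer(n),
                 u = as.integer(u), units_per_oligomer = as.integer(m)),
            class = "oligomer_population")
}

#' @export
print.oligomer_population <- function(x, ...) {
  cat("Oligomer population:", length(x$long_units), "oligomers of", x$n,
      "subunits (", x$units_per_oligomer, "units of size", x$u, ")\n")
  cat("Long subunits:", sum(x$long_units) * x$u, "of",
      length(x$long_units) * x$n, "\n")
  invisible(x)
}

#' Tabulate long-subunit composition counts of a population
#'
#' @param pop An [oligomer_population()].
#' @return Named integer vector of oligomer counts over `0..n` long
#'   subunits, suitable for [parity_fraction()] and
#'   [infer_exchange_unit()].
#' @export
composition_counts <- function(pop) {
  stopifnot(inherits(pop, "oligomer_population"))
  long_sub <- pop$long_units * pop$u
  counts <- tabulate(long_sub + 1L, nbins = pop$n + 1L)
  names(counts) <- 0:pop$n
  counts
}

#' Stochastic unit-swap simulation of subunit exchange
#'
#' Each step picks two distinct oligomers uniformly at random, draws one
#' exchange unit uniformly from each, and swaps them. Long- and short-unit
#' totals are conserved exactly at every step; the long-run composition
#' distribution converges to [composition_distribution()] at the
#' population's overall long fraction.
#'
#' @param pop An [oligomer_population()] with at least 2 oligomers.
#' @param swaps Number of swap steps, >= 0.
#' @param seed Optional integer seed.
#' @param record_every If > 0, composition counts are snapshotted every this
#'   many steps.
#' @return List with `population` (final state), `snapshots` (list of counts
#'   keyed by step, possibly empty) and `swaps`.
#' @export
simulate_exchange <- function(pop, swaps, seed = NULL, record_every = 0) {
  stopifnot(inherits(pop, "oligomer_population"), swaps >= 0)
  k <- length(pop$long_units)
  if (k < 2L) stop("need at least 2 oligomers to exchange")
  if (!is.null(seed)) set.seed(seed)
  L <- pop$long_units
  m <- pop$units_per_oligomer
  snapshots <- list()
  if (swaps > 0) {
    for (s in seq_len(swaps)) {
      ij <- sample.int(k, 2L)
      i <- ij[1L]; j <- ij[2L]
      # a unit drawn uniformly from oligomer i is long with prob L[i] / m
      long_i <- stats::runif(1) < L[i] / m
      long_j <- stats::runif(1) < L[j] / m
      if (long_i != long_j) {
        d <- if (long_i) 1L else -1L
        L[i] <- L[i] - d
        L[j] <- L[j] + d
      }
      if (record_every > 0 && s %% record_every == 0) {
        snap <- oligomer_population(L, pop$n, pop$u)
        snapshots[[as.character(s)]] <- composition_counts(snap)
      }
    }
  }
  list(population = oligomer_population(L, pop$n, pop$u),
       snapshots = snapshots, swaps = swaps)
}
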