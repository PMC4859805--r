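# Seeded generators emulating each experimental input. Defaults are the
# study conditions: FP polarization span 0.05-0.20 with 2% Gaussian noise,
# direct titration 0-1000 uM, competition titration 0-500 uM at 10 uM hub,
# MS intensity noise 5%, spectral noise 1%, equimolar (f = 0.5) mixing.

#' Default titration grid
#'
#' Zero plus log-spaced concentrations, matching a serial-dilution series.
#'
#' @param n Number of points (including zero).
#' @param lo,hi Smallest nonzero and largest concentration (uM).
#' @return Increasing concentration vector (uM) of length `n`.
#' @export
titration_grid <- function(n = 12, lo = 2, hi = 500) {
  stopifnot(n >= 2, lo > 0, hi > lo)
  c(0, exp(seq(log(lo), log(hi), length.out = n - 1)))
}

#' Simulate a direct fluorescence-polarization titration
#'
#' [direct_polarization()] evaluated on a concentration grid plus i.i.d.
#' Gaussian noise expressed as a fraction of the polarization span.
#'
#' @param kd Dissociation constant (uM).
#' @param a_free,a_bound Polarization end points.
#' @param grid Hub concentrations (uM); default 12 points, 0-1000 uM.
#' @param noise Noise standard deviation as a fraction of
#'   `|a_bound - a_free|`.
#' @param seed Optional integer seed.
#' @return Data frame `conc_uM`, `polarization`; the generating parameters
#'   are stored in `attr(, "truth")`.
#' @export
gen_direct_curve <- function(kd = 100, a_free = 0.05, a_bound = 0.20,
                             grid = titration_grid(12, 2, 1000),
                             noise = 0.02, seed = NULL) {
  stopifnot(kd > 0, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  y <- direct_polarization(grid, kd, a_free, a_bound)
  if (length(grid))
    y <- y + stats::rnorm(length(grid), 0, noise * abs(a_bound - a_free))
  out <- data.frame(conc_uM = grid, polarization = y)
  attr(out, "truth") <- list(mode = "direct", kd = kd, a_free = a_free,
                             a_bound = a_bound, noise = noise)
  out
}

#' Simulate a competition fluorescence-polarization titration
#'
#' @inheritParams gen_direct_curve
#' @param p_tot Total hub concentration (uM).
#' @param a0,af Polarization at zero competitor and at full competition.
#' @param grid Unlabeled-peptide concentrations (uM); default 12 points,
#'   0-500 uM.
#' @return Data frame as in [gen_direct_curve()].
#' @export
gen_competition_curve <- function(kd = 90, p_tot = 10, a0 = 0.20, af = 0.05,
                                  grid = titration_grid(12, 2, 500),
                                  noise = 0.02, seed = NULL) {
  stopifnot(kd > 0, p_tot > 0, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  y <- competition_polarization(grid, kd, p_tot, a0, af)
  if (length(grid))
    y <- y + stats::rnorm(length(grid), 0, noise * abs(a0 - af))
  out <- data.frame(conc_uM = grid, polarization = y)
  attr(out, "truth") <- list(mode = "competition", kd = kd, p_tot = p_tot,
                             a0 = a0, af = af, noise = noise)
  out
}

#' Simulate a native electrospray mass spectrum of an oligomer mixture
#'
#' Each species contributes one peak per charge state at the [mz_series()]
#' position, with a Gaussian charge-state envelope (normalised to unit sum,
#' so the summed intensity of a species is proportional to its abundance),
#' multiplicative intensity noise and ppm-scale m/z noise.
#'
#' @param masses Neutral masses (Da), one per species.
#' @param abundances Relative abundances, same length.
#' @param z_centers Envelope centre charge per species.
#' @param z_width Envelope standard deviation (charge units).
#' @param mz_noise_ppm m/z error standard deviation (ppm).
#' @param intensity_noise Multiplicative intensity noise (fraction).
#' @param seed Optional integer seed.
#' @return Data frame `mz`, `intensity` sorted by m/z; truth in
#'   `attr(, "truth")`.
#' @export
gen_mass_spectrum <- function(masses, abundances, z_centers,
                              z_width = 2, mz_noise_ppm = 0,
                              intensity_noise = 0, seed = NULL) {
  stopifnot(length(masses) == length(abundances),
            length(masses) == length(z_centers),
            all(masses > 0), all(abundances >= 0), z_width > 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(masses), function(s) {
    zc <- z_centers[s]
    z <- max(1, floor(zc - 3 * z_width)):ceiling(zc + 3 * z_width)
    w <- stats::dnorm(z, zc, z_width)
    w <- w / sum(w)
    mz <- mz_series(masses[s], z)
    if (mz_noise_ppm > 0)
      mz <- mz * (1 + stats::rnorm(length(mz), 0, mz_noise_ppm * 1e-6))
    int <- abundances[s] * w
    if (intensity_noise > 0)
      int <- pmax(int * (1 + stats::rnorm(length(int), 0, intensity_noise)), 0)
    data.frame(mz = mz, intensity = int, species = s)
  })
  all <- do.call(rbind, rows)
  out <- all[order(all$mz), c("mz", "intensity")]
  rownames(out) <- NULL
  attr(out, "truth") <- list(masses = masses, abundances = abundances,
                             z_centers = z_centers, z_width = z_width,
                             mz_noise_ppm = mz_noise_ppm,
                             intensity_noise = intensity_noise)
  out
}

#' Simulate mixed oligomer populations under monomer or dimer exchange
#'
#' Draws oligomer compositions from [composition_distribution()], i.e. the
#' fully exchanged (equilibrium) state of mixing long- and short-subunit
#' pools through units of size `u`.
#'
#' @param n_oligomers Number of oligomers to draw.
#' @param n Subunits per oligomer.
#' @param u Exchange-unit size (1 or 2).
#' @param f Long-unit mixing fraction.
#' @param seed Optional integer seed.
#' @return List with `population` (an [oligomer_population()], `NULL` when
#'   `n_oligomers` is 0) and `counts` (composition counts over 0..n long
#'   subunits).
#' @export
gen_exchange_populations <- function(n_oligomers, n = 4, u = 2, f = 0.5,
                                     seed = NULL) {
  stopifnot(n_oligomers >= 0, n %% u == 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::setNames(integer(n + 1), 0:n)
  if (n_oligomers == 0)
    return(list(population = NULL, counts = counts))
  B <- stats::rbinom(n_oligomers, n %/% u, f)
  pop <- oligomer_population(B, n, u)
  list(population = pop, counts = composition_counts(pop))
}

#' Simulate a FRET emission-spectrum time series
#'
#' Donor (510 nm) and acceptor (614 nm) Gaussian emission bands on a 1 nm
#' grid over 500-700 nm. As the exchanged fraction rises, the acceptor band
#' grows and the donor band shrinks linearly, so the 614/510 ratio is a
#' monotone readout of exchange.
#'
#' @param times Time stamps (min), strictly increasing.
#' @param fractions Exchanged fraction at each time, in \[0, 1\].
#' @param donor_amp,acceptor_amp0 Donor amplitude and acceptor amplitude at
#'   zero exchange.
#' @param transfer Fraction of donor amplitude converted to acceptor at
#'   full exchange.
#' @param noise Additive Gaussian noise, fraction of the donor amplitude.
#' @param seed Optional integer seed.
#' @return List of per-time-point lists with elements `time_min`,
#'   `wavelength_nm`, `intensity`; truth in `attr(, "truth")`.
#' @export
gen_fret_series <- function(times, fractions, donor_amp = 4,
                            acceptor_amp0 = 0.5, transfer = 0.6,
                            noise = 0.01, seed = NULL) {
  stopifnot(length(times) == length(fractions))
  if (any(fractions < 0 | fractions > 1))
    stop("exchanged fractions must lie in [0, 1]")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  wl <- seq(500, 700, by = 1)
  out <- lapply(seq_along(times), function(i) {
    fr <- fractions[i]
    don <- donor_amp * (1 - transfer * fr) * stats::dnorm(wl, 510, 15) /
      stats::dnorm(510, 510, 15)
    acc <- (acceptor_amp0 + donor_amp * transfer * fr) *
      stats::dnorm(wl, 614, 20) / stats::dnorm(614, 614, 20)
    int <- don + acc
    if (noise > 0) int <- pmax(int + stats::rnorm(length(wl), 0,
                                                  noise * donor_amp), 0)
    list(time_min = times[i], wavelength_nm = wl, intensity = int)
  })
  attr(out, "truth") <- list(fractions = fractions, donor_amp = donor_amp,
                             acceptor_amp0 = acceptor_amp0,
                             transfer = transfer, noise = noise)
  out
}

#' Generate an idealized ring, lock-washer or spiral Calpha assembly
#'
#' Copies of a small rigid Calpha template are placed on a screw: subunit k
#' is rotated by `k * twist_deg` about the z axis and raised by `k * rise`.
#' With `rise = 0` this is a closed ring (C_n when `twist_deg = 360/n`);
#' with `twist_deg = 60` and `rise = pitch/6` a hexagonal P6_1-like spiral.
#' [ring_geometry()] on the subunit centroids inverts the construction
#' exactly in the noiseless case.
#'
#' @param n_subunits Number of subunits, >= 3.
#' @param radius Ring radius (Angstrom) of the subunit centroids.
#' @param twist_deg Rotation per subunit (degrees), in (0, 360).
#' @param rise Axial rise per subunit (Angstrom), >= 0.
#' @param handedness `"right"` or `"left"`; ignored when `rise = 0`.
#' @param template Optional matrix of template Calpha coordinates centred
#'   near the origin; default is a 10-residue helical arc.
#' @return A [ca_structure()] with one chain per subunit (A, B, C, ...).
#' @export
gen_ring_assembly <- function(n_subunits, radius = 50,
                              twist_deg = 360 / n_subunits, rise = 0,
                              handedness = c("right", "left"),
                              template = NULL) {
  handedness <- match.arg(handedness)
  if (n_subunits < 3) stop("need at least 3 subunits")
  stopifnot(radius > 0, twist_deg > 0, twist_deg < 360, rise >= 0)
  if (is.null(template)) {
    # 10-residue helical arc, centred at its centroid
    t10 <- seq(0, 2.5, length.out = 10)
    template <- cbind(2.3 * cos(2 * pi * t10 / 1.8),
                      2.3 * sin(2 * pi * t10 / 1.8), 1.5 * t10)
  }
  template <- sweep(as.matrix(template), 2, colMeans(as.matrix(template)))
  z_sign <- if (handedness == "right") 1 else -1
  chains <- make_chain_ids(n_subunits)
  rows <- lapply(seq_len(n_subunits) - 1L, function(k) {
    th <- k * twist_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    centre <- c(radius * cos(th), radius * sin(th), z_sign * k * rise)
    xyz <- sweep(template %*% t(R), 2, centre, `+`)
    data.frame(chain = chains[k + 1L], resno = seq_len(nrow(template)),
               insert = "", resid = "ALA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  ca_structure(do.call(rbind, rows))
}

make_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(pool)) return(pool[seq_len(n)])
  stop("too many subunits for single-character chain ids")
}
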