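#' FRET ratio of an emission spectrum
#'
#' Acceptor emission at 614 nm divided by donor emission at 510 nm, each
#' read at the nearest wavelength grid point (no interpolation). The rise of
#' this ratio after mixing donor- and acceptor-labeled holoenzymes reports
#' co-assembly of subunits from the two pools.
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm); must span
#'   510 and 614 nm.
#' @param intensity Emission intensities (arbitrary units, >= 0).
#' @param acceptor_nm,donor_nm Read-out wavelengths (nm).
#' @return The dimensionless acceptor/donor ratio.
#' @export
fret_ratio <- function(wavelength_nm, intensity,
                       acceptor_nm = 614, donor_nm = 510) {
  stopifnot(length(wavelength_nm) == length(intensity),
            all(is.finite(wavelength_nm)), all(is.finite(intensity)))
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (min(wavelength_nm) > min(donor_nm, acceptor_nm) ||
      max(wavelength_nm) < max(donor_nm, acceptor_nm))
    stop("wavelength grid does not span the donor/acceptor read-out points")
  i_acc <- which.min(abs(wavelength_nm - acceptor_nm))
  i_don <- which.min(abs(wavelength_nm - donor_nm))
  if (intensity[i_don] == 0)
    stop("donor intensity is zero at ", wavelength_nm[i_don],
         " nm: ratio undefined")
  intensity[i_acc] / intensity[i_don]
}

#' FRET-ratio time course from a series of emission spectra
#'
#' Reduces each spectrum to its [fret_ratio()] and reports whether the
#' series rises with time, using a sign test on consecutive differences
#' (an increase in the ratio over hours of incubation is the signature of
#' ongoing subunit exchange; a flat series means none).
#'
#' @param times Time stamps (min), strictly increasing, length >= 2.
#' @param spectra List (same length) of data frames or lists with elements
#'   `wavelength_nm` and `intensity`.
#' @param alpha Significance level of the one-sided sign test.
#' @inheritParams fret_ratio
#' @return Data frame with columns `time_min` and `ratio`; attribute
#'   `trend` is `"increasing"`, `"no exchange"` or `"decreasing"`, and
#'   attribute `p_value` holds the sign-test p-value for an increase.
#' @export
ratio_timecourse <- function(times, spectra, alpha = 0.05,
                             acceptor_nm = 614, donor_nm = 510) {
  stopifnot(length(times) == length(spectra), length(times) >= 2L)
  if (anyDuplicated(times)) stop("duplicate time stamps")
  if (any(diff(times) <= 0)) stop("time stamps must be strictly increasing")
  ratios <- vapply(spectra, function(s)
    fret_ratio(s$wavelength_nm, s$intensity, acceptor_nm, donor_nm),
    numeric(1))
  d <- diff(ratios)
  pos <- sum(d > 0); neg <- sum(d < 0)
  trend <- "no exchange"; p <- 1
  if (pos + neg > 0) {
    p <- stats::binom.test(pos, pos + neg, alternative = "greater")$p.value
    if (p < alpha) trend <- "increasing"
    else if (stats::binom.test(neg, pos + neg,
                               alternative = "greater")$p.value < alpha)
      trend <- "decreasing"
  }
  structure(data.frame(time_min = times, ratio = ratios),
            trend = trend, p_value = p)
}
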