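PROTON_MASS <- 1.00728  # Da, positive-ion electrospray adduct

#' m/z positions of a charge-state series
#'
#' Positive-ion electrospray relation `m/z = (M + z * 1.00728) / z` for a
#' neutral species of mass `M` carrying `z` protons.
#'
#' @param mass Neutral mass (Da), > 0.
#' @param charges Integer charge states, >= 1.
#' @return m/z values (Th), one per charge, strictly decreasing in `z` when
#'   `charges` is increasing.
#' @export
mz_series <- function(mass, charges) {
  stopifnot(length(mass) == 1L, mass > 0)
  charges <- as.integer(charges)
  if (any(charges < 1L)) stop("charges must be positive integers")
  (mass + charges * PROTON_MASS) / charges
}

#' Infer charge states and species from a native mass spectrum
#'
#' Adjacent-charge-state spacing method: for two peaks `a > b` (in m/z)
#' belonging to one charge-state envelope with consecutive charges, the
#' charge of the higher-m/z peak is `round((b - 1.00728) / (a - b))`. Every
#' peak pair is screened with this relation; a pair is accepted when the two
#' implied neutral masses agree within `tol_ppm`. Accepted (peak, charge,
#' mass) votes are clustered by neutral mass; clusters supported by at least
#' two distinct peaks become species. Peaks that fit no consistent envelope
#' are left unassigned, never forced.
#'
#' @param spectrum Data frame with columns `mz` (Th, > 0) and
#'   `intensity` (>= 0).
#' @param tol_ppm Mass agreement tolerance between peaks of one envelope
#'   (ppm of neutral mass).
#' @param z_max Largest charge considered.
#' @return Data frame with one row per input peak: `mz`, `intensity`,
#'   `charge`, `mass` (neutral-mass estimate from that peak) and `species`
#'   (integer envelope id); `NA` for unassigned peaks.
#' @export
infer_charges <- function(spectrum, tol_ppm = 100, z_max = 60) {
  spectrum <- validate_spectrum(spectrum)
  mz <- spectrum$mz
  n <- length(mz)
  out <- data.frame(mz = mz, intensity = spectrum$intensity,
                    charge = rep(NA_integer_, n), mass = rep(NA_real_, n),
                    species = rep(NA_integer_, n))
  if (n < 2L) return(out)

  # candidate (peak, z, M) votes from all ordered pairs
  votes <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      b <- mz[i]; a <- mz[j]           # a > b
      z <- round((b - PROTON_MASS) / (a - b))
      if (!is.finite(z) || z < 1 || z + 1 > z_max) next
      m_a <- z * (a - PROTON_MASS)
      m_b <- (z + 1) * (b - PROTON_MASS)
      if (abs(m_a - m_b) <= tol_ppm * 1e-6 * m_a) {
        votes[[length(votes) + 1L]] <-
          data.frame(peak = c(j, i), charge = c(z, z + 1L),
                     mass = c(m_a, m_b))
      }
    }
  }
  if (!length(votes)) return(out)
  votes <- do.call(rbind, votes)

  # single-link clustering of implied masses within tolerance
  ordv <- order(votes$mass)
  votes <- votes[ordv, , drop = FALSE]
  gap <- diff(votes$mass) > 2 * tol_ppm * 1e-6 * votes$mass[-nrow(votes)]
  votes$cluster <- cumsum(c(1L, as.integer(gap)))

  # keep clusters with >= 2 distinct peaks; resolve peak conflicts by
  # preferring the cluster with more supporting peaks
  info <- lapply(split(votes, votes$cluster), function(v) {
    peaks <- unique(v$peak)
    list(votes = v, n_peaks = length(peaks))
  })
  info <- info[vapply(info, function(x) x$n_peaks >= 2L, logical(1))]
  if (!length(info)) return(out)
  info <- info[order(vapply(info, function(x) x$n_peaks, integer(1)),
                     decreasing = TRUE)]

  species_id <- 0L
  for (cl in info) {
    v <- cl$votes[!cl$votes$peak %in% which(!is.na(out$species)), ,
                  drop = FALSE]
    if (length(unique(v$peak)) < 2L) next
    species_id <- species_id + 1L
    for (p in unique(v$peak)) {
      vp <- v[v$peak == p, , drop = FALSE]
      zp <- as.integer(names(sort(table(vp$charge), decreasing = TRUE))[1])
      out$charge[p] <- zp
      out$mass[p] <- zp * (mz[p] - PROTON_MASS)
      out$species[p] <- species_id
    }
  }
  out
}

#' Deconvolve a native mass spectrum into neutral species
#'
#' Runs [infer_charges()] to locate the charge-state envelopes, then reduces
#' each to a neutral-mass estimate (intensity-weighted mean over its peaks,
#' intensity-weighted standard deviation as uncertainty) and a summed
#' abundance. When two species are oligomers of the same subunit, some m/z
#' positions coincide exactly (e.g. a 12-mer at charge 18 and a 14-mer at
#' charge 21 of a common subunit); such shared peaks are attributed to every
#' matching envelope, with their intensity split in proportion to each
#' species' Gaussian charge-state envelope as estimated from its unshared
#' peaks.
#'
#' @inheritParams infer_charges
#' @return Data frame with one row per species: `species`, `mass`,
#'   `mass_sd`, `intensity`, `n_peaks`, `charges` (comma-separated charge
#'   states used). Empty spectrum gives zero rows.
#' @export
deconvolve <- function(spectrum, tol_ppm = 100, z_max = 60) {
  spectrum <- validate_spectrum(spectrum)
  assigned <- infer_charges(spectrum, tol_ppm = tol_ppm, z_max = z_max)
  empty <- data.frame(species = integer(), mass = numeric(),
                      mass_sd = numeric(), intensity = numeric(),
                      n_peaks = integer(), charges = character(),
                      stringsAsFactors = FALSE)
  hit <- assigned[!is.na(assigned$species), , drop = FALSE]
  if (!nrow(hit)) return(empty)

  # provisional species masses from the exclusive envelope assignment
  masses0 <- vapply(split(hit, hit$species), function(v)
    stats::weighted.mean(v$mass, v$intensity), numeric(1))

  # re-match every peak against every provisional mass: peak p belongs to
  # species s if some charge z puts z * (mz_p - proton) within tolerance
  mz <- spectrum$mz; int <- spectrum$intensity
  n_pk <- length(mz); n_sp <- length(masses0)
  z_of <- matrix(NA_integer_, n_pk, n_sp)
  for (s in seq_len(n_sp)) {
    z <- round(masses0[s] / (mz - PROTON_MASS))
    ok <- z >= 1 & z <= z_max &
      abs(z * (mz - PROTON_MASS) - masses0[s]) <= tol_ppm * 1e-6 * masses0[s]
    z_of[ok, s] <- as.integer(z[ok])
  }
  member <- !is.na(z_of)
  n_match <- rowSums(member)

  # Gaussian envelope (mean, sd, amplitude in z) per species from peaks it
  # holds exclusively; used only to split multiply matched peaks
  share <- matrix(0, n_pk, n_sp)
  env <- lapply(seq_len(n_sp), function(s) {
    excl <- member[, s] & n_match == 1L
    if (!any(excl)) return(NULL)
    z <- z_of[excl, s]; w <- int[excl]
    mu <- stats::weighted.mean(z, w)
    sd_z <- sqrt(max(sum(w * (z - mu)^2) / sum(w), 0.25))
    amp <- sum(w) / sum(stats::dnorm(z, mu, sd_z))
    list(mu = mu, sd = sd_z, amp = amp)
  })
  for (p in seq_len(n_pk)) {
    sp <- which(member[p, ])
    if (!length(sp)) next
    if (length(sp) == 1L) { share[p, sp] <- int[p]; next }
    pred <- vapply(sp, function(s) {
      e <- env[[s]]
      if (is.null(e)) return(0)
      e$amp * stats::dnorm(z_of[p, s], e$mu, e$sd)
    }, numeric(1))
    if (sum(pred) == 0) pred <- rep(1, length(sp))
    share[p, sp] <- int[p] * pred / sum(pred)
  }

  res <- lapply(seq_len(n_sp), function(s) {
    pk <- which(member[, s])
    w <- share[pk, s]
    if (sum(w) == 0) w <- rep(1, length(pk))
    m_each <- z_of[pk, s] * (mz[pk] - PROTON_MASS)
    m <- stats::weighted.mean(m_each, w)
    data.frame(species = s, mass = m,
               mass_sd = sqrt(sum(w / sum(w) * (m_each - m)^2)),
               intensity = sum(share[pk, s]), n_peaks = length(pk),
               charges = paste(sort(unique(z_of[pk, s])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res[order(res$mass), , drop = FALSE]
}

#' Assign oligomer and tag stoichiometry to a neutral mass
#'
#' Finds the subunit count `n` and missing-tag count `t` whose lattice mass
#' `n * m_subunit - t * m_tag` is closest to the observed mass, with
#' `0 <= t <= n`. Tags are counted as *absent* relative to the fully tagged
#' n-mer, matching "n-mer minus t His tags" species labels for constructs
#' with incompletely cleaved purification tags. Ties break toward smaller
#' `n`, then smaller `t`.
#'
#' @param mass Observed neutral mass (Da).
#' @param m_subunit Mass of one (fully tagged) subunit (Da).
#' @param m_tag Mass removed per missing tag (Da); 0 disables tag counting.
#' @param tol Largest residual (Da) accepted as an assignment.
#' @return Data frame row: `n`, `t`, `residual`, `assigned`. When no lattice
#'   point lies within `tol`, `assigned` is `FALSE` and `n`, `t` report the
#'   best (rejected) candidate.
#' @export
assign_stoichiometry <- function(mass, m_subunit, m_tag = 0, tol = 500) {
  stopifnot(mass > 0, m_subunit > 0, m_tag >= 0, tol > 0)
  n_max <- max(1L, ceiling(mass / m_subunit) + 1L)
  best <- c(n = NA_real_, t = NA_real_, resid = Inf)
  for (n in seq_len(n_max)) {
    t_range <- if (m_tag > 0) 0:n else 0L
    for (t in t_range) {
      r <- abs(mass - (n * m_subunit - t * m_tag))
      if (r < best["resid"] - 1e-9) best <- c(n = n, t = t, resid = r)
    }
  }
  data.frame(n = as.integer(best[["n"]]), t = as.integer(best[["t"]]),
             residual = best[["resid"]], assigned = best[["resid"]] <= tol)
}

#' Collision-induced dissociation products of an oligomer
#'
#' Collisional activation of a gaseous protein complex ejects one highly
#' charged monomer, leaving the (n-1)-mer: a 12-mer yields a monomer plus an
#' 11-mer, a 14-mer a monomer plus a 13-mer.
#'
#' @param n Parent subunit count, >= 2.
#' @return Named integer vector `c(ejected = 1, residual = n - 1)`.
#' @export
cid_products <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L)
  if (n < 2L) stop("CID of an oligomer requires n >= 2")
  c(ejected = 1L, residual = n - 1L)
}

#' Abundance ratio of two oligomeric stoichiometries
#'
#' @param assignments Data frame with columns `n` (subunit count) and
#'   `intensity` (summed species intensity), e.g. [deconvolve()] output
#'   joined with [assign_stoichiometry()].
#' @param n_a,n_b Subunit counts to compare.
#' @return Summed-intensity ratio (species with `n_a` subunits over `n_b`).
#' @export
abundance_ratio <- function(assignments, n_a, n_b) {
  stopifnot(all(c("n", "intensity") %in% names(assignments)))
  ia <- sum(assignments$intensity[assignments$n == n_a])
  ib <- sum(assignments$intensity[assignments$n == n_b])
  if (ia == 0 || ib == 0)
    stop("abundance ratio undefined: species with n = ",
         if (ia == 0) n_a else n_b, " absent from the assignments")
  ia / ib
}

#' Full stoichiometry pipeline for a peak list
#'
#' Convenience wrapper: deconvolve the spectrum, then assign each species a
#' subunit count with [assign_stoichiometry()].
#'
#' @inheritParams deconvolve
#' @inheritParams assign_stoichiometry
#' @return [deconvolve()] output with `n`, `t`, `residual`, `assigned`
#'   columns appended.
#' @export
ms_stoichiometry <- function(spectrum, m_subunit, m_tag = 0, tol = 500,
                             tol_ppm = 100, z_max = 60) {
  species <- deconvolve(spectrum, tol_ppm = tol_ppm, z_max = z_max)
  if (!nrow(species)) {
    species[c("n", "t", "residual", "assigned")] <-
      list(integer(), integer(), numeric(), logical())
    return(species)
  }
  assign <- do.call(rbind, lapply(species$mass, assign_stoichiometry,
                                  m_subunit = m_subunit, m_tag = m_tag,
                                  tol = tol))
  cbind(species, assign)
}

validate_spectrum <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("mz", "intensity") %in% names(spectrum)))
  if (any(spectrum$mz <= 0)) stop("m/z values must be positive")
  if (any(!is.finite(spectrum$intensity)) || any(spectrum$intensity < 0))
    stop("intensities must be finite and non-negative")
  spectrum[order(spectrum$mz), c("mz", "intensity"), drop = FALSE]
}
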