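# Independent oracles used to cross-check the package's implementations.
# Each solves the same physical problem by a different route (numeric
# equilibrium, brute-force enumeration, finite differences, random search)
# and never calls the code path it checks.

# Exact 1:1 mass-action equilibrium by root-finding on the law of mass
# action itself (no quadratic formula).
massaction_complex <- function(p_tot, l_tot, kd) {
  if (l_tot == 0 || p_tot == 0) return(0)
  if (kd == 0) return(min(p_tot, l_tot))
  f <- function(pl) (p_tot - pl) * (l_tot - pl) / pl - kd
  stats::uniroot(f, c(1e-15, min(p_tot, l_tot) - 1e-15),
                 tol = 1e-13)$root
}

# Three-species (protein + labeled + unlabeled ligand) numeric equilibrium.
# Returns the polarization implied by the bound fraction of the labeled
# species, rescaled so that l_tot = 0 reproduces a0.
three_species_fp <- function(l_tot, p_tot, lab_tot, kd, kd_lab, a0, af) {
  free_p <- function(lt) {
    # conservation: P + PL + PLab = p_tot with free L = lt/(1 + P/kd) etc.
    g <- function(P) P + P * (lt / (1 + P / kd)) / kd +
      P * (lab_tot / (1 + P / kd_lab)) / kd_lab - p_tot
    stats::uniroot(g, c(1e-15, p_tot), tol = 1e-14)$root
  }
  fb <- function(lt) {
    P <- free_p(lt)
    (P / kd_lab) / (1 + P / kd_lab)
  }
  fb0 <- fb(0)
  vapply(l_tot, function(lt) af + (a0 - af) * fb(lt) / fb0, numeric(1))
}

# Brute-force species finding: every (peak, z) pair is a mass hypothesis;
# masses supported by >= 3 distinct peaks within tol_ppm are species.
brute_force_species <- function(spectrum, tol_ppm, z_max = 60,
                                min_peaks = 3) {
  proton <- 1.00728
  cand <- do.call(rbind, lapply(seq_len(nrow(spectrum)), function(i) {
    z <- 1:z_max
    data.frame(peak = i, z = z, mass = z * (spectrum$mz[i] - proton))
  }))
  cand <- cand[order(cand$mass), ]
  gap <- diff(cand$mass) > tol_ppm * 1e-6 * cand$mass[-nrow(cand)]
  cand$cluster <- cumsum(c(1L, as.integer(gap)))
  hits <- lapply(split(cand, cand$cluster), function(v) {
    if (length(unique(v$peak)) < min_peaks) return(NULL)
    data.frame(mass = mean(v$mass), n_peaks = length(unique(v$peak)))
  })
  hits <- do.call(rbind, hits)
  # keep dominant, well-supported clusters
  hits[order(-hits$n_peaks), , drop = FALSE]
}

# Finite-difference Hessian of the elastic-network energy
# E = sum over contact pairs of 0.5 * (|xi - xj| - d0_ij)^2
# evaluated at the equilibrium coordinates (where all terms vanish).
fd_enm_hessian <- function(xyz, cutoff, h = 1e-4) {
  n <- nrow(xyz)
  d0 <- as.matrix(dist(xyz))
  contact <- d0 <= cutoff & upper.tri(d0)
  energy <- function(v) {
    x <- matrix(v, ncol = 3, byrow = TRUE)
    e <- 0
    idx <- which(contact, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      e <- e + 0.5 * (sqrt(sum((x[i, ] - x[j, ])^2)) - d0[i, j])^2
    }
    e
  }
  v0 <- as.vector(t(xyz))
  m <- length(v0)
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      vpp <- v0; vpp[a] <- vpp[a] + h; vpp[b] <- vpp[b] + h
      vpm <- v0; vpm[a] <- vpm[a] + h; vpm[b] <- vpm[b] - h
      vmp <- v0; vmp[a] <- vmp[a] - h; vmp[b] <- vmp[b] + h
      vmm <- v0; vmm[a] <- vmm[a] - h; vmm[b] <- vmm[b] - h
      H[a, b] <- (energy(vpp) - energy(vpm) - energy(vmp) + energy(vmm)) /
        (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# Brute-force rigid superposition: random rotations (uniform quaternions)
# plus local refinement, minimising RMSD after centroid matching.
random_rotation_rmsd <- function(A, B, n_random = 4000, seed = 101) {
  set.seed(seed)
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  rmsd_of <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  qs <- matrix(rnorm(4 * n_random), ncol = 4)
  vals <- apply(qs, 1, rmsd_of)
  best_q <- qs[which.min(vals), ]
  opt <- optim(best_q, rmsd_of, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  opt$value
}

# random rigid transform for invariance properties
random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, rig) sweep(xyz %*% t(rig$R), 2, rig$t, `+`)
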