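#' Elastic-network normal modes of a Calpha structure
#'
#' Anisotropic (Tirion-type) elastic network: every Calpha pair within the
#' cutoff is joined by a uniform harmonic spring, the 3N x 3N Hessian of the
#' pairwise-distance potential is assembled analytically and diagonalised.
#' A connected, non-collinear structure has exactly six zero-frequency
#' rigid-body modes; internal motions start at mode 7, ordered by increasing
#' eigenvalue. Mode shapes, not absolute frequencies, are the meaningful
#' output (the spring constant only scales the spectrum).
#'
#' A collinear bead chain is degenerate for this potential: transverse
#' displacements cost no energy, so it has 2N + 1 zero modes rather than 6.
#'
#' @param structure A [ca_structure()] or coordinate matrix (rows = atoms).
#' @param cutoff Spring cutoff distance (Angstrom).
#' @param gamma Uniform spring constant (arbitrary units; scales
#'   eigenvalues only).
#' @param zero_tol_factor Eigenvalues below `zero_tol_factor * max(eig)` are
#'   counted as zero modes.
#' @return List of class `"enm_modes"`: `values` (eigenvalues ascending),
#'   `vectors` (3N x 3N, orthonormal columns matching `values`), `n_zero`,
#'   `cutoff`, `n_atoms`.
#' @export
enm_modes <- function(structure, cutoff = 10, gamma = 1,
                      zero_tol_factor = 1e-8) {
  xyz <- if (is.matrix(structure)) structure else ca_coords(structure)
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 atoms")
  d2 <- as.matrix(stats::dist(xyz))^2
  contact <- d2 <= cutoff^2 & upper.tri(d2)

  comp <- connected_components(contact | t(contact))
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("contact graph is disconnected at cutoff ", cutoff, " A: ",
         length(sizes), " components of sizes ",
         paste(sizes, collapse = ", "))
  }

  H <- matrix(0, 3 * n, 3 * n)
  idx <- function(i) (3 * (i - 1) + 1):(3 * i)
  pairs <- which(contact, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dv <- xyz[j, ] - xyz[i, ]
    blk <- gamma * tcrossprod(dv) / sum(dv^2)
    H[idx(i), idx(j)] <- H[idx(i), idx(j)] - blk
    H[idx(j), idx(i)] <- H[idx(j), idx(i)] - blk
    H[idx(i), idx(i)] <- H[idx(i), idx(i)] + blk
    H[idx(j), idx(j)] <- H[idx(j), idx(j)] + blk
  }
  eig <- eigen(H, symmetric = TRUE)
  values <- rev(eig$values)
  vectors <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  n_zero <- sum(values < zero_tol_factor * max(values))
  res <- list(values = values, vectors = vectors, n_zero = n_zero,
              cutoff = cutoff, n_atoms = n)
  class(res) <- "enm_modes"
  res
}

#' @export
print.enm_modes <- function(x, ...) {
  cat("Elastic-network normal modes:", x$n_atoms, "atoms, cutoff",
      x$cutoff, "A\n")
  cat("  zero modes:", x$n_zero, "; lowest internal eigenvalues:",
      paste(signif(x$values[x$n_zero + seq_len(min(3, 3 * x$n_atoms -
        x$n_zero))], 3), collapse = ", "), "\n")
  invisible(x)
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Overlap between a normal mode and an observed displacement
#'
#' Normalised inner product (cosine) of a mode vector and a displacement
#' vector over the same atoms: 1 means the conformational change lies
#' exactly along the mode, 0 that the two are orthogonal. Used to ask
#' whether the difference between two hub conformations is captured by a
#' low-frequency mode.
#'
#' @param mode Numeric 3N vector (a column of `enm_modes()$vectors`).
#' @param displacement Numeric 3N vector (e.g. the flattened, unscaled
#'   b - a Calpha differences).
#' @return Cosine overlap in \[-1, 1\].
#' @export
mode_overlap <- function(mode, displacement) {
  stopifnot(length(mode) == length(displacement))
  nm <- sqrt(sum(mode^2)); nd <- sqrt(sum(displacement^2))
  if (nm == 0 || nd == 0) stop("zero vector: overlap undefined")
  sum(mode * displacement) / (nm * nd)
}
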