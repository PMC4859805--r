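#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation minimising the RMSD between
#' paired Calpha positions, computed by singular value decomposition with a
#' determinant correction so reflections are never returned.
#'
#' @param mobile,target [ca_structure()] objects (or plain coordinate
#'   matrices with matched rows).
#' @param selection Optional character vector of residue keys
#'   (`"chain_resno_insert"`) or chain ids used for the alignment; by
#'   default all residue keys shared by both structures. Ignored for matrix
#'   input.
#' @return List of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation` (length 3, applied after rotation), `rmsd` (Angstrom over
#'   the selection), `n` (aligned pairs). Apply with [apply_transform()].
#' @export
kabsch_superpose <- function(mobile, target, selection = NULL) {
  pair <- paired_coords(mobile, target, selection)
  A <- pair$mobile; B <- pair$target
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 paired residues, got ", n)
  ca_m <- colMeans(A); ca_t <- colMeans(B)
  A0 <- sweep(A, 2, ca_m); B0 <- sweep(B, 2, ca_t)
  if (qr(A0)$rank < 2L || qr(B0)$rank < 2L)
    stop("selection is collinear: superposition is degenerate")
  s <- svd(crossprod(A0, B0))       # H = A0' B0 ; R = V diag(1,1,d) U'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ca_t - as.vector(R %*% ca_m)
  moved <- sweep(A %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition over", x$n, "residue pairs, RMSD =",
      signif(x$rmsd, 4), "A\n")
  invisible(x)
}

#' Apply a rigid transform to a structure
#'
#' @param structure A [ca_structure()] or coordinate matrix.
#' @param transform A `"superposition"` from [kabsch_superpose()].
#' @return Same type as the input, with coordinates `R x + t`.
#' @export
apply_transform <- function(structure, transform) {
  stopifnot(inherits(transform, "superposition"))
  move <- function(m) sweep(m %*% t(transform$rotation), 2,
                            transform$translation, `+`)
  if (is.matrix(structure)) return(move(structure))
  stopifnot(inherits(structure, "ca_structure"))
  structure$ca[c("x", "y", "z")] <- move(ca_coords(structure))
  if (!is.null(structure$atoms))
    structure$atoms[c("x", "y", "z")] <-
      move(as.matrix(structure$atoms[c("x", "y", "z")]))
  structure
}

paired_coords <- function(mobile, target, selection = NULL) {
  if (is.matrix(mobile) && is.matrix(target)) {
    stopifnot(nrow(mobile) == nrow(target))
    return(list(mobile = mobile, target = target,
                keys = as.character(seq_len(nrow(mobile)))))
  }
  stopifnot(inherits(mobile, "ca_structure"), inherits(target, "ca_structure"))
  km <- ca_keys(mobile$ca); kt <- ca_keys(target$ca)
  shared <- intersect(km, kt)
  if (!is.null(selection)) {
    keep <- shared %in% selection |
      vapply(strsplit(shared, "_"), `[`, character(1), 1L) %in% selection
    shared <- shared[keep]
  }
  if (!length(shared)) stop("no shared residue keys between the structures")
  list(mobile = ca_coords(mobile)[match(shared, km), , drop = FALSE],
       target = ca_coords(target)[match(shared, kt), , drop = FALSE],
       keys = shared)
}

#' Per-residue displacement field between two conformations
#'
#' Vectors from structure `a` to structure `b` for residues whose Calpha
#' moves at least `min_len` Angstrom, each scaled by `scale` for display
#' (the drawing convention for conformational-change arrows: scale factor 2,
#' 2 Angstrom display threshold). Residues are matched by
#' (chain, residue number, insertion code); superpose on an anchor selection
#' first with [kabsch_superpose()] + [apply_transform()].
#'
#' @param a,b [ca_structure()] objects sharing residue keys.
#' @param scale Arrow scale factor.
#' @param min_len Minimum true displacement (Angstrom) for a vector to be
#'   reported; the threshold is inclusive (`>=`).
#' @return Data frame of class `"displacement_field"` with `key`, `dx`,
#'   `dy`, `dz` (scaled components) and `length` (unscaled, Angstrom);
#'   attributes `n_shown` and `n_hidden`.
#' @export
displacement_field <- function(a, b, scale = 2, min_len = 2) {
  pair <- paired_coords(a, b)
  if (inherits(a, "ca_structure") &&
      length(pair$keys) == 0) stop("disjoint residue keys")
  d <- pair$target - pair$mobile
  len <- sqrt(rowSums(d^2))
  keep <- len >= min_len
  out <- data.frame(key = pair$keys[keep],
                    dx = d[keep, 1] * scale,
                    dy = d[keep, 2] * scale,
                    dz = d[keep, 3] * scale,
                    length = len[keep], stringsAsFactors = FALSE)
  structure(out, n_shown = sum(keep), n_hidden = sum(!keep),
            class = c("displacement_field", "data.frame"))
}

#' Screw-axis (helical) parameters of an ordered ring or spiral
#'
#' Fits a screw axis to ordered subunit centroids and reports the mean
#' per-step rotation, per-step axial rise and handedness. A closed planar
#' ring (e.g. the six dimers of a dodecameric hub) gives rotation 360/m and
#' rise ~0; a lock-washer or P6_1-like spiral gives the same rotation with a
#' nonzero rise whose sign, relative to the rotation sense, sets the
#' handedness (right-handed when the assembly advances along the axis like
#' a standard screw).
#'
#' The axis direction is estimated from the second differences of the
#' centroid sequence (which lie in the plane perpendicular to the axis for
#' any circular helix), the rise from the least-squares slope of the axial
#' coordinate versus step, and the rotation from the mean angular increment
#' about the fitted axis after a least-squares circle fit.
#'
#' @param centroids Matrix of ordered subunit centroids (rows, x/y/z in
#'   Angstrom), at least 3.
#' @param closed_tol Absolute rise (Angstrom) below which the assembly is
#'   called `"closed"`.
#' @return List of class `"helical_params"`: `axis` (unit vector, oriented
#'   so the per-step rotation is positive), `rotation_deg` in (0, 360),
#'   `rise` (Angstrom per step, signed along `axis`), `handedness`
#'   (`"right"`, `"left"` or `"closed"`), `radius` (mean centroid distance
#'   from the axis).
#' @export
ring_geometry <- function(centroids, closed_tol = 0.5) {
  centroids <- as.matrix(centroids)
  m <- nrow(centroids)
  if (m < 3L) stop("need at least 3 ordered centroids")
  v <- diff(centroids)
  if (qr(v)$rank < 2L) stop("centroids are collinear: no ring geometry")
  if (m >= 4L) {
    w <- diff(v)                       # second differences: perpendicular to axis
    axis <- svd(w, nu = 0)$v[, 3]
  } else {
    axis <- pracma_cross(v[1, ], v[2, ])
    axis <- axis / sqrt(sum(axis^2))
  }
  axis <- axis / sqrt(sum(axis^2))

  z <- as.vector(centroids %*% axis)
  k <- seq_len(m)
  rise <- stats::cov(z, k) / stats::var(k)   # LS slope of z on step index

  # orthonormal in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(axis, e1)
  p <- cbind(as.vector(centroids %*% e1), as.vector(centroids %*% e2))

  ctr <- fit_circle_2d(p)
  q <- sweep(p, 2, ctr)
  ang <- atan2(q[, 2], q[, 1])
  dang <- diff(ang)
  dang <- ((dang + pi) %% (2 * pi)) - pi   # unwrap to (-pi, pi]
  rot <- mean(dang)
  if (rot < 0) {        # orient the axis so the rotation sense is positive
    axis <- -axis; rot <- -rot; rise <- -rise
  }
  handed <- if (abs(rise) < closed_tol) "closed"
            else if (rise > 0) "right" else "left"
  structure(list(axis = axis, rotation_deg = rot * 180 / pi, rise = rise,
                 handedness = handed,
                 radius = mean(sqrt(rowSums(q^2)))),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "Screw axis: rotation %.2f deg/step, rise %.2f A/step (%s), radius %.1f A\n",
    x$rotation_deg, x$rise, x$handedness, x$radius))
  invisible(x)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Kasa algebraic circle fit; exact for points on a circle
fit_circle_2d <- function(p) {
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- rowSums(p^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("circle fit failed: centroids may be collinear"))
  sol[1:2]
}

#' Cross-interface polar contacts
#'
#' Donor/acceptor heavy-atom (N or O) pairs between two subunits within a
#' distance cutoff: a count of candidate hydrogen bonds at a hub interface.
#' Loss of these contacts when an interface cracks open (sidechains pulled
#' away from their partners) is scored as a drop in the contact count.
#'
#' @param structure A [ca_structure()] read with full atoms
#'   ([read_ca_structure()] keeps them).
#' @param chains_a,chains_b Chain ids of the two sides of the interface.
#' @param cutoff Heavy-atom distance cutoff (Angstrom), inclusive.
#' @return Data frame of contacts (`chain_a`, `resno_a`, `atom_a`,
#'   `chain_b`, `resno_b`, `atom_b`, `dist`) with attribute `n_contacts`.
#' @export
polar_contacts <- function(structure, chains_a, chains_b, cutoff = 3.5) {
  stopifnot(inherits(structure, "ca_structure"))
  at <- structure$atoms
  if (is.null(at) || !"elesy" %in% names(at))
    stop("atoms unavailable: full-atom records are required for polar contacts")
  polar <- at[at$elesy %in% c("N", "O"), , drop = FALSE]
  pa <- polar[polar$chain %in% chains_a, , drop = FALSE]
  pb <- polar[polar$chain %in% chains_b, , drop = FALSE]
  if (!nrow(pa) || !nrow(pb))
    stop("atoms unavailable: no N/O atoms for one side of the interface")
  xa <- as.matrix(pa[c("x", "y", "z")])
  xb <- as.matrix(pb[c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  hits <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  out <- data.frame(chain_a = pa$chain[hits[, 1]],
                    resno_a = pa$resno[hits[, 1]],
                    atom_a = pa$elety[hits[, 1]],
                    chain_b = pb$chain[hits[, 2]],
                    resno_b = pb$resno[hits[, 2]],
                    atom_b = pb$elety[hits[, 2]],
                    dist = sqrt(pmax(d2[hits], 0)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_contacts") <- nrow(out)
  out
}
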