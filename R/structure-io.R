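#' Construct a Calpha structure object
#'
#' @param ca Data frame with columns `chain`, `resno`, `insert` (insertion
#'   code, `""` if none), `resid` (residue name) and coordinates `x`, `y`,
#'   `z` in Angstrom, one row per Calpha in file order.
#' @param atoms Optional full heavy-atom table (same columns plus `elety`
#'   atom name and `elesy` element symbol) for interface-contact analysis.
#' @return Object of class `"ca_structure"`.
#' @export
ca_structure <- function(ca, atoms = NULL) {
  need <- c("chain", "resno", "insert", "resid", "x", "y", "z")
  stopifnot(is.data.frame(ca), all(need %in% names(ca)))
  if (!nrow(ca)) stop("no Calpha records")
  if (any(!is.finite(as.matrix(ca[c("x", "y", "z")]))))
    stop("non-finite coordinates")
  keys <- ca_keys(ca)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    stop("duplicate (chain, residue) keys: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  structure(list(ca = ca, atoms = atoms), class = "ca_structure")
}

ca_keys <- function(ca) paste(ca$chain, ca$resno, ca$insert, sep = "_")

#' @export
print.ca_structure <- function(x, ...) {
  cat("Calpha structure:", nrow(x$ca), "residues in",
      length(unique(x$ca$chain)), "chain(s) [",
      paste(unique(x$ca$chain), collapse = " "), "]\n")
  if (!is.null(x$atoms))
    cat("Full atom table present:", nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Coordinate matrix of a Calpha structure
#'
#' @param structure A [ca_structure()].
#' @return Numeric matrix, one row per residue, columns x/y/z (Angstrom).
#' @export
ca_coords <- function(structure) {
  stopifnot(inherits(structure, "ca_structure"))
  as.matrix(structure$ca[c("x", "y", "z")])
}

#' Read a PDB file into a Calpha structure
#'
#' Parses ATOM records (via \pkg{bio3d}), keeps Calpha atoms with alternate
#' location `""` or `"A"`, preserves insertion codes in the residue keys and
#' ignores HETATM records. The full heavy-atom table is retained for
#' [polar_contacts()].
#'
#' @param file Path to a PDB file.
#' @param chains Optional character vector restricting to these chain ids.
#' @return A [ca_structure()].
#' @export
read_ca_structure <- function(file, chains = NULL) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at <- at[at$alt %in% c("", "A"), , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no Calpha atoms in ", file)
  mk <- function(d) data.frame(chain = d$chain, resno = d$resno,
                               insert = d$insert, resid = d$resid,
                               x = d$x, y = d$y, z = d$z,
                               stringsAsFactors = FALSE)
  atoms <- mk(at)
  atoms$elety <- at$elety
  atoms$elesy <- at$elesy
  ca_structure(mk(ca), atoms = atoms)
}

#' Write a Calpha structure as a PDB file
#'
#' @param structure A [ca_structure()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ca_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "ca_structure"))
  ca <- structure$ca
  xyz <- as.vector(t(as.matrix(ca[c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, resno = ca$resno,
                   chain = ca$chain, resid = ca$resid,
                   elety = rep("CA", nrow(ca)), insert = ca$insert)
  invisible(file)
}

#' Subunit centroids of an assembly
#'
#' Mean Calpha position per subunit, in the supplied subunit order (ring
#' tracing is not inferred automatically; pass chains in ring order, e.g.
#' A..N around the hub).
#'
#' @param structure A [ca_structure()].
#' @param subunits Character vector of chain ids in ring/spiral order, or a
#'   list of chain-id vectors when a subunit spans several chains.
#' @return Matrix of centroids (one row per subunit, x/y/z in Angstrom).
#' @export
subunit_centroids <- function(structure, subunits) {
  stopifnot(inherits(structure, "ca_structure"))
  if (!is.list(subunits)) subunits <- as.list(subunits)
  xyz <- ca_coords(structure)
  out <- t(vapply(subunits, function(ch) {
    sel <- structure$ca$chain %in% ch
    if (!any(sel)) stop("no residues for chain(s) ", paste(ch, collapse = ","))
    colMeans(xyz[sel, , drop = FALSE])
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}
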