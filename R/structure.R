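#' Mass-weighted centre of mass of a PDB selection
#'
#' Convenience reader for setting up real-system analyses (e.g. extracting
#' the ligand and reference-group COMs that define rho and d).  Requires the
#' bio3d package.
#'
#' @param path PDB file
#' @param selection list understood by [bio3d::atom.select()]: any of
#'   \code{chain}, \code{resno}, \code{resid}, \code{elety}, \code{eleno}
#' @return length-3 COM in Angstrom, with attribute \code{"mass"} (total amu)
#' @examples
#' pdb <- system.file("extdata", "synthetic_hostguest.pdb", package = "lvmetad")
#' read_structure_com(pdb, list(resid = "LIG"))
#' @export
read_structure_com <- function(path, selection) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_structure_com requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  sel <- do.call(bio3d::atom.select, c(list(pdb), selection, verbose = FALSE))
  if (length(sel$atom) == 0)
    stop("selection error: no atoms matched", call. = FALSE)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  ele <- suppressWarnings(bio3d::atom2ele(pdb))[sel$atom]
  masses <- element_masses()[ele]
  if (any(is.na(masses)))
    stop(sprintf("selection error: no mass for element '%s'",
                 ele[which(is.na(masses))[1]]), call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  com <- colSums(xyz * masses) / sum(masses)
  structure(as.numeric(com), mass = sum(masses))
}

# standard atomic masses (amu) for the elements of typical protein-ligand
# systems
element_masses <- function() {
  c(H = 1.00794, D = 2.0141, C = 12.0107, N = 14.0067, O = 15.9994,
    F = 18.9984, Na = 22.9898, Mg = 24.305, P = 30.9738, S = 32.065,
    Cl = 35.453, K = 39.0983, Ca = 40.078, Mn = 54.938, Fe = 55.845,
    Co = 58.9332, Ni = 58.6934, Cu = 63.546, Zn = 65.38, Se = 78.96,
    Br = 79.904, I = 126.904)
}
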