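# electron counts of the elements common in protein PDB files
.element_electrons <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
                        SE = 34, FE = 26, MG = 12, MN = 25, ZN = 30,
                        CA = 20, "NA" = 11, K = 19, CL = 17)

#' Read a subunit from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records, resolves each atom's element
#' to its electron count, converts coordinates from Angstrom to nm, and
#' centers the atom set on its electron-weighted center of mass. Unknown
#' elements raise a warning and fall back to carbon.
#'
#' @param path PDB file path.
#' @param het logical, include HETATM records (bound ligands, ions).
#' @return Data frame with columns `x, y, z` (nm, centered) and `electrons`,
#'   ready for [coarse_grain_subunit()].
#' @export
read_pdb_subunit <- function(path, het = FALSE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) {
    stop("read_pdb_subunit: no atoms in ", path, call. = FALSE)
  }
  ele <- toupper(trimws(at$elesy))
  blank <- is.na(ele) | ele == ""
  # fall back to the first letter of the atom name when the element column
  # is absent
  ele[blank] <- substr(gsub("[^A-Za-z].*$", "",
                            toupper(trimws(at$elety[blank]))), 1, 1)
  electrons <- .element_electrons[ele]
  if (any(is.na(electrons))) {
    warning("read_pdb_subunit: unknown element(s) ",
            paste(unique(ele[is.na(electrons)]), collapse = ", "),
            "; using carbon")
    electrons[is.na(electrons)] <- .element_electrons[["C"]]
  }
  out <- data.frame(x = at$x / 10, y = at$y / 10, z = at$z / 10,
                    electrons = as.numeric(electrons))
  for (cl in c("x", "y", "z")) {
    out[[cl]] <- out[[cl]] - weighted.mean(out[[cl]], out$electrons)
  }
  out
}
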