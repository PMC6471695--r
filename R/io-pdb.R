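#' Read an atomic model from a PDB file
#'
#' Reads every ATOM/HETATM record (in file order, never reordered) into an
#' \linkS4class{AtomicModel}. Only coordinates and element symbols are kept;
#' occupancy and B-factors are ignored because the Gaussian simulator uses
#' positions (and optionally atomic numbers) only.
#'
#' @param path path to a PDB-format file.
#' @param weighting "uniform" gives every atom weight 1; "atomic_number"
#'   weights atoms by the element's atomic number (unknown elements fall
#'   back to carbon).
#' @return An \linkS4class{AtomicModel}; empty (with a warning) when the
#'   file contains no atom records.
#' @export
readAtomicModel <- function(path, weighting = c("uniform", "atomic_number")) {
  weighting <- match.arg(weighting)
  if (!file.exists(path)) stop("file does not exist: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(pdb) || nrow(pdb$atom) == 0L) {
    warning("no ATOM/HETATM records found in ", path,
            "; returning an empty model")
    return(AtomicModel())
  }
  pos <- as.matrix(pdb$atom[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  elem <- toupper(trimws(as.character(pdb$atom$elesy)))
  w <- if (weighting == "atomic_number") atomicNumbers(elem) else
    rep(1, nrow(pos))
  AtomicModel(pos, weights = w, elements = elem)
}

# Atomic numbers for the elements common in protein/nucleic structures.
atomicNumbers <- function(elements) {
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34, FE = 26,
         ZN = 30, MG = 12, MN = 25, CA = 20, `NA` = 11, K = 19, CL = 17,
         CU = 29, NI = 28, CO = 27, I = 53, BR = 35, F = 9)
  out <- unname(z[elements])
  out[is.na(out)] <- 6  # unknown -> carbon
  out
}
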