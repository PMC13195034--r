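#' Ordered C-alpha trace of one protein domain
#'
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param resno strictly increasing integer residue numbers (default 1..n).
#' @param id source identifier.
#' @param chain chain label.
#' @return a `structure_chain` object.
#' @export
structure_chain <- function(xyz, resno = seq_len(nrow(xyz)), id = "chain",
                            chain = "A") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  if (nrow(xyz) < 3L) stop("structure chain needs >= 3 residues")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(diff(resno) <= 0)) stop("residue indices must be strictly increasing")
  structure(list(id = id, chain = chain, resno = as.integer(resno),
                 xyz = unname(xyz)),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("structure_chain", x$id, "chain", x$chain, ":",
      length(x$resno), "CA residues\n")
  invisible(x)
}

#' @export
length.structure_chain <- function(x) length(x$resno)

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Only ATOM/CA records are consumed; alternate locations resolve to the
#' first occurrence; residues lacking a CA atom are skipped with a warning.
#' Coordinates are taken as-is (no centering).
#'
#' @param path PDB file.
#' @param chain chain identifier (default first chain present).
#' @param residue_range optional `c(lo, hi)`; residues outside are dropped.
#' @return a [structure_chain()].
#' @export
read_structure_ca <- function(path, chain = NULL, residue_range = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain, "' not found in ", path)
  resnos <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  # altloc: first occurrence per residue
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  skipped <- setdiff(resnos, ca$resno)
  if (length(skipped))
    warning(length(skipped), " residue(s) without CA skipped in ", basename(path))
  if (!is.null(residue_range)) {
    ca <- ca[ca$resno >= residue_range[1L] & ca$resno <= residue_range[2L], ,
             drop = FALSE]
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  structure_chain(cbind(ca$x, ca$y, ca$z), resno = ca$resno,
                  id = sub("\\.pdb$", "", basename(path)), chain = chain)
}

#' Write a C-alpha trace as a PDB file
#' @param chain a [structure_chain()].
#' @param path output path.
#' @export
write_structure_pdb <- function(chain, path) {
  n <- length(chain$resno)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(chain$xyz)),
                   resno = chain$resno,
                   chain = rep(chain$chain, n),
                   resid = rep("ALA", n),
                   elety = rep("CA", n))
  invisible(path)
}
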