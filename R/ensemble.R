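#' Conformational ensemble container
#'
#' A `conformational_ensemble` holds an aligned set of structural frames:
#' a numeric array of coordinates (frames x atoms x 3, in Angstrom) plus a
#' per-atom metadata table shared by all frames. It is the common substrate of
#' the residue-interaction-network and essential-dynamics stages.
#'
#' @param coords numeric array, frames x atoms x 3 (Angstrom).
#' @param atoms data.frame with one row per atom and columns `resid`
#'   (1-based residue index), `resname` (3-letter residue name), `chain`
#'   (chain identifier), `name` (atom name, e.g. "CA"), `elem` (element symbol).
#' @param region optional character vector of per-residue structural-region
#'   classes (helix, beta, top_loop, bottom_loop, short_beta), indexed by
#'   residue.
#'
#' @return An object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(coords, atoms, region = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  required <- c("resid", "resname", "chain", "name", "elem")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms)))
    stop("atoms must be a data.frame with columns ",
         paste(required, collapse = ", "))
  if (nrow(atoms) != dim(coords)[2])
    stop("atom table rows (", nrow(atoms), ") do not match coordinate atoms (",
         dim(coords)[2], ")")
  structure(
    list(coords = coords, atoms = atoms, region = region),
    class = "conformational_ensemble"
  )
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformational_ensemble> %d frames, %d atoms, %d residues\n",
    n_frames(x), n_atoms(x), length(unique(x$atoms$resid))
  ))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `conformational_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Number of atoms in an ensemble
#' @param ens a `conformational_ensemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(ens) dim(ens$coords)[2]

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param ens a `conformational_ensemble`.
#' @param i frame index.
#' @return numeric matrix, atoms x 3.
#' @export
frame_coords <- function(ens, i) {
  m <- ens$coords[i, , , drop = FALSE]
  dim(m) <- dim(ens$coords)[2:3]
  m
}

# frames x 3N matrix view (atom-major: x1,y1,z1,x2,...) used by PCA
flatten_frames <- function(ens) {
  nf <- n_frames(ens); na <- n_atoms(ens)
  out <- matrix(0, nf, 3L * na)
  for (d in 1:3) out[, seq(d, 3L * na, by = 3L)] <- ens$coords[, , d]
  out
}

unflatten_frames <- function(mat, template) {
  nf <- nrow(mat); na <- ncol(mat) / 3L
  coords <- array(0, c(nf, na, 3L))
  for (d in 1:3) coords[, , d] <- mat[, seq(d, 3L * na, by = 3L)]
  conformational_ensemble(coords, template$atoms, template$region)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Frames are written as MODEL/ENDMDL blocks of ATOM records with 1-based
#' residue numbering, so that the file round-trips through standard ensemble
#' readers.
#'
#' @param ens a `conformational_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  atoms <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ens, f)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(atoms)),
      ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
      atoms$resname, atoms$chain, atoms$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, atoms$elem
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a conformational ensemble
#'
#' Uses the bio3d reader; all models must share the same atom table.
#'
#' @param path PDB file path.
#' @return a `conformational_ensemble`.
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # frames x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  na <- ncol(xyz) / 3L
  coords <- array(0, c(nrow(xyz), na, 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3L * na, by = 3L)]
  atoms <- data.frame(
    resid = pdb$atom$resno,
    resname = pdb$atom$resid,
    chain = pdb$atom$chain,
    name = pdb$atom$elety,
    elem = trimws(pdb$atom$elesy),
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (any(!nzchar(atoms$elem)) || anyNA(atoms$elem))
    atoms$elem <- substr(trimws(atoms$name), 1, 1)
  conformational_ensemble(coords, atoms)
}
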