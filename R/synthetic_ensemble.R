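# Synthetic structural ensembles with planted essential modes.
#
# The generator emulates what a solvated MD run provides downstream: an
# ensemble whose fluctuations are Gaussian along a small number of orthogonal
# collective modes, plus isotropic thermal noise. Broader planted variances
# stand in for denaturant (8 M urea) conditions; no force field is involved.

# Run expr with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards, so every generator is a pure function of seed.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Residue palette cycled along the toy chain; the pseudo-sidechain atom is the
# residue's representative functional atom so that all three contact types
# (hydrophobic, electrostatic, vdw) occur in toy networks.
.toy_palette <- data.frame(
  resname = c("LEU", "LYS", "GLU", "ALA", "SER", "PHE", "ASP", "ARG", "VAL", "THR"),
  sc_name = c("CD1", "NZ",  "OE1", "CB",  "OG",  "CZ",  "OD1", "NH1", "CG1", "OG1"),
  sc_elem = c("C",   "N",   "O",   "C",   "O",   "C",   "O",   "N",   "C",   "O"),
  stringsAsFactors = FALSE
)

# Idealized alpha-helix trace: rise 1.5 A per residue, 100 degrees per turn,
# CA radius 2.3 A, pseudo-sidechain atom 1.5 A radially outward from CA.
helix_base <- function(n_residues, atoms_per_residue = 2L, chain = "A") {
  stopifnot(n_residues >= 1, atoms_per_residue %in% c(1L, 2L))
  theta <- (seq_len(n_residues) - 1L) * 100 * pi / 180
  z <- (seq_len(n_residues) - 1L) * 1.5
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), z)
  pal <- .toy_palette[((seq_len(n_residues) - 1L) %% nrow(.toy_palette)) + 1L, ]
  if (atoms_per_residue == 2L) {
    sc <- cbind(3.8 * cos(theta), 3.8 * sin(theta), z)
    xyz <- matrix(0, 2L * n_residues, 3L)
    xyz[seq(1, by = 2, length.out = n_residues), ] <- ca
    xyz[seq(2, by = 2, length.out = n_residues), ] <- sc
    atoms <- data.frame(
      resid = rep(seq_len(n_residues), each = 2L),
      resname = rep(pal$resname, each = 2L),
      chain = chain,
      name = as.vector(rbind("CA", pal$sc_name)),
      elem = as.vector(rbind("C", pal$sc_elem)),
      stringsAsFactors = FALSE
    )
  } else {
    xyz <- ca
    atoms <- data.frame(
      resid = seq_len(n_residues), resname = pal$resname, chain = chain,
      name = "CA", elem = "C", stringsAsFactors = FALSE
    )
  }
  list(xyz = xyz, atoms = atoms)
}

#' Specification of a synthetic ensemble
#'
#' Describes a toy conformational ensemble: an idealized helix base geometry
#' that fluctuates along a small set of planted orthonormal collective modes
#' with prescribed amplitudes, plus isotropic Gaussian noise and (optionally)
#' a random rigid-body jitter per frame.
#'
#' @param n_residues residue count of the toy chain.
#' @param atoms_per_residue 1 (C-alpha trace) or 2 (C-alpha plus one
#'   pseudo-sidechain atom); default 2.
#' @param n_frames frame count; must be at least 10x the number of modes.
#' @param mode_sds standard deviations (Angstrom) of the planted modes,
#'   strictly decreasing; one mode per entry. May be empty.
#' @param modes optional matrix (3N x k) of orthonormal mode vectors; if
#'   omitted, random orthonormal modes with rigid-body components projected
#'   out are drawn from the seed.
#' @param isotropic_noise_sd per-coordinate Gaussian noise sd (Angstrom).
#' @param rigid_jitter logical; add a random small rotation/translation per
#'   frame.
#' @param seed integer seed; the generator is a pure function of it.
#'
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_residues, n_frames, mode_sds = numeric(0),
                          atoms_per_residue = 2L, modes = NULL,
                          isotropic_noise_sd = 0.05, rigid_jitter = FALSE,
                          seed = 1L) {
  k <- length(mode_sds)
  if (k > 1 && any(diff(mode_sds) >= 0))
    stop("mode_sds must be strictly decreasing")
  if (k > 0 && any(mode_sds <= 0)) stop("mode_sds must be positive")
  if (n_frames < max(10L * k, k + 1L, 1L))
    stop("n_frames too small: need at least max(10 x modes, modes + 1) frames")
  if (isotropic_noise_sd < 0) stop("isotropic_noise_sd must be >= 0")
  structure(
    list(n_residues = as.integer(n_residues),
         atoms_per_residue = as.integer(atoms_per_residue),
         n_frames = as.integer(n_frames), mode_sds = mode_sds, modes = modes,
         isotropic_noise_sd = isotropic_noise_sd,
         rigid_jitter = isTRUE(rigid_jitter), seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

# Orthonormal basis of rigid-body motions (3 translations + 3 linearized
# rotations about the centroid) for a base geometry given as an n x 3 matrix.
rigid_body_basis <- function(xyz) {
  n <- nrow(xyz)
  centered <- sweep(xyz, 2, colMeans(xyz))
  basis <- matrix(0, 3L * n, 6L)
  for (d in 1:3) basis[seq(d, 3L * n, by = 3L), d] <- 1
  # infinitesimal rotation about axis e_d: dx = e_d x r
  ax <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (d in 1:3) {
    disp <- t(apply(centered, 1, function(r) pracma_cross(ax[[d]], r)))
    basis[, 3L + d] <- as.vector(t(disp))
  }
  qr.Q(qr(basis))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Random orthonormal internal modes: rigid-body subspace projected out so the
# planted motion is (to first order) invariant under superposition.
draw_internal_modes <- function(xyz, k) {
  n3 <- 3L * nrow(xyz)
  rb <- rigid_body_basis(xyz)
  raw <- matrix(stats::rnorm(n3 * k), n3, k)
  raw <- raw - rb %*% (t(rb) %*% raw)
  qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
}

random_rotation_matrix <- function(max_angle = 5 * pi / 180) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, -max_angle, max_angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Generate a toy conformational ensemble with planted modes
#'
#' Frame coordinates are `base + sum_i z_i * sd_i * mode_i + noise` with
#' `z_i` standard normal, on an idealized helix base geometry. The same seed
#' always yields identical coordinates.
#'
#' @param spec an [ensemble_spec()].
#' @return a `conformational_ensemble` with attribute `planted`, a list of the
#'   base geometry, mode matrix and mode sds actually used.
#' @export
make_toy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  base <- helix_base(spec$n_residues, spec$atoms_per_residue)
  n3 <- 3L * nrow(base$xyz)
  k <- length(spec$mode_sds)
  with_seed(spec$seed, {
    modes <- spec$modes
    if (is.null(modes)) {
      modes <- if (k > 0) draw_internal_modes(base$xyz, k) else
        matrix(0, n3, 0)
    }
    if (ncol(modes) != k) stop("modes must have one column per mode sd")
    if (k > 0) {
      gram <- crossprod(modes)
      if (max(abs(gram - diag(k))) > 1e-8)
        stop("planted modes must be orthonormal")
    }
    base_flat <- as.vector(t(base$xyz))          # x1,y1,z1,x2,...
    z <- matrix(stats::rnorm(spec$n_frames * k), spec$n_frames, k)
    disp <- if (k > 0) z %*% (t(modes) * spec$mode_sds) else
      matrix(0, spec$n_frames, n3)
    flat <- sweep(disp, 2, base_flat, "+")
    if (spec$isotropic_noise_sd > 0)
      flat <- flat + stats::rnorm(length(flat), sd = spec$isotropic_noise_sd)
    coords <- array(0, c(spec$n_frames, nrow(base$xyz), 3L))
    for (d in 1:3) coords[, , d] <- flat[, seq(d, n3, by = 3L)]
    if (spec$rigid_jitter) {
      for (f in seq_len(spec$n_frames)) {
        R <- random_rotation_matrix()
        tr <- stats::rnorm(3, sd = 1)
        coords[f, , ] <- sweep(coords[f, , ] %*% t(R), 2, tr, "+")
      }
    }
    ens <- conformational_ensemble(coords, base$atoms,
                                   region = toy_region_classes(spec$n_residues))
    attr(ens, "planted") <- list(base = base$xyz, modes = modes,
                                 sds = spec$mode_sds)
    ens
  })
}

#' Deterministic structural-region classes for the toy chain
#'
#' Assigns contiguous blocks of the chain to the five region classes used in
#' caspase anatomy (helix, beta, top_loop, bottom_loop, short_beta), in fixed
#' proportions, so that region-stratified summaries are exercised on toy data.
#'
#' @param n_residues residue count.
#' @return character vector of length `n_residues`.
#' @export
toy_region_classes <- function(n_residues) {
  classes <- c("helix", "beta", "top_loop", "bottom_loop", "short_beta")
  props <- c(0.3, 0.3, 0.15, 0.15, 0.1)
  sizes <- diff(round(c(0, cumsum(props)) * n_residues))
  rep(classes, times = sizes)[seq_len(n_residues)]
}

#' Generate a synthetic conservation table
#'
#' Grades are on the 1 (variable) to 9 (conserved) scale. Designated hub
#' positions receive grades 8 or 9; all other positions are uniform over 1-9.
#'
#' @param n_positions number of alignment positions.
#' @param hub_positions integer positions forced to high conservation.
#' @param seed integer seed.
#' @return data.frame with columns `position`, `grade`.
#' @export
make_conservation_table <- function(n_positions, hub_positions = integer(0),
                                    seed = 1L) {
  if (n_positions == 0)
    return(data.frame(position = integer(0), grade = integer(0)))
  hub_positions <- as.integer(hub_positions)
  if (length(hub_positions) &&
      (min(hub_positions) < 1 || max(hub_positions) > n_positions))
    stop("hub_positions out of range")
  with_seed(seed, {
    grade <- sample.int(9L, n_positions, replace = TRUE)
    if (length(hub_positions))
      grade[hub_positions] <- sample(8:9, length(hub_positions), replace = TRUE)
    data.frame(position = seq_len(n_positions), grade = grade)
  })
}

#' Write a conservation table as TSV
#' @param tab data.frame from [make_conservation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a conservation TSV (position, grade)
#' @param path input path.
#' @return data.frame with columns `position`, `grade`.
#' @export
read_conservation_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write per-residue region annotation as TSV
#' @param region character vector of region classes, indexed by residue.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(region, path) {
  utils::write.table(
    data.frame(position = seq_along(region), region = region),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a region annotation TSV
#' @param path input path.
#' @return character vector of region classes indexed by position.
#' @export
read_region_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- character(max(tab$position))
  out[tab$position] <- tab$region
  out
}
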