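# Essential dynamics: least-squares superposition, coordinate-covariance PCA,
# projections onto the leading principal components, and the
# G = -RT ln(P/Pmax) free-energy landscape with metastable-basin extraction.

#' Select atoms of an ensemble
#' @param ens a `conformational_ensemble`.
#' @param selection `"CA"` (alpha carbons), `"heavy"` (non-hydrogen, the
#'   "all protein atoms" of an all-heavy-atom model), `"all"`, or an integer
#'   vector of atom indices.
#' @return integer atom indices.
#' @export
select_atoms <- function(ens, selection = "heavy") {
  if (is.numeric(selection)) return(as.integer(selection))
  switch(selection,
    CA = which(ens$atoms$name == "CA"),
    heavy = which(toupper(ens$atoms$elem) != "H"),
    all = seq_len(n_atoms(ens)),
    stop("unknown selection '", selection, "'")
  )
}

# Kabsch: optimal rotation R and translation mapping mobile onto ref
# (both n x 3, already restricted to the fit selection).
kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  # right-multiplying rotation: mobile %*% R ~ ref, with a proper rotation
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, center_mobile = cm, center_ref = cr)
}

#' Superpose every frame onto a reference frame
#'
#' Least-squares (Kabsch) rotation and translation of each frame onto the
#' reference over the fit selection; the transform is applied to all atoms.
#'
#' @param ens a `conformational_ensemble`.
#' @param reference reference frame index; default 1.
#' @param selection fit selection (see [select_atoms()]); default `"CA"`.
#' @return list with `ensemble` (superposed) and `rmsd` (per-frame RMSD over
#'   the fit selection, Angstrom).
#' @export
superpose <- function(ens, reference = 1L, selection = "CA") {
  sel <- select_atoms(ens, selection)
  if (length(sel) < 3) stop("fit selection needs at least 3 atoms")
  ref <- frame_coords(ens, reference)[sel, , drop = FALSE]
  if (qr(sweep(ref, 2, colMeans(ref)))$rank < 2)
    stop("degenerate (collinear) fit selection")
  coords <- ens$coords
  rmsd <- numeric(n_frames(ens))
  for (f in seq_len(n_frames(ens))) {
    xyz <- frame_coords(ens, f)
    k <- kabsch(xyz[sel, , drop = FALSE], ref)
    moved <- sweep(xyz, 2, k$center_mobile) %*% k$R
    moved <- sweep(moved, 2, k$center_ref, "+")
    coords[f, , ] <- moved
    rmsd[f] <- sqrt(mean(rowSums((moved[sel, , drop = FALSE] - ref)^2)))
  }
  list(ensemble = conformational_ensemble(coords, ens$atoms, ens$region),
       rmsd = rmsd)
}

#' Coordinate-covariance PCA of an ensemble
#'
#' Eigendecomposition of the covariance of the mean-centered selected
#' coordinates. Eigenvalues (Angstrom^2) are sorted descending and sum to the
#' covariance trace; eigenvector signs are fixed by making each mode's
#' largest-magnitude component positive. Optional mass weighting multiplies
#' each coordinate by sqrt(m) before the covariance.
#'
#' @param ens a (superposed) `conformational_ensemble`.
#' @param selection see [select_atoms()]; default `"heavy"`.
#' @param mass_weighted logical; default FALSE.
#' @return a `pca_result`: `values` (eigenvalues), `vectors` (3N x k
#'   orthonormal), `mean` (3N), `selection` (atom indices), `masses`.
#' @export
pca <- function(ens, selection = "heavy", mass_weighted = FALSE) {
  if (n_frames(ens) < 2) stop("PCA needs at least 2 frames")
  sel <- select_atoms(ens, selection)
  flat <- flatten_frames(ens)
  cols <- as.vector(rbind(3L * sel - 2L, 3L * sel - 1L, 3L * sel))
  X <- flat[, cols, drop = FALSE]
  masses <- rep(1, length(sel))
  if (mass_weighted) {
    mass_of <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
    masses <- mass_of[toupper(ens$atoms$elem[sel])]
    masses[is.na(masses)] <- 12.011
    X <- sweep(X, 2, rep(sqrt(masses), each = 3), "*")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(
    list(values = vals, vectors = vecs, mean = mu, selection = sel,
         mass_weighted = mass_weighted, masses = masses,
         trace = sum(diag(cv))),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d modes over %d atoms; leading eigenvalues (A^2): %s\n",
    length(x$values), length(x$selection),
    paste(signif(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Project frames onto principal components
#'
#' @param ens the ensemble the PCA was computed on (same atoms).
#' @param pca_res a [pca()] result.
#' @param k number of components; default 2.
#' @return n_frames x k matrix of projections (columns PC1, PC2, ...).
#' @export
project <- function(ens, pca_res, k = 2L) {
  stopifnot(inherits(pca_res, "pca_result"), k <= ncol(pca_res$vectors))
  if (max(pca_res$selection) > n_atoms(ens))
    stop("ensemble does not match the PCA's atom selection")
  flat <- flatten_frames(ens)
  sel <- pca_res$selection
  cols <- as.vector(rbind(3L * sel - 2L, 3L * sel - 1L, 3L * sel))
  X <- flat[, cols, drop = FALSE]
  if (pca_res$mass_weighted)
    X <- sweep(X, 2, rep(sqrt(pca_res$masses), each = 3), "*")
  proj <- sweep(X, 2, pca_res$mean) %*% pca_res$vectors[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  proj
}

#' Free-energy landscape over PC1/PC2
#'
#' 2D histogram of the projections; each occupied bin gets
#' G = -RT ln(count/max_count) in kcal/mol, so the most populated bin sits at
#' G = 0 and empty bins are masked (NA) rather than assigned a ceiling.
#'
#' @param projections n x >=2 matrix from [project()].
#' @param bins bins per axis; default 32.
#' @param temperature Kelvin; default 298.15 (RT = 0.5925 kcal/mol).
#' @return a `free_energy_landscape`: `G` (bins x bins, NA where empty),
#'   `counts`, `xedges`, `yedges`, `temperature`, `n_points`.
#' @export
build_fel <- function(projections, bins = 32L, temperature = 298.15) {
  stopifnot(nrow(projections) >= 1)
  if (bins < 2) stop("need at least 2 bins per axis")
  x <- projections[, 1]; y <- projections[, 2]
  pad_edges <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1L)
  }
  xe <- pad_edges(x); ye <- pad_edges(y)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (n in seq_along(ix)) counts[ix[n], iy[n]] <- counts[ix[n], iy[n]] + 1L
  RT <- rt_kcal(temperature)
  G <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  G[occ] <- -RT * log(counts[occ] / max(counts))
  structure(
    list(G = G, counts = counts, xedges = xe, yedges = ye,
         temperature = temperature, n_points = length(x)),
    class = "free_energy_landscape"
  )
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf(
    "<free_energy_landscape> %dx%d bins, %d occupied, %d points, G max %.2f kcal/mol\n",
    nrow(x$G), ncol(x$G), sum(!is.na(x$G)), x$n_points, max(x$G, na.rm = TRUE)))
  invisible(x)
}

#' Extract metastable basins from a free-energy landscape
#'
#' Local minima of the occupied 8-neighborhood grid are found by a
#' persistence sweep: occupied bins are processed in order of increasing G
#' (ties by lowest row, then column, which also collapses flat plateaus to a
#' single minimum), tracking connected components with union-find. When two
#' components meet, the shallower minimum's persistence is the barrier height
#' at which it merges into the deeper one. A minimum counts as a metastable
#' basin when its persistence is at least `min_prominence` and it lies at
#' least `min_prominence` below the shallowest occupied bin (this suppresses
#' spurious minima from sparsely sampled single-count rim bins). Surviving
#' minima closer than `min_separation` bins (Chebyshev distance) are merged
#' keeping the deeper; basins are returned ordered by depth (ascending G).
#'
#' @param fel a [build_fel()] result.
#' @param min_separation minimum bin separation between basins; default 2.
#' @param min_prominence minimum barrier depth in kcal/mol; default 1.0
#'   (about 1.7 kT at 298.15 K — shallower dips are sampling noise, not
#'   metastable states).
#' @return data.frame with `basin`, `row`, `col`, `G`, `persistence`, `pc1`,
#'   `pc2` (bin centers).
#' @export
find_basins <- function(fel, min_separation = 2L, min_prominence = NULL) {
  G <- fel$G
  if (all(is.na(G))) stop("fully masked landscape")
  if (is.null(min_prominence)) min_prominence <- 1.0
  nr <- nrow(G); nc <- ncol(G)
  occ <- which(!is.na(G), arr.ind = TRUE)
  g <- G[occ]
  ord <- order(g, occ[, 1], occ[, 2])
  occ <- occ[ord, , drop = FALSE]; g <- g[ord]
  pos <- matrix(0L, nr, nc)             # processing rank of each occupied bin
  pos[occ] <- seq_along(g)

  parent <- seq_along(g)
  comp_min <- seq_along(g)              # minimum (rank index) of each component
  persistence <- rep(NA_real_, length(g))
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  for (q in seq_along(g)) {
    r <- occ[q, 1]; cc <- occ[q, 2]
    nbr_roots <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
        pq <- pos[rr, ccc]
        if (pq > 0 && pq < q) nbr_roots <- c(nbr_roots, find_root(pq))
      }
    }
    nbr_roots <- unique(nbr_roots)
    if (length(nbr_roots) == 0) next    # q is a new local minimum
    # attach q to the deepest neighboring component; merge the rest into it
    depths <- g[comp_min[nbr_roots]]
    main <- nbr_roots[which.min(depths)]
    parent[q] <- main
    for (rt in setdiff(nbr_roots, main)) {
      persistence[comp_min[rt]] <- g[q] - g[comp_min[rt]]
      parent[rt] <- main
    }
  }
  # a bin was born as a minimum iff it had no earlier-processed neighbor
  born_min <- vapply(seq_along(g), function(q) {
    r <- occ[q, 1]; cc <- occ[q, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
        pq <- pos[rr, ccc]
        if (pq > 0 && pq < q) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  minima <- which(born_min)
  pers <- persistence[minima]
  pers[is.na(pers)] <- Inf              # never merged (incl. global minimum)
  g_ceiling <- max(g) - min_prominence
  keep <- (pers >= min_prominence) & (g[minima] <= g_ceiling | g[minima] == min(g))
  minima <- minima[keep]; pers <- pers[keep]
  ordm <- order(g[minima], occ[minima, 1], occ[minima, 2])
  minima <- minima[ordm]; pers <- pers[ordm]
  # merge close minima, keeping the deeper (already sorted by depth)
  sel <- logical(length(minima))
  for (q in seq_along(minima)) {
    if (!any(sel)) { sel[q] <- TRUE; next }
    kept <- minima[sel]
    dch <- pmax(abs(occ[kept, 1] - occ[minima[q], 1]),
                abs(occ[kept, 2] - occ[minima[q], 2]))
    if (all(dch >= min_separation)) sel[q] <- TRUE
  }
  minima <- minima[sel]; pers <- pers[sel]
  xc <- (fel$xedges[-1] + fel$xedges[-length(fel$xedges)]) / 2
  yc <- (fel$yedges[-1] + fel$yedges[-length(fel$yedges)]) / 2
  data.frame(basin = seq_along(minima),
             row = occ[minima, 1], col = occ[minima, 2],
             G = g[minima], persistence = pers,
             pc1 = xc[occ[minima, 1]], pc2 = yc[occ[minima, 2]])
}

#' Representative frame of a basin
#'
#' The frame whose (PC1, PC2) projection lies nearest (Euclidean) to the
#' basin's minimum-bin center; ties resolved to the lowest frame index.
#'
#' @param basin one row of [find_basins()] output.
#' @param projections the projection matrix the landscape was built from.
#' @return integer frame index.
#' @export
representative_frame <- function(basin, projections) {
  d2 <- (projections[, 1] - basin$pc1)^2 + (projections[, 2] - basin$pc2)^2
  which.min(d2)   # which.min returns the first (lowest) index on ties
}

#' Breadth of a free-energy landscape
#'
#' @param fel a [build_fel()] result.
#' @return list with `occupied_bins`, `bin_area` (PC units^2), `area`
#'   (occupied bins x bin area) and `pc1_span` (extent of occupied columns
#'   along PC1).
#' @export
landscape_breadth <- function(fel) {
  occ <- which(fel$counts > 0, arr.ind = TRUE)
  dx <- diff(fel$xedges[1:2]); dy <- diff(fel$yedges[1:2])
  rows <- range(occ[, 1])
  list(
    occupied_bins = nrow(occ),
    bin_area = dx * dy,
    area = nrow(occ) * dx * dy,
    pc1_span = fel$xedges[rows[2] + 1L] - fel$xedges[rows[1]]
  )
}
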