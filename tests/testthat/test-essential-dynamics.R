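make_ens <- function(n_res = 12, n_frames = 200, sds = c(2, 1), noise = 0.02,
                     seed = 1, ...) {
  make_toy_ensemble(ensemble_spec(n_residues = n_res, n_frames = n_frames,
                                  mode_sds = sds, isotropic_noise_sd = noise,
                                  seed = seed, ...))
}

test_that("superposition removes rigid-body motion exactly", {
  ens <- make_ens(n_frames = 5, sds = numeric(0), noise = 0)
  # identical frames: identity transform, zero RMSD
  sup <- superpose(ens)
  expect_equal(sup$rmsd, rep(0, 5), tolerance = 1e-10)
  expect_equal(sup$ensemble$coords, ens$coords, tolerance = 1e-10)
  # translation by (5, 0, 0)
  shifted <- ens
  shifted$coords[2, , 1] <- shifted$coords[2, , 1] + 5
  sup <- superpose(shifted)
  expect_lt(sup$rmsd[2], 1e-10)
  # a known 30-degree rotation about z is undone
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rotated <- ens
  rotated$coords[3, , ] <- ens$coords[3, , ] %*% t(R)
  sup <- superpose(rotated)
  expect_lt(sup$rmsd[3], 1e-6)
  expect_equal(sup$ensemble$coords[3, , ], ens$coords[3, , ],
               tolerance = 1e-6)
})

test_that("degenerate fit selections are rejected", {
  xyz <- cbind(0:4, 0, 0)  # collinear
  ens <- ensemble_from_atoms(xyz, resid = 1:5, resname = "GLY",
                             name = "CA", elem = "C", n_copies = 2)
  expect_error(superpose(ens, selection = "CA"), "collinear")
  expect_error(superpose(ens, selection = 1:2), "3 atoms")
})

test_that("PCA satisfies its spectral invariants on random ensembles", {
  for (seed in 1:3) {
    ens <- make_ens(seed = seed)
    p <- pca(ens, "heavy")
    expect_true(all(diff(p$values) <= 1e-12))
    expect_true(all(p$values >= 0))
    expect_equal(crossprod(p$vectors), diag(length(p$values)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(p$values), p$trace, tolerance = 1e-8)
  }
})

test_that("a single noiseless mode yields a rank-one spectrum with its sample variance", {
  ens <- make_ens(n_frames = 300, sds = 2, noise = 0)
  p <- pca(ens, "heavy")
  pl <- attr(ens, "planted")
  flat <- caspensemble:::flatten_frames(ens)
  z <- sweep(flat, 2, as.vector(t(pl$base))) %*% pl$modes[, 1]
  expect_equal(p$values[1], var(as.vector(z)), tolerance = 1e-8)
  expect_lt(p$values[2], 1e-10)
  expect_gt(abs(sum(p$vectors[, 1] * pl$modes[, 1])), 1 - 1e-8)
})

test_that("planted two-mode variances and directions are recovered", {
  ens <- make_ens(n_res = 20, n_frames = 1000, sds = c(2, 1), noise = 0.05,
                  seed = 42)
  p <- pca(ens, "heavy")
  pl <- attr(ens, "planted")
  expect_equal(p$values[1] / p$values[2], 4, tolerance = 0.15)
  expect_gt(abs(sum(p$vectors[, 1] * pl$modes[, 1])), 0.98)
  expect_gt(abs(sum(p$vectors[, 2] * pl$modes[, 2])), 0.98)
})

test_that("duplicating every frame leaves eigenvalues essentially unchanged", {
  ens <- make_ens(n_frames = 100)
  dup <- conformational_ensemble(
    ens$coords[rep(seq_len(100), each = 2), , ], ens$atoms)
  # duplication only changes the n-1 denominator
  expect_equal(pca(dup, "heavy")$values * 199 / 200,
               pca(ens, "heavy")$values * 99 / 100, tolerance = 1e-10)
})

test_that("projections are centered, recover planted displacements, and carry the eigenvalues", {
  ens <- make_ens(n_frames = 400, seed = 3, noise = 0)
  p <- pca(ens, "heavy")
  proj <- project(ens, p, k = 3)
  expect_lt(max(abs(colMeans(proj))), 1e-8)
  expect_equal(apply(proj, 2, var), p$values[1:3], tolerance = 1e-6,
               ignore_attr = TRUE)
  # a frame displaced from the mean by 3 * PC1 projects to (3, 0)
  synth <- ens
  synth$coords[1, , ] <- matrix(p$mean + 3 * p$vectors[, 1],
                                ncol = 3, byrow = TRUE)
  pr <- project(synth, p)[1, ]
  expect_equal(unname(pr), c(3, 0), tolerance = 1e-8)
  small <- make_ens(n_res = 3, n_frames = 40)
  expect_error(project(small, p), "match")
})

test_that("rigid-body jitter changes nothing after superposition", {
  spec_still <- ensemble_spec(n_residues = 12, n_frames = 150,
                              mode_sds = c(2, 1), isotropic_noise_sd = 0.02,
                              seed = 8)
  spec_jit <- ensemble_spec(n_residues = 12, n_frames = 150,
                            mode_sds = c(2, 1), isotropic_noise_sd = 0.02,
                            rigid_jitter = TRUE, seed = 8)
  still <- make_toy_ensemble(spec_still)
  jit <- make_toy_ensemble(spec_jit)
  # same seed, so the jittered ensemble is the still one under per-frame
  # rigid motions; superposition must remove them entirely
  sup_still <- superpose(still)$ensemble
  sup_jit <- superpose(jit)$ensemble
  # the two superposed ensembles coincide up to one global rigid transform
  # (the reference frame's jitter), so their internal geometry is identical
  k <- caspensemble:::kabsch(frame_coords(sup_jit, 1), frame_coords(sup_still, 1))
  for (f in c(1, 75, 150)) {
    aligned <- sweep(sweep(frame_coords(sup_jit, f), 2, k$center_mobile) %*% k$R,
                     2, k$center_ref, "+")
    expect_equal(aligned, frame_coords(sup_still, f), tolerance = 1e-8)
  }
  p_still <- pca(sup_still, "heavy")
  p_jit <- pca(sup_jit, "heavy")
  expect_equal(p_jit$values, p_still$values, tolerance = 1e-8)
  pr_s <- project(sup_still, p_still)
  pr_j <- project(sup_jit, p_jit)
  for (kk in 1:2)
    expect_gt(abs(cor(pr_s[, kk], pr_j[, kk])), 0.999999)
  fel_s <- build_fel(pr_s); fel_j <- build_fel(pr_j)
  expect_equal(sort(find_basins(fel_j)$G), sort(find_basins(fel_s)$G),
               tolerance = 1e-8)
  expect_equal(landscape_breadth(fel_j)$area, landscape_breadth(fel_s)$area,
               tolerance = 1e-8)
})

test_that("the landscape is a -RT log histogram with its stated invariants", {
  RT <- 1.9872e-3 * 298.15
  # all points in one bin
  one <- build_fel(cbind(rep(0.3, 10), rep(-0.2, 10)), bins = 8)
  expect_equal(sum(!is.na(one$G)), 1)
  expect_equal(min(one$G, na.rm = TRUE), 0)
  expect_equal(sum(one$counts), 10)
  # two occupied bins with counts 75 / 25 -> dG = RT ln 3
  proj <- cbind(c(rep(-1, 75), rep(1, 25)), 0)
  two <- build_fel(proj, bins = 2)
  expect_equal(sort(as.vector(two$G[!is.na(two$G)])),
               c(0, RT * log(3)), tolerance = 1e-12)
  expect_equal(RT * log(3), 0.651, tolerance = 1e-3)
  # normalization: sum over occupied bins of exp(-G/RT) * Pmax == 1
  set.seed(9)
  fel <- build_fel(cbind(rnorm(5000), rnorm(5000)))
  pmax <- max(fel$counts) / fel$n_points
  expect_equal(sum(exp(-fel$G[!is.na(fel$G)] / RT)) * pmax, 1,
               tolerance = 1e-12)
  expect_true(all(fel$G[!is.na(fel$G)] >= 0))
  expect_equal(sum(fel$counts), 5000)
  expect_error(build_fel(proj, bins = 1), "bins")
})

test_that("an isotropic Gaussian landscape is quadratic in radius", {
  set.seed(123)
  proj <- cbind(rnorm(1e4), rnorm(1e4))
  fel <- build_fel(proj)
  tab <- caspensemble:::fel_as_table(fel)
  tab <- tab[tab$count >= 5, ]  # bins with enough counts for a stable G
  fit <- lm(G ~ I(pc1^2 + pc2^2), data = tab)
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_gt(coef(fit)[2], 0)
})

test_that("basin extraction finds one basin for unimodal and two for bimodal samples", {
  set.seed(21)
  uni <- build_fel(cbind(rnorm(1e4), rnorm(1e4)))
  b1 <- find_basins(uni)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$G, 0)
  bi <- build_fel(rbind(cbind(rnorm(1000, -4), rnorm(1000)),
                        cbind(rnorm(1000, 4), rnorm(1000))))
  b2 <- find_basins(bi)
  expect_equal(nrow(b2), 2)
  expect_true(all(b2$G < 0.5))
  # flat landscape: single basin at the lowest (row, col)
  grid_pts <- as.matrix(expand.grid(seq(0.05, 0.95, length.out = 8),
                                    seq(0.05, 0.95, length.out = 8)))
  flat <- build_fel(grid_pts, bins = 8)
  bf <- find_basins(flat)
  expect_equal(nrow(bf), 1)
  expect_equal(c(bf$row, bf$col), c(1, 1))
  masked <- uni; masked$G[] <- NA
  expect_error(find_basins(masked), "masked")
})

test_that("representative frames are the nearest projections to the basin center", {
  set.seed(5)
  proj <- cbind(rnorm(500), rnorm(500))
  fel <- build_fel(proj)
  basins <- find_basins(fel)
  for (b in seq_len(nrow(basins))) {
    got <- representative_frame(basins[b, ], proj)
    d2 <- (proj[, 1] - basins$pc1[b])^2 + (proj[, 2] - basins$pc2[b])^2
    expect_equal(got, which.min(d2))  # brute-force scan
  }
  # a frame placed exactly at the basin center wins
  proj2 <- rbind(proj, c(basins$pc1[1], basins$pc2[1]))
  expect_equal(representative_frame(basins[1, ], proj2), 501)
  one <- build_fel(matrix(c(0, 0), 1, 2))
  expect_equal(representative_frame(find_basins(one)[1, ],
                                    matrix(c(0, 0), 1, 2)), 1)
})

test_that("landscape breadth grows with planted-mode amplitude and ignores frame order", {
  wins <- 0
  for (seed in 1:10) {
    narrow <- make_ens(n_res = 10, n_frames = 150, sds = c(2, 1), seed = seed)
    wide <- make_ens(n_res = 10, n_frames = 150, sds = c(4, 2), seed = seed)
    br_n <- landscape_breadth(build_fel(project(narrow, pca(narrow, "heavy"))))
    br_w <- landscape_breadth(build_fel(project(wide, pca(wide, "heavy"))))
    if (br_w$area > br_n$area) wins <- wins + 1
  }
  expect_gt(wins, 5)
  # permutation invariance
  set.seed(3)
  proj <- cbind(rnorm(400), rnorm(400))
  b0 <- landscape_breadth(build_fel(proj))
  b1 <- landscape_breadth(build_fel(proj[sample(400), ]))
  expect_equal(b0, b1)
  single <- landscape_breadth(build_fel(matrix(c(0, 0), 1, 2)))
  expect_equal(single$occupied_bins, 1)
})
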