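# Two-residue fixture: a Lys sidechain nitrogen near a Glu sidechain oxygen,
# with backbone carbons, residues 1 and 3 (not chain-adjacent).
salt_bridge_fixture <- function(sep = 3.5) {
  ensemble_from_atoms(
    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0),          # LYS CA, NZ
                c(10, 10, 10), c(1.5 + sep, 0, 0)), # GLU CA, OE1
    resid = c(1, 1, 3, 3),
    resname = c("LYS", "LYS", "GLU", "GLU"),
    name = c("CA", "NZ", "CA", "OE1"),
    elem = c("C", "N", "C", "O")
  )
}

test_that("the distance cutoff is a strict boundary", {
  near <- detect_contacts(frame_coords(salt_bridge_fixture(3.99), 1),
                          salt_bridge_fixture()$atoms, cutoff = 4.0)
  expect_equal(nrow(near), 1)
  far <- detect_contacts(frame_coords(salt_bridge_fixture(4.01), 1),
                         salt_bridge_fixture()$atoms, cutoff = 4.0)
  expect_equal(nrow(far), 0)
})

test_that("contacts are typed by the charge and apolarity rules", {
  ens <- salt_bridge_fixture(3.5)
  ct <- detect_contacts(frame_coords(ens, 1), ens$atoms, cutoff = 4.0)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$type, "electrostatic")
  expect_equal(c(ct$res_i, ct$res_j), c(1, 3))
  # two leucine sidechain carbons -> hydrophobic
  leu <- ensemble_from_atoms(
    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(9, 9, 9), c(4.5, 0, 0)),
    resid = c(1, 1, 3, 3), resname = "LEU",
    name = c("CA", "CD1", "CA", "CD1"), elem = "C"
  )
  ct <- detect_contacts(frame_coords(leu, 1), leu$atoms, cutoff = 4.0)
  expect_equal(ct$type, "hydrophobic")
  # a serine oxygen near a leucine carbon is plain van der Waals
  mixed <- ensemble_from_atoms(
    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(9, 9, 9), c(4.5, 0, 0)),
    resid = c(1, 1, 3, 3), resname = c("SER", "SER", "LEU", "LEU"),
    name = c("CA", "OG", "CA", "CD1"), elem = c("C", "O", "C", "C")
  )
  ct <- detect_contacts(frame_coords(mixed, 1), mixed$atoms, cutoff = 4.0)
  expect_equal(ct$type, "vdw")
})

test_that("chain-adjacent residues never form contacts; cross-chain pairs always may", {
  adj <- ensemble_from_atoms(
    xyz = rbind(c(0, 0, 0), c(2, 0, 0)),
    resid = c(1, 2), resname = "ALA", name = c("CB", "CB"), elem = "C"
  )
  expect_equal(nrow(detect_contacts(frame_coords(adj, 1), adj$atoms, 4)), 0)
  cross <- ensemble_from_atoms(
    xyz = rbind(c(0, 0, 0), c(2, 0, 0)),
    resid = c(1, 1), resname = "ALA", name = c("CB", "CB"), elem = "C",
    chain = c("A", "B")
  )
  expect_equal(nrow(detect_contacts(frame_coords(cross, 1), cross$atoms, 4)), 1)
  # hydrogens are ignored; missing metadata is rejected
  h <- ensemble_from_atoms(
    xyz = rbind(c(0, 0, 0), c(2, 0, 0)),
    resid = c(1, 3), resname = "ALA", name = c("HB1", "CB"), elem = c("H", "C")
  )
  expect_equal(nrow(detect_contacts(frame_coords(h, 1), h$atoms, 4)), 0)
  bad <- h; bad$atoms$elem[2] <- ""
  expect_error(detect_contacts(frame_coords(bad, 1), bad$atoms, 4), "element")
})

test_that("edge weights average per-frame contact counts and track occupancy", {
  # residues 1 and 3, two atoms each; frame 1 has 3 atom contacts, frame 2 has 1
  atoms <- data.frame(
    resid = c(1, 1, 3, 3), resname = "ALA", chain = "A",
    name = c("CB", "CB2", "CB", "CB2"), elem = "C", stringsAsFactors = FALSE
  )
  # frame 1 pairs: (a1,a3)=2, (a2,a3)=1, (a2,a4)=3.5 -> 3 contacts
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(4.5, 0, 0))
  # frame 2: only (a1,a3)=3.5 -> 1 contact
  f2 <- rbind(c(0, 0, 0), c(0, 0, 30), c(3.5, 0, 0), c(50, 0, 0))
  coords <- array(0, c(2, 4, 3)); coords[1, , ] <- f1; coords[2, , ] <- f2
  ens <- conformational_ensemble(coords, atoms)
  rin <- build_rin(ens, cutoff = 4)
  pooled <- caspensemble:::pooled_edges(rin)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$mean_weight, 2.0)   # (3 + 1) / 2
  expect_equal(rin$edges$occupancy, 1.0)
  # contact in 1 of 4 frames with 2 atom pairs -> mean 0.5, occupancy 0.25
  coords4 <- array(0, c(4, 4, 3))
  coords4[1, , ] <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  for (f in 2:4) coords4[f, , ] <- rbind(c(0, 0, 0), c(1, 0, 0),
                                         c(50, 0, 0), c(60, 0, 0))
  ens4 <- conformational_ensemble(coords4, atoms)
  rin4 <- build_rin(ens4, cutoff = 4)
  # frame 1: atoms (1,3),(1,4),(2,3),(2,4) at distances 2,3,1,2 -> 4 contacts
  expect_equal(rin4$edges$mean_weight, 1.0)
  expect_equal(rin4$edges$occupancy, 0.25)
  # single frame: mean weight equals that frame's count
  rin1 <- build_rin(conformational_ensemble(coords4[1, , , drop = FALSE], atoms),
                    cutoff = 4)
  expect_equal(rin1$edges$mean_weight, 4)
})

test_that("degree centrality sums incident mean weights", {
  star <- rin_from_edges(4, i = c(1, 1, 1), j = c(2, 3, 4), w = c(2, 3, 5))
  dc <- degree_centrality(star)
  expect_equal(unname(dc), c(10, 2, 3, 5))
  expect_equal(unname(degree_centrality(star, weighted = FALSE)),
               c(3, 1, 1, 1))
  tri <- rin_from_edges(3, i = c(1, 1, 2), j = c(2, 3, 3), w = c(1, 1, 1))
  expect_equal(unname(degree_centrality(tri)), c(2, 2, 2))
  empty <- rin_from_edges(3, integer(0), integer(0), numeric(0))
  expect_equal(unname(degree_centrality(empty)), c(0, 0, 0))
})

test_that("degree conservation holds exactly on generated networks", {
  for (seed in 1:5) {
    spec <- ensemble_spec(n_residues = 15, n_frames = 10, mode_sds = 1,
                          seed = seed)
    rin <- build_rin(make_toy_ensemble(spec), cutoff = 6)
    expect_equal(sum(degree_centrality(rin)), 2 * sum(rin$edges$mean_weight))
  }
})

test_that("betweenness matches hand-computable graphs", {
  path3 <- rin_from_edges(3, i = c(1, 2), j = c(2, 3), w = c(1, 1))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  star5 <- rin_from_edges(5, i = rep(1, 4), j = 2:5, w = rep(1, 4))
  expect_equal(unname(betweenness_centrality(star5))[1], 6)  # choose(4,2)
  expect_error(betweenness_centrality(
    rin_from_edges(3, i = 1, j = 3, w = -2)), "positive")
})

test_that("betweenness equals the exhaustive path-enumeration oracle on random graphs", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample(4:9, 1)
    rin <- random_rin(n)
    got <- betweenness_centrality(rin)
    edges <- caspensemble:::pooled_edges(rin)
    edges$len <- 1 / edges$mean_weight
    expect_equal(unname(got), bc_exhaustive(n, edges), tolerance = 1e-9)
  }
})

test_that("adding an edge never decreases degree and relabeling permutes outputs", {
  set.seed(11)
  rin <- random_rin(8)
  dc0 <- degree_centrality(rin)
  extra <- rin
  extra$edges <- rbind(extra$edges,
                       data.frame(i = 2, j = 7, type = "vdw",
                                  mean_weight = 1.5, occupancy = 1))
  dc1 <- degree_centrality(extra)
  expect_true(all(dc1 >= dc0))
  expect_equal(dc1[c(2, 7)], dc0[c(2, 7)] + 1.5, ignore_attr = TRUE)
  # permutation invariance
  perm <- sample(8)
  relabeled <- rin
  relabeled$edges$i <- perm[rin$edges$i]
  relabeled$edges$j <- perm[rin$edges$j]
  swap <- relabeled$edges$i > relabeled$edges$j
  tmp <- relabeled$edges$i[swap]
  relabeled$edges$i[swap] <- relabeled$edges$j[swap]
  relabeled$edges$j[swap] <- tmp
  expect_equal(unname(degree_centrality(relabeled)[perm]),
               unname(degree_centrality(rin)))
  expect_equal(unname(betweenness_centrality(relabeled)[perm]),
               unname(betweenness_centrality(rin)), tolerance = 1e-9)
})

test_that("conservation grades bin as high / intermediate / variable", {
  expect_equal(bin_conservation(c(9, 8)), c("high", "high"))
  expect_equal(bin_conservation(c(7, 6)), c("intermediate", "intermediate"))
  expect_equal(bin_conservation(c(5, 3, 1)), rep("variable", 3))
  expect_error(bin_conservation(0), "1..9")
  expect_error(bin_conservation(10), "1..9")
})

test_that("hub classification applies the DC/BC quadrant rule", {
  rec <- data.frame(residue = 1:4,
                    DC = c(25, 25, 10, 30),
                    BC = c(1500, 10, 5000, 999))
  out <- classify_hubs(rec)
  expect_equal(out$hubs, 1)
  expect_equal(sum(out$quadrant_counts), 4)
  expect_equal(unname(out$quadrant_counts["high", "high"]), 1)
  empty <- classify_hubs(rec[0, ])
  expect_length(empty$hubs, 0)
})

test_that("a persistently packed residue is flagged as a hub at fixture-scaled thresholds", {
  # residue 1 surrounded by 14 residues within contact range, held over 5 frames
  set.seed(2)
  n_leaf <- 14
  dirs <- matrix(rnorm(3 * n_leaf), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- rbind(c(0, 0, 0), dirs * 3.5)
  ens <- ensemble_from_atoms(
    xyz, resid = c(1, seq(3, by = 2, length.out = n_leaf)),
    resname = "ALA", name = "CB", elem = "C", n_copies = 5
  )
  rin <- build_rin(ens, cutoff = 4)
  met <- residue_metrics(rin)
  met <- met[met$DC > 0 | met$BC > 0, ]
  out <- classify_hubs(met, dc_threshold = 10, bc_threshold = 5)
  expect_true(1 %in% out$hubs)
})

test_that("metric distributions partition records and match hand medians", {
  rec <- data.frame(residue = 1:6,
                    DC = c(1, 3, 5, 10, 20, 30),
                    BC = 0,
                    region = rep(c("helix", "beta"), each = 3))
  out <- metric_distributions(rec, "region", "DC")
  expect_setequal(names(out$values), c("helix", "beta"))
  expect_equal(sum(lengths(out$values)), 6)
  expect_equal(out$summary$median[out$summary$group == "helix"], 3)
  expect_equal(out$summary$median[out$summary$group == "beta"], 20)
  one <- metric_distributions(transform(rec, region = "helix"), "region")
  expect_length(one$values, 1)
  rec_na <- rec; rec_na$region[2] <- NA
  expect_error(metric_distributions(rec_na, "region"), "non-missing")
})

test_that("network export writes readable TSV and GraphML", {
  rin <- rin_from_edges(4, i = c(1, 2), j = c(3, 4), w = c(1.5, 2.5))
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  write_rin(rin, tsv, gml)
  back <- read.delim(tsv)
  expect_equal(back$mean_weight, c(1.5, 2.5))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::E(g)$mean_weight), c(1.5, 2.5))
  unlink(c(tsv, gml))
})
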