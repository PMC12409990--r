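# Independent oracles and small fixture builders shared across tests.

# Exhaustive betweenness oracle: enumerate all simple paths between every
# node pair, keep those of minimal total length (1e-9 tolerance), and credit
# interior nodes with the fraction of minimal paths passing through them.
# Exponential-time by design; only for graphs of ~10 nodes or fewer.
bc_exhaustive <- function(n_nodes, edges) {
  adj <- lapply(seq_len(n_nodes), function(v) list(to = integer(0), len = numeric(0)))
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; l <- edges$len[r]
    adj[[i]]$to <- c(adj[[i]]$to, j); adj[[i]]$len <- c(adj[[i]]$len, l)
    adj[[j]]$to <- c(adj[[j]]$to, i); adj[[j]]$len <- c(adj[[j]]$len, l)
  }
  enumerate <- function(s, t) {
    paths <- list()
    recurse <- function(path, len) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- list(path = path, len = len)
        return(invisible())
      }
      nb <- adj[[v]]
      for (k in seq_along(nb$to))
        if (!nb$to[k] %in% path) recurse(c(path, nb$to[k]), len + nb$len[k])
    }
    recurse(s, 0)
    paths
  }
  bc <- numeric(n_nodes)
  if (n_nodes < 3) return(bc)
  for (s in seq_len(n_nodes - 1L)) for (t in seq(s + 1L, n_nodes)) {
    ps <- enumerate(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    minimal <- ps[lens <= min(lens) + 1e-9]
    through <- numeric(n_nodes)
    for (p in minimal) {
      inner <- setdiff(p$path, c(s, t))
      through[inner] <- through[inner] + 1
    }
    bc <- bc + through / length(minimal)
  }
  bc
}

# Build a residue_interaction_network directly from an edge table, for
# centrality tests that need exact hand-chosen weights.
rin_from_edges <- function(n_residues, i, j, w, type = "vdw") {
  edges <- data.frame(i = as.integer(i), j = as.integer(j),
                      type = rep_len(type, length(i)), mean_weight = w,
                      occupancy = rep_len(1, length(i)),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, n_residues = n_residues, n_frames = 1L,
                 cutoff = NA_real_),
            class = "residue_interaction_network")
}

# Random connected-ish weighted graph as a RIN, for oracle comparisons.
random_rin <- function(n_nodes, p_edge = 0.45) {
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  rin_from_edges(n_nodes, pairs[keep, 1], pairs[keep, 2],
                 w = runif(sum(keep), 0.2, 3))
}

# Minimal single-frame ensemble from explicit atom placements.
ensemble_from_atoms <- function(xyz, resid, resname, name, elem,
                                chain = "A", n_copies = 1L) {
  atoms <- data.frame(resid = resid, resname = resname, chain = chain,
                      name = name, elem = elem, stringsAsFactors = FALSE)
  coords <- array(0, c(n_copies, nrow(xyz), 3L))
  for (f in seq_len(n_copies)) coords[f, , ] <- xyz
  conformational_ensemble(coords, atoms)
}
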