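# Typed residue-interaction networks from conformational ensembles.
#
# Heavy-atom pairs within a distance cutoff (default 4 A) from residues at
# least two apart in the chain (any pair across chains) are counted as
# contacts and typed: electrostatic when the atoms belong to oppositely
# charged sidechain groups, hydrophobic when both are carbons of apolar
# sidechains, van der Waals otherwise. Per frame, per residue pair, the
# contact count is the edge weight ("sum"); weights are then averaged over
# frames ("average"). These operational typing rules are this package's
# definitions and can be overridden via `typing_rules()`.

#' Contact typing rules
#'
#' @param acidic_atoms sidechain oxygens of Asp/Glu counted as negative.
#' @param basic_atoms sidechain nitrogens of Lys/Arg/His counted as positive.
#' @param apolar_residues residues whose sidechain carbons count as
#'   hydrophobic.
#' @param backbone_atoms atom names never counted as sidechain.
#' @return a list of rules consumed by [detect_contacts()].
#' @export
typing_rules <- function(
    acidic_atoms = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
    basic_atoms = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2")),
    apolar_residues = c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP"),
    backbone_atoms = c("N", "CA", "C", "O", "OXT")) {
  list(acidic_atoms = acidic_atoms, basic_atoms = basic_atoms,
       apolar_residues = apolar_residues, backbone_atoms = backbone_atoms)
}

atom_charge_class <- function(resname, name, rules) {
  out <- rep("none", length(resname))
  for (rn in names(rules$acidic_atoms))
    out[resname == rn & name %in% rules$acidic_atoms[[rn]]] <- "neg"
  for (rn in names(rules$basic_atoms))
    out[resname == rn & name %in% rules$basic_atoms[[rn]]] <- "pos"
  out
}

#' Detect typed atom-pair contacts in a single frame
#'
#' Returns all heavy-atom pairs within `cutoff` whose residues are separated
#' by at least 2 in the chain (same chain) or belong to different chains.
#' Each pair is labelled `electrostatic`, `hydrophobic` or `vdw`.
#'
#' @param xyz atoms x 3 coordinate matrix (Angstrom).
#' @param atoms atom metadata data.frame (`resid`, `resname`, `chain`,
#'   `name`, `elem`).
#' @param cutoff distance cutoff in Angstrom; default 4.0.
#' @param rules typing rules from [typing_rules()].
#' @return data.frame with columns `i`, `j` (atom indices), `res_i`, `res_j`,
#'   `dist`, `type`.
#' @export
detect_contacts <- function(xyz, atoms, cutoff = 4.0, rules = typing_rules()) {
  stopifnot(cutoff > 0)
  if (anyNA(atoms$elem) || any(!nzchar(atoms$elem)) ||
      anyNA(atoms$name) || any(!nzchar(atoms$name)))
    stop("atom metadata must include element and atom name for every atom")
  heavy <- which(toupper(atoms$elem) != "H")
  sub <- atoms[heavy, ]
  d <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  same_chain <- outer(sub$chain, sub$chain, "==")
  seqsep <- abs(outer(sub$resid, sub$resid, "-"))
  ok <- d < cutoff & upper.tri(d) & (!same_chain | seqsep >= 2)
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(i = integer(0), j = integer(0), res_i = integer(0),
                      res_j = integer(0), dist = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  a <- idx[, 1]; b <- idx[, 2]
  charge <- atom_charge_class(sub$resname, sub$name, rules)
  sidechain_c <- toupper(sub$elem) == "C" &
    !(sub$name %in% rules$backbone_atoms) &
    sub$resname %in% rules$apolar_residues
  type <- rep("vdw", length(a))
  type[sidechain_c[a] & sidechain_c[b]] <- "hydrophobic"
  opp <- (charge[a] == "neg" & charge[b] == "pos") |
    (charge[a] == "pos" & charge[b] == "neg")
  type[opp] <- "electrostatic"
  data.frame(i = heavy[a], j = heavy[b],
             res_i = sub$resid[a], res_j = sub$resid[b],
             dist = d[idx], type = type, stringsAsFactors = FALSE)
}

#' Build a residue-interaction network from an ensemble
#'
#' Per frame and residue pair, the edge weight is the count of atom-pair
#' contacts; `mean_weight` averages these per-frame counts over all frames
#' (frames without the contact contribute 0) and `occupancy` is the fraction
#' of frames in which the pair has at least one contact. Edges with zero
#' total contact are omitted, as are pairs adjacent in the chain.
#'
#' @param ens a `conformational_ensemble`.
#' @param cutoff contact cutoff in Angstrom; default 4.0.
#' @param rules typing rules from [typing_rules()].
#' @return a `residue_interaction_network`: list with `edges` (data.frame
#'   `i`, `j`, `type`, `mean_weight`, `occupancy`, with i < j), `n_residues`,
#'   `n_frames`, `cutoff`.
#' @export
build_rin <- function(ens, cutoff = 4.0, rules = typing_rules()) {
  stopifnot(inherits(ens, "conformational_ensemble"))
  nf <- n_frames(ens)
  if (nf < 1) stop("empty ensemble")
  acc <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    contacts <- detect_contacts(frame_coords(ens, f), ens$atoms, cutoff, rules)
    if (nrow(contacts) == 0) next
    lo <- pmin(contacts$res_i, contacts$res_j)
    hi <- pmax(contacts$res_i, contacts$res_j)
    key <- paste(lo, hi, contacts$type, sep = "|")
    counts <- table(key)
    for (k in names(counts)) {
      prev <- if (is.null(acc[[k]])) c(0, 0) else acc[[k]]
      acc[[k]] <- c(prev[1] + counts[[k]], prev[2] + 1)
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0), type = character(0),
                        mean_weight = numeric(0), occupancy = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    tot <- t(vapply(keys, function(k) acc[[k]], numeric(2)))
    edges <- data.frame(
      i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
      type = parts[, 3],
      mean_weight = tot[, 1] / nf,
      occupancy = tot[, 2] / nf,
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$i, edges$j, edges$type), ]
    rownames(edges) <- NULL
  }
  structure(
    list(edges = edges, n_residues = max(ens$atoms$resid),
         n_frames = nf, cutoff = cutoff),
    class = "residue_interaction_network"
  )
}

#' @export
print.residue_interaction_network <- function(x, ...) {
  cat(sprintf(
    "<residue_interaction_network> %d residues, %d typed edges (%d frames, cutoff %.1f A)\n",
    x$n_residues, nrow(x$edges), x$n_frames, x$cutoff))
  invisible(x)
}

# Edges pooled over interaction types: one row per residue pair, weights
# summed (a pair's total non-covalent contact count).
pooled_edges <- function(rin) {
  e <- rin$edges
  if (nrow(e) == 0)
    return(data.frame(i = integer(0), j = integer(0), mean_weight = numeric(0)))
  key <- paste(e$i, e$j, sep = "|")
  w <- tapply(e$mean_weight, key, sum)
  parts <- do.call(rbind, strsplit(names(w), "|", fixed = TRUE))
  out <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                    mean_weight = as.numeric(w))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Weighted degree centrality
#'
#' DC(v) is the sum over v's incident edges of the mean contact count
#' (interaction types pooled); it quantifies how many non-covalent contacts a
#' residue makes with its neighbors, averaged over the ensemble. With
#' `weighted = FALSE` each neighbor counts 1 instead (unit-edge degree).
#'
#' @param rin a `residue_interaction_network`.
#' @param weighted sum mean contact counts (default) or count neighbors.
#' @return named numeric vector of length `n_residues` (isolated residues 0).
#' @export
degree_centrality <- function(rin, weighted = TRUE) {
  dc <- stats::setNames(numeric(rin$n_residues), seq_len(rin$n_residues))
  e <- pooled_edges(rin)
  w <- if (weighted) e$mean_weight else rep(1, nrow(e))
  for (r in seq_len(nrow(e))) {
    dc[e$i[r]] <- dc[e$i[r]] + w[r]
    dc[e$j[r]] <- dc[e$j[r]] + w[r]
  }
  dc
}

#' Betweenness centrality on the contact graph
#'
#' Unnormalized node betweenness of the undirected residue graph with edge
#' length 1/mean_weight (stronger contacts are shorter), so
#' BC(v) = sum over pairs s < t (s,t != v) of the fraction of shortest s-t
#' paths through v. Disconnected pairs contribute 0. With
#' `weighted = FALSE` all edges have unit length.
#'
#' @param rin a `residue_interaction_network`.
#' @param weighted use 1/mean_weight edge lengths (default) or unit lengths.
#' @return named numeric vector of length `n_residues`.
#' @export
betweenness_centrality <- function(rin, weighted = TRUE) {
  e <- pooled_edges(rin)
  if (nrow(e) > 0 && any(e$mean_weight <= 0))
    stop("edge weights must be positive")
  g <- igraph::make_empty_graph(n = rin$n_residues, directed = FALSE)
  if (nrow(e) > 0)
    g <- igraph::add_edges(g, rbind(e$i, e$j))
  w <- if (weighted && nrow(e) > 0) 1 / e$mean_weight else NULL
  bc <- igraph::betweenness(g, directed = FALSE, weights = w, normalized = FALSE)
  stats::setNames(as.numeric(bc), seq_len(rin$n_residues))
}

#' Map a conservation grade to its bin
#'
#' Grades 8-9 are `high`, 6-7 `intermediate`, 1-5 `variable` (grade 5, left
#' unassigned by the published binning, is grouped with variable).
#'
#' @param grade integer vector of grades in 1..9.
#' @return character vector of bins.
#' @export
bin_conservation <- function(grade) {
  if (any(grade < 1 | grade > 9 | grade != round(grade)))
    stop("grades must be integers in 1..9")
  out <- rep("variable", length(grade))
  out[grade >= 6] <- "intermediate"
  out[grade >= 8] <- "high"
  out
}

#' Assemble the per-residue metric table
#'
#' @param rin a `residue_interaction_network`.
#' @param conservation optional data.frame (`position`, `grade`).
#' @param region optional character vector of region classes by residue.
#' @param weighted passed to the centrality functions.
#' @return data.frame with columns `residue`, `DC`, `BC` and, when supplied,
#'   `grade`, `conservation_bin`, `region`.
#' @export
residue_metrics <- function(rin, conservation = NULL, region = NULL,
                            weighted = TRUE) {
  out <- data.frame(
    residue = seq_len(rin$n_residues),
    DC = as.numeric(degree_centrality(rin, weighted)),
    BC = as.numeric(betweenness_centrality(rin, weighted))
  )
  if (!is.null(conservation)) {
    out$grade <- conservation$grade[match(out$residue, conservation$position)]
    out$conservation_bin <- NA_character_
    has <- !is.na(out$grade)
    out$conservation_bin[has] <- bin_conservation(out$grade[has])
  }
  if (!is.null(region)) out$region <- region[out$residue]
  out
}

#' Classify hub residues by the DC/BC quadrant rule
#'
#' A residue is a hub when its degree centrality exceeds `dc_threshold` AND
#' its betweenness exceeds `bc_threshold`; most residues cluster below both,
#' and the residues outside that quadrant mark stable scaffolding contacts.
#'
#' @param records data.frame with columns `residue`, `DC`, `BC`.
#' @param dc_threshold default 20.
#' @param bc_threshold default 1000.
#' @return list with `hubs` (residue indices) and `quadrant_counts` (2x2
#'   table of low/high DC x low/high BC).
#' @export
classify_hubs <- function(records, dc_threshold = 20, bc_threshold = 1000) {
  stopifnot(dc_threshold > 0, bc_threshold > 0)
  if (nrow(records) == 0)
    return(list(hubs = integer(0),
                quadrant_counts = matrix(0L, 2, 2,
                  dimnames = list(DC = c("low", "high"), BC = c("low", "high")))))
  hi_dc <- records$DC > dc_threshold
  hi_bc <- records$BC > bc_threshold
  counts <- table(factor(ifelse(hi_dc, "high", "low"), c("low", "high")),
                  factor(ifelse(hi_bc, "high", "low"), c("low", "high")))
  names(dimnames(counts)) <- c("DC", "BC")
  list(hubs = records$residue[hi_dc & hi_bc], quadrant_counts = counts)
}

#' Metric distributions by region or conservation bin
#'
#' Partitions per-residue metric values into exhaustive, disjoint groups and
#' summarizes each with median and quartiles, as displayed in the violin-plot
#' comparisons of water vs urea ensembles.
#'
#' @param records data.frame from [residue_metrics()].
#' @param group_by `"region"` or `"conservation_bin"`.
#' @param metric column to summarize; default `"DC"`.
#' @return list with `values` (named list of per-group vectors) and `summary`
#'   (data.frame group, n, q1, median, q3).
#' @export
metric_distributions <- function(records, group_by = c("region", "conservation_bin"),
                                 metric = "DC") {
  group_by <- match.arg(group_by)
  if (!group_by %in% names(records) || anyNA(records[[group_by]]))
    stop("every record must carry a non-missing '", group_by, "' attribute")
  groups <- split(records[[metric]], records[[group_by]])
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    q <- stats::quantile(groups[[g]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(groups[[g]]),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  list(values = groups, summary = summary)
}

#' Export a residue-interaction network
#'
#' Writes edges as TSV (i, j, type, mean_weight, occupancy) and, optionally,
#' as GraphML with the same edge attributes.
#'
#' @param rin a `residue_interaction_network`.
#' @param tsv_path TSV output path (or NULL to skip).
#' @param graphml_path GraphML output path (or NULL to skip).
#' @return invisible NULL.
#' @export
write_rin <- function(rin, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(rin$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::make_empty_graph(n = rin$n_residues, directed = FALSE)
    if (nrow(rin$edges) > 0) {
      g <- igraph::add_edges(g, rbind(rin$edges$i, rin$edges$j))
      igraph::E(g)$type <- rin$edges$type
      igraph::E(g)$mean_weight <- rin$edges$mean_weight
      igraph::E(g)$occupancy <- rin$edges$occupancy
    }
    igraph::V(g)$residue <- seq_len(rin$n_residues)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(NULL)
}
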