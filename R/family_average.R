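# Averaging per-residue network metrics across a protein family via a master
# multiple sequence alignment, so that structurally equivalent positions are
# compared across homologs spanning the evolutionary tree.

#' Read a master alignment from FASTA
#' @param path FASTA file of aligned sequences (gaps as `-`).
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aln), names(aln))
}

aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Average per-residue metrics across a family on a master alignment
#'
#' For each alignment column, the mean DC and BC are arithmetic means over
#' the proteins that are not gapped at that column; gap positions are
#' excluded from both numerator and denominator. Columns gapped in every
#' protein are dropped. When the tables carry conservation bins or region
#' classes, each column also reports the majority class among contributing
#' proteins (ties broken by high > intermediate > variable for conservation,
#' first alphabetically for regions).
#'
#' @param tables named list of per-protein metric data.frames (from
#'   [residue_metrics()]); row order must follow the sequence. An optional
#'   `aa` column (1-letter) or `resname` column (3-letter) is checked against
#'   the alignment.
#' @param alignment named character vector of aligned sequences (names
#'   matching `tables`), or a FASTA path.
#' @return data.frame with `column`, `mean_DC`, `mean_BC`, `n_proteins`, and
#'   when available `consensus_bin`, `region`.
#' @export
average_over_family <- function(tables, alignment) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment))
    alignment <- read_alignment_fasta(alignment)
  if (is.null(names(tables)) || !all(names(tables) %in% names(alignment)))
    stop("every table must have a matching alignment sequence")
  widths <- unique(nchar(alignment[names(tables)]))
  if (length(widths) != 1) stop("alignment sequences have unequal widths")
  n_col <- widths

  col_of <- list()   # per protein: residue index -> alignment column
  for (prot in names(tables)) {
    chars <- strsplit(alignment[[prot]], "")[[1]]
    ungapped <- which(chars != "-")
    tab <- tables[[prot]]
    if (length(ungapped) != nrow(tab))
      stop("sequence/alignment mismatch for '", prot, "': alignment has ",
           length(ungapped), " residues, table has ", nrow(tab))
    seq_tab <- NULL
    if ("aa" %in% names(tab)) seq_tab <- toupper(tab$aa)
    else if ("resname" %in% names(tab)) seq_tab <- unname(aa3to1[toupper(tab$resname)])
    if (!is.null(seq_tab) && !anyNA(seq_tab) &&
        !all(seq_tab == toupper(chars[ungapped])))
      stop("sequence/alignment mismatch for '", prot,
           "': residue identities differ from the aligned sequence")
    col_of[[prot]] <- ungapped
  }

  sum_dc <- sum_bc <- numeric(n_col)
  n_prot <- integer(n_col)
  bins <- vector("list", n_col)
  regions <- vector("list", n_col)
  for (prot in names(tables)) {
    tab <- tables[[prot]]
    cols <- col_of[[prot]]
    sum_dc[cols] <- sum_dc[cols] + tab$DC
    sum_bc[cols] <- sum_bc[cols] + tab$BC
    n_prot[cols] <- n_prot[cols] + 1L
    if ("conservation_bin" %in% names(tab))
      for (k in seq_along(cols))
        bins[[cols[k]]] <- c(bins[[cols[k]]], tab$conservation_bin[k])
    if ("region" %in% names(tab))
      for (k in seq_along(cols))
        regions[[cols[k]]] <- c(regions[[cols[k]]], tab$region[k])
  }
  keep <- which(n_prot > 0)
  out <- data.frame(
    column = keep,
    mean_DC = sum_dc[keep] / n_prot[keep],
    mean_BC = sum_bc[keep] / n_prot[keep],
    n_proteins = n_prot[keep]
  )
  if (any(lengths(bins) > 0)) {
    order_pref <- c("high", "intermediate", "variable")
    out$consensus_bin <- vapply(keep, function(cc) {
      b <- bins[[cc]]
      if (is.null(b)) return(NA_character_)
      tt <- table(factor(b, levels = order_pref))
      names(tt)[which.max(tt)]
    }, character(1))
  }
  if (any(lengths(regions) > 0)) {
    out$region <- vapply(keep, function(cc) {
      r <- regions[[cc]]
      if (is.null(r)) return(NA_character_)
      tt <- sort(table(r), decreasing = TRUE)
      names(tt)[1]
    }, character(1))
  }
  out
}
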