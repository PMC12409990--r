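# Synthetic equilibrium-unfolding datasets from known thermodynamic
# parameters, for parameter-recovery testing of the global fitter.

# Stand-in per-probe baselines; chosen to resemble normalized fluorescence
# (280 nm: all aromatics; 295 nm: Trp only) and far-UV CD ellipticity traces.
# The intermediate signal is deliberately probe-dependent, as for a molten
# globule: hyperfluorescent at 280 nm (tryptophans shielded from solvent but
# released from native quenchers), unfolded-like at 295 nm, native-like
# secondary structure by CD. This differential signature is what makes the
# intermediate identifiable in a global fit; a cI at the N/U midpoint on
# every probe would be indistinguishable from an N/U mixture.
.preset_baselines_3s <- list(
  "280nm" = list(aN = 1.00, bN = -0.012, cI = 1.45, aU = 0.25, bU = 0.008),
  "295nm" = list(aN = 0.85, bN = -0.010, cI = 0.17, aU = 0.15, bU = 0.006),
  "CD"    = list(aN = -1.00, bN = 0.005, cI = -0.97, aU = -0.15, bU = -0.004)
)
.preset_baselines_2s <- lapply(.preset_baselines_3s, function(b) b[c("aN", "bN", "aU", "bU")])

#' Folding presets
#'
#' Registry of generating conditions for synthetic unfolding experiments:
#' \describe{
#'   \item{`"21M"`}{three-state monomer; dG = (1.0, 2.7) kcal/mol — the
#'     global-fit free energies reported for the subfamily-swap (21M)
#'     caspase variants — with stand-in m-values m = (1.2, 0.7) kcal/mol/M
#'     (second transition centered near 4 M urea, matching the observed
#'     slope change there; the first transition complete well below it, so
#'     both transitions carry recoverable information at 2\% noise) and
#'     stand-in baselines.}
#'   \item{`"hub_mutant"`}{two-state; dG = 2.3 kcal/mol — the reported fit
#'     for the phenylalanine-core (F-to-A) variant — with stand-in
#'     m = 0.575 kcal/mol/M (midpoint 4 M).}
#' }
#' Probes are 280 nm and 295 nm fluorescence plus far-UV CD; concentrations
#' 2, 6 and 8 uM; temperature 298.15 K.
#'
#' @param name preset name.
#' @return a `folding_preset` list with elements `name`, `params`
#'   (a [thermo_params()]), `probes`, `concentrations` (uM).
#' @export
folding_preset <- function(name = c("21M", "hub_mutant")) {
  name <- match.arg(name)
  params <- switch(name,
    "21M" = thermo_params("three_state", dG = c(1.0, 2.7), m = c(1.2, 0.7),
                          baselines = .preset_baselines_3s),
    "hub_mutant" = thermo_params("two_state", dG = 2.3, m = 0.575,
                                 baselines = .preset_baselines_2s)
  )
  structure(
    list(name = name, params = params, probes = names(params$baselines),
         concentrations = c(2, 6, 8)),
    class = "folding_preset"
  )
}

#' Generate synthetic equilibrium-unfolding datasets
#'
#' One dataset per probe x concentration x direction x replicate, on a common
#' urea grid; unfolding and refolding curves follow the same equilibrium
#' model with independent noise (the folding reactions are reversible).
#' Signal = forward model + homoscedastic Gaussian noise whose sd is
#' `noise_sd_fraction` times that probe's N-to-U signal range (|aN - aU|).
#' Monomer models have no concentration term, so generated curves are
#' concentration-independent by construction; `cm_shift_per_doubling`
#' optionally injects an oligomer-like midpoint shift (M of urea per doubling
#' of protein concentration) for adversarial fixtures.
#'
#' @param preset a [folding_preset()] or a list with the same fields.
#' @param urea_grid monotone non-empty numeric grid (M); default 25 points
#'   over 0-9 M.
#' @param noise_sd_fraction noise sd as a fraction of signal range; >= 0.
#' @param n_replicates replicate datasets per probe x concentration.
#' @param seed integer seed.
#' @param cm_shift_per_doubling midpoint shift per concentration doubling
#'   relative to the lowest concentration (default 0 = true monomer).
#' @param directions curve directions to generate; default both unfolding
#'   and refolding.
#' @return data.frame with columns `urea_M`, `signal`, `probe`, `conc_uM`,
#'   `replicate`, `direction`.
#' @export
make_unfolding_datasets <- function(preset, urea_grid = seq(0, 9, length.out = 25),
                                    noise_sd_fraction = 0.02, n_replicates = 1L,
                                    seed = 1L, cm_shift_per_doubling = 0,
                                    directions = c("unfolding", "refolding")) {
  if (length(urea_grid) == 0 || is.unsorted(urea_grid))
    stop("urea_grid must be non-empty and monotone increasing")
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be >= 0")
  params <- preset$params
  stopifnot(inherits(params, "thermo_params"))
  conc_ref <- min(preset$concentrations)
  with_seed(seed, {
    out <- list()
    for (probe in preset$probes) {
      b <- params$baselines[[probe]]
      noise_sd <- noise_sd_fraction * abs(b$aN - b$aU)
      for (conc in preset$concentrations) {
        p_use <- params
        if (cm_shift_per_doubling != 0) {
          shift <- cm_shift_per_doubling * log2(conc / conc_ref)
          p_use$dG <- params$dG + params$m * shift
        }
        clean <- signal_model(p_use, urea_grid, probe)
        for (dir in directions) for (rep_i in seq_len(n_replicates)) {
          out[[length(out) + 1L]] <- data.frame(
            urea_M = urea_grid,
            signal = clean + stats::rnorm(length(urea_grid), sd = noise_sd),
            probe = probe, conc_uM = conc, replicate = rep_i,
            direction = dir, stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Write unfolding datasets as TSV
#' @param data data.frame from [make_unfolding_datasets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unfolding_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read unfolding datasets from TSV
#' @param path input path.
#' @return data.frame with the columns written by [write_unfolding_tsv()].
#' @export
read_unfolding_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
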