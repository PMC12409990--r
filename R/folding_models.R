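# Equilibrium unfolding forward models (linear extrapolation method).
#
# Free energies follow the convention dG(urea) = dG0 - m*[urea] with
# K = exp(-dG/RT), so a positive dG0 means the folded species is stable in
# water. Two-state: N <-> U with constant K1. Three-state monomer:
# N <-> I <-> U with sequential constants K1, K2. Observed signal is the
# population-weighted sum of per-species linear baselines; the intermediate
# baseline is a urea-independent constant (standard identifiability choice).

R_KCAL <- 1.9872e-3  # gas constant, kcal / (mol K)

#' Thermodynamic parameters for equilibrium unfolding
#'
#' @param model `"two_state"` (N<->U) or `"three_state"` (N<->I<->U monomer).
#' @param dG free energies of unfolding in water, kcal/mol, one per
#'   transition (length 1 for two-state, 2 for three-state).
#' @param m m-values, kcal/mol/M, same length as `dG`; all positive.
#' @param baselines named list, one entry per probe; each entry a list with
#'   `aN`, `bN` (native intercept/slope), `aU`, `bU` (unfolded), and for the
#'   three-state model `cI` (constant intermediate signal).
#' @param temperature Kelvin; default 298.15.
#'
#' @return a `thermo_params` object.
#' @export
thermo_params <- function(model = c("two_state", "three_state"), dG, m,
                          baselines = NULL, temperature = 298.15) {
  model <- match.arg(model)
  n_tr <- if (model == "two_state") 1L else 2L
  if (length(dG) != n_tr || length(m) != n_tr)
    stop("dG and m must have length ", n_tr, " for the ", model, " model")
  if (any(m <= 0)) stop("all m-values must be positive")
  if (!is.null(baselines)) {
    for (p in names(baselines)) {
      b <- baselines[[p]]
      need <- c("aN", "bN", "aU", "bU")
      if (!all(need %in% names(b)))
        stop("baselines for probe '", p, "' must contain ",
             paste(need, collapse = ", "))
      if (model == "two_state" && "cI" %in% names(b))
        stop("intermediate baseline supplied for a two-state model (probe '",
             p, "')")
      if (model == "three_state" && !("cI" %in% names(b)))
        stop("three-state model needs an intermediate baseline cI (probe '",
             p, "')")
    }
  }
  structure(
    list(model = model, dG = as.numeric(dG), m = as.numeric(m),
         baselines = baselines, temperature = temperature),
    class = "thermo_params"
  )
}

rt_kcal <- function(temperature) R_KCAL * temperature

#' Species fractions for the two-state model
#'
#' K1(urea) = exp(-(dG0 - m*urea)/RT); fU = K1/(1+K1), fN = 1 - fU.
#'
#' @param params a two-state [thermo_params()].
#' @param urea numeric vector of urea concentrations (M).
#' @return data.frame with columns `urea`, `fN`, `fU`; rows sum to 1 exactly.
#' @export
fractions_two_state <- function(params, urea) {
  stopifnot(inherits(params, "thermo_params"), params$model == "two_state")
  RT <- rt_kcal(params$temperature)
  K1 <- exp(-(params$dG[1] - params$m[1] * urea) / RT)
  fU <- K1 / (1 + K1)
  data.frame(urea = urea, fN = 1 - fU, fU = fU)
}

#' Species fractions for the three-state monomer model
#'
#' Sequential N <-> I <-> U: fN = 1/(1+K1+K1*K2), fI = K1*fN, fU = K1*K2*fN.
#'
#' @param params a three-state [thermo_params()].
#' @param urea numeric vector of urea concentrations (M).
#' @return data.frame with columns `urea`, `fN`, `fI`, `fU`; rows sum to 1.
#' @export
fractions_three_state <- function(params, urea) {
  stopifnot(inherits(params, "thermo_params"), params$model == "three_state")
  RT <- rt_kcal(params$temperature)
  K1 <- exp(-(params$dG[1] - params$m[1] * urea) / RT)
  K2 <- exp(-(params$dG[2] - params$m[2] * urea) / RT)
  fN <- 1 / (1 + K1 + K1 * K2)
  data.frame(urea = urea, fN = fN, fI = K1 * fN, fU = K1 * K2 * fN)
}

#' Predicted spectroscopic signal
#'
#' signal = fN*(aN + bN*urea) + [fI*cI] + fU*(aU + bU*urea), with the
#' intermediate contributing a urea-independent constant.
#'
#' @param params [thermo_params()] carrying baselines for `probe`.
#' @param urea numeric vector (M).
#' @param probe probe label matching a `baselines` entry.
#' @return numeric vector of predicted signals.
#' @export
signal_model <- function(params, urea, probe) {
  stopifnot(inherits(params, "thermo_params"))
  b <- params$baselines[[probe]]
  if (is.null(b)) stop("no baselines for probe '", probe, "'")
  if (params$model == "two_state") {
    fr <- fractions_two_state(params, urea)
    fr$fN * (b$aN + b$bN * urea) + fr$fU * (b$aU + b$bU * urea)
  } else {
    fr <- fractions_three_state(params, urea)
    fr$fN * (b$aN + b$bN * urea) + fr$fI * b$cI +
      fr$fU * (b$aU + b$bU * urea)
  }
}

#' Transition midpoints
#' @param params a [thermo_params()].
#' @return numeric vector Cm_i = dG_i / m_i (M).
#' @export
midpoints <- function(params) params$dG / params$m
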