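# Synthetic-data generators with known ground truth: Gaussian-band reference
# spectra, pH titration series obeying the one-parameter protonation model,
# reversible mass-action transglycosylation kinetics whose endpoint satisfies
# both equilibrium constraints, and HPLC peak tables proportional to species
# concentrations. Every generator is deterministic under a fixed seed.

#' Build reference spectra from Gaussian band models
#'
#' Each reference state is a sum of Gaussian absorption bands
#' `A * exp(-(lambda - center)^2 / (2 width^2))` evaluated on the wavelength
#' grid.
#'
#' @param bands Named list, one element per reference state; each element a
#'   data frame (or 3-column matrix) with columns `center_nm`, `width_nm`,
#'   `amplitude_au`, one row per band. Widths must be > 0, amplitudes >= 0.
#' @param grid Wavelength grid (nm). Default 250:350, the quantification
#'   range, in 1 nm steps.
#' @return A [reference_set()] when `bands` has two or more states; a plain
#'   data frame for a single state.
#' @examples
#' refs <- make_references(list(
#'   prot   = data.frame(center_nm = 270, width_nm = 12, amplitude_au = 0.8),
#'   deprot = data.frame(center_nm = 307, width_nm = 15, amplitude_au = 1.0)))
#' @export
make_references <- function(bands, grid = 250:350) {
  stopifnot(is.list(bands), !is.null(names(bands)))
  cols <- lapply(bands, function(bm) {
    bm <- as.data.frame(bm)
    names(bm) <- c("center_nm", "width_nm", "amplitude_au")
    if (any(bm$width_nm <= 0) || any(bm$amplitude_au < 0))
      stop("band widths must be > 0 and amplitudes >= 0", call. = FALSE)
    Reduce(`+`, lapply(seq_len(nrow(bm)), function(i)
      bm$amplitude_au[i] *
        exp(-(grid - bm$center_nm[i])^2 / (2 * bm$width_nm[i]^2))),
      accumulate = FALSE, init = numeric(length(grid)))
  })
  if (length(cols) >= 2)
    do.call(reference_set, c(list(wavelength_nm = grid), cols))
  else
    cbind(data.frame(wavelength_nm = grid),
          as.data.frame(cols, check.names = FALSE))
}

#' Generate a synthetic pH titration series
#'
#' Mixes the protonated and deprotonated reference spectra according to the
#' protonation model `alpha(pH) = 10^(pH - pKa) / (1 + 10^(pH - pKa))` and
#' adds Gaussian noise: `spectrum(pH) = (1 - alpha) ref_prot + alpha
#' ref_deprot + N(0, noise_sd)`.
#'
#' @param pKa_true Ground-truth pKa.
#' @param pH_values pH sampling points. Default `seq(4, 10, by = 0.5)`.
#' @param refs A two-state [reference_set()]; the first reference column is
#'   taken as protonated, the second as deprotonated.
#' @param noise_sd Additive noise standard deviation (AU). Default 0.002.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A long data frame of class `titration_series` with columns `pH`,
#'   `wavelength_nm`, `absorbance_au` and a `ground_truth` attribute recording
#'   `pKa`, `alpha`, `noise_sd` and `seed`.
#' @export
make_titration <- function(pKa_true, pH_values = seq(4, 10, by = 0.5), refs,
                           noise_sd = 0.002, seed = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  ref_names <- setdiff(names(refs), "wavelength_nm")
  if (length(ref_names) != 2)
    stop("titration generation needs exactly two reference states", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prot <- refs[[ref_names[1]]]
  deprot <- refs[[ref_names[2]]]
  alpha <- 10^(pH_values - pKa_true) / (1 + 10^(pH_values - pKa_true))
  out <- do.call(rbind, lapply(seq_along(pH_values), function(i) {
    ab <- (1 - alpha[i]) * prot + alpha[i] * deprot
    if (noise_sd > 0) ab <- ab + stats::rnorm(length(ab), 0, noise_sd)
    data.frame(pH = pH_values[i], wavelength_nm = refs$wavelength_nm,
               absorbance_au = ab)
  }))
  structure(out,
            class = c("titration_series", "data.frame"),
            ground_truth = list(pKa = pKa_true, alpha = alpha,
                                noise_sd = noise_sd, seed = seed))
}

#' Simulate a transglycosylation time course by reversible mass action
#'
#' Integrates the two coupled reversible mass-action reactions
#' `r1 = kf1 ([N_d][Pi] - [S][B_d]/K_donor)` (donor phosphorolysis) and
#' `r2 = kf2 ([S][B_p] - K_product [N_p][Pi])` (glycosylation), whose fixed
#' point is exactly the coupled-equilibrium state: the terminal conversion
#' matches [solve_equilibrium()] once the trajectory has relaxed. The rate law
#' is generic mass action, not an enzymological model; it exists to produce
#' thermodynamically consistent trajectories.
#'
#' @param system A [transgly_system()].
#' @param kf1,kf2 Forward rate coefficients (1/(mM min), > 0).
#' @param t_grid Output time grid (min), starting at 0.
#' @param rtol,atol Integrator tolerances (deSolve lsoda). Defaults `1e-10`
#'   and `1e-12` keep mass balances conserved to ~1e-9 relative.
#' @return An object of class `kinetic_trajectory`: data frame with columns
#'   `time_min` and the six species concentrations, with attributes `params`
#'   (system, kf1, kf2) and `equilibrated` (`TRUE` when the last two grid
#'   points agree to 1e-6 relative in conversion; a warning is emitted
#'   otherwise).
#' @export
simulate_transglycosylation <- function(system, kf1, kf2, t_grid,
                                        rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(system, "transgly_system"), kf1 > 0, kf2 > 0)
  if (t_grid[1] != 0) stop("t_grid must start at 0", call. = FALSE)
  y0 <- c(Nd = system$mix[["donor_0"]], Bd = 0,
          Bp = system$mix[["base_0"]], Np = 0,
          S = 0, Pi = system$mix[["phosphate_0"]])
  Kd <- system$constants[["K_donor"]]
  Kp <- system$constants[["K_product"]]
  derivs <- function(t, y, parms) {
    r1 <- kf1 * (y[["Nd"]] * y[["Pi"]] - y[["S"]] * y[["Bd"]] / Kd)
    r2 <- kf2 * (y[["S"]] * y[["Bp"]] - Kp * y[["Np"]] * y[["Pi"]])
    list(c(Nd = -r1, Bd = r1, Bp = -r2, Np = r2,
           S = r1 - r2, Pi = -r1 + r2))
  }
  sol <- deSolve::ode(y0, t_grid, derivs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- data.frame(time_min = sol[, "time"],
                    donor_nucleoside = sol[, "Nd"],
                    donor_base = sol[, "Bd"],
                    acceptor_base = sol[, "Bp"],
                    product_nucleoside = sol[, "Np"],
                    pentose1P = sol[, "S"],
                    phosphate = sol[, "Pi"])
  n <- nrow(out)
  B0 <- system$mix[["base_0"]]
  equilibrated <- B0 > 0 && n >= 2 &&
    abs(out$product_nucleoside[n] - out$product_nucleoside[n - 1]) <=
      1e-6 * max(out$product_nucleoside[n], atol)
  if (!equilibrated)
    warning("time grid too short: trajectory has not reached equilibrium",
            call. = FALSE)
  structure(out,
            class = c("kinetic_trajectory", "data.frame"),
            params = list(system = system, kf1 = kf1, kf2 = kf2),
            equilibrated = equilibrated)
}

#' Generate a synthetic HPLC peak table from species concentrations
#'
#' Peak areas are `response_factor * concentration * (1 + eps)` with
#' multiplicative Gaussian noise `eps ~ N(0, noise_sd)` (truncated so areas
#' stay nonnegative); retention times come from the compound retention-time
#' map.
#'
#' @param state Named numeric of species concentrations (mM); names must be
#'   compound labels present in `rt_map`.
#' @param response_factors Named numeric of per-compound detector response
#'   factors (> 0), or a scalar applied to all. Default 1 (equal response).
#' @param noise_sd Relative noise standard deviation. Default 0.02.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param rt_map Retention-time centers; default [default_rt_map()].
#' @param wavelength Detection wavelength recorded on the peaks. Default 307.
#' @return A [peak_table()] with compounds pre-assigned, carrying the
#'   generating `state` as the `ground_truth` attribute.
#' @export
make_peak_table <- function(state, response_factors = 1, noise_sd = 0.02,
                            seed = NULL, rt_map = default_rt_map(),
                            wavelength = 307) {
  stopifnot(is.numeric(state), !is.null(names(state)), all(state >= 0))
  if (!all(names(state) %in% names(rt_map)))
    stop("every species in state needs a retention time in rt_map", call. = FALSE)
  rf <- if (length(response_factors) == 1 && is.null(names(response_factors)))
    stats::setNames(rep(response_factors, length(state)), names(state))
  else response_factors[names(state)]
  if (any(!is.finite(rf)) || any(rf <= 0))
    stop("response factors must be > 0 for every species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(length(state), 0, noise_sd) else 0
  areas <- pmax(rf * state * (1 + eps), 0)
  tab <- peak_table(rt_min = unname(rt_map[names(state)]),
                    area = unname(areas),
                    wavelength_nm = wavelength,
                    compound = names(state))
  attr(tab, "ground_truth") <- list(state = state, response_factors = rf,
                                    noise_sd = noise_sd, seed = seed)
  tab
}
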