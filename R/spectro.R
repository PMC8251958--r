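# Spectrophotometric analytics: nonnegative spectral unmixing of UV/Vis
# spectra into reference-state fractions, pKa determination from the
# protonation fraction alpha(pH) = 10^(pH - pKa) / (1 + 10^(pH - pKa)),
# and enzyme activity from the initial linear rate of a progress curve.

#' Construct a UV/Vis spectrum
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param absorbance_au Absorbances (AU), same length.
#' @return A data frame of class `spectrum` with columns `wavelength_nm` and
#'   `absorbance_au`.
#' @export
uv_spectrum <- function(wavelength_nm, absorbance_au) {
  if (length(wavelength_nm) != length(absorbance_au))
    stop("wavelength and absorbance vectors must have equal length", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  structure(data.frame(wavelength_nm = wavelength_nm,
                       absorbance_au = absorbance_au),
            class = c("spectrum", "data.frame"))
}

#' Construct a reference-spectrum set
#'
#' A set of named endpoint spectra (for example fully protonated / fully
#' deprotonated nucleobase) on one shared wavelength grid, used as the basis
#' for spectral unmixing.
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param ... At least two named numeric vectors of absorbances (AU), one per
#'   reference state, each on the shared grid.
#' @return A data frame of class `reference_set` with column `wavelength_nm`
#'   followed by one column per reference.
#' @export
reference_set <- function(wavelength_nm, ...) {
  refs <- list(...)
  if (length(refs) == 1 && is.data.frame(refs[[1]]))
    refs <- as.list(refs[[1]])
  if (length(refs) < 2)
    stop("a reference set needs at least two reference spectra", call. = FALSE)
  if (is.null(names(refs)) || any(names(refs) == ""))
    stop("all reference spectra must be named", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  lens <- vapply(refs, length, integer(1))
  if (any(lens != length(wavelength_nm)))
    stop("all reference spectra must share the wavelength grid", call. = FALSE)
  structure(cbind(data.frame(wavelength_nm = wavelength_nm),
                  as.data.frame(refs, check.names = FALSE)),
            class = c("reference_set", "data.frame"))
}

.ref_matrix <- function(refs) {
  as.matrix(refs[, setdiff(names(refs), "wavelength_nm"), drop = FALSE])
}

#' Unmix a spectrum into reference-state fractions
#'
#' Nonnegative least-squares decomposition of an observed spectrum into the
#' reference spectra, with the coefficients normalized to fractions summing
#' to one. Nonnegativity is imposed because the fractions are physical state
#' populations.
#'
#' @param spec A [uv_spectrum()], or anything with `wavelength_nm` and
#'   `absorbance_au` columns. If its grid differs from the reference grid it
#'   is resampled by linear interpolation with a warning.
#' @param refs A [reference_set()].
#' @param condition_max Condition-number guard: references whose design matrix
#'   exceeds this are rejected as collinear. Default `1e8`.
#'
#' @return An object of class `unmix_result`: list with `fractions` (named,
#'   nonnegative, summing to 1), `coefficients` (unnormalized nonnegative
#'   least-squares scale factors), `residual` (Euclidean norm of the spectral
#'   residual, AU) and `resampled`.
#' @export
unmix <- function(spec, refs, condition_max = 1e8) {
  stopifnot(inherits(refs, "reference_set"))
  A <- .ref_matrix(refs)
  if (kappa(A, exact = TRUE) > condition_max)
    stop("ill-conditioned reference set: references are (near-)collinear",
         call. = FALSE)
  resampled <- FALSE
  wl <- spec$wavelength_nm
  b <- spec$absorbance_au
  if (length(wl) != nrow(refs) || any(wl != refs$wavelength_nm)) {
    if (min(wl) > min(refs$wavelength_nm) || max(wl) < max(refs$wavelength_nm))
      stop("spectrum does not cover the reference wavelength grid", call. = FALSE)
    b <- stats::approx(wl, b, xout = refs$wavelength_nm)$y
    resampled <- TRUE
    warning("spectrum resampled onto the reference grid by linear interpolation",
            call. = FALSE)
  }
  fit <- pracma::lsqnonneg(A, b)
  coefs <- stats::setNames(fit$x, colnames(A))
  total <- sum(coefs)
  if (total <= 0)
    stop("no signal: all unmixing coefficients are zero", call. = FALSE)
  structure(
    list(fractions = coefs / total,
         coefficients = coefs,
         residual = sqrt(sum((b - A %*% fit$x)^2)),
         resampled = resampled),
    class = "unmix_result"
  )
}

#' Fit a pKa to a pH-resolved titration series
#'
#' Unmixes every spectrum of the series into protonated/deprotonated
#' fractions, forms the deprotonation fraction
#' `alpha = x_deprot / (x_deprot + x_prot)`, and fits the one-parameter
#' protonation model `alpha(pH) = 10^(pH - pKa) / (1 + 10^(pH - pKa))` by
#' nonlinear least squares with pKa as the sole parameter. The fitted pKa is
#' exactly the pH at which the fitted alpha crosses 0.5.
#'
#' @param series A titration series: data frame with columns `pH`,
#'   `wavelength_nm`, `absorbance_au` (one spectrum per distinct pH), e.g.
#'   from [make_titration()] or [read_titration_csv()].
#' @param refs A [reference_set()] with the protonated and deprotonated
#'   endpoint spectra.
#' @param deprot Name of the deprotonated reference column. Default is the
#'   second reference column.
#'
#' @return An object of class `pka_fit`: list with `pKa`, `stderr` (asymptotic
#'   standard error from the least-squares curvature), and `data` (per-pH
#'   observed and fitted alpha).
#' @export
fit_pka <- function(series, refs, deprot = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  need <- c("pH", "wavelength_nm", "absorbance_au")
  if (!all(need %in% names(series)))
    stop("series must have columns pH, wavelength_nm, absorbance_au", call. = FALSE)
  ref_names <- setdiff(names(refs), "wavelength_nm")
  if (length(ref_names) != 2)
    stop("pKa fitting needs exactly two references (protonated, deprotonated)",
         call. = FALSE)
  if (is.null(deprot)) deprot <- ref_names[2]
  if (!deprot %in% ref_names)
    stop("deprot must name one of the reference columns", call. = FALSE)

  pH <- sort(unique(series$pH))
  if (length(pH) < 5)
    stop("at least 5 distinct pH values are required", call. = FALSE)
  alpha <- vapply(pH, function(p) {
    sub <- series[series$pH == p, ]
    sub <- sub[order(sub$wavelength_nm), ]
    u <- unmix(uv_spectrum(sub$wavelength_nm, sub$absorbance_au), refs)
    unname(u$fractions[deprot])
  }, numeric(1))

  if (all(alpha > 0.95) || all(alpha < 0.05))
    stop("no protonation transition within the sampled pH range", call. = FALSE)
  start <- pH[which.min(abs(alpha - 0.5))]
  if (min(pH) > start - 1 || max(pH) < start + 1)
    warning("series spans less than one pH unit on a side of the transition ",
            "midpoint; expect a wide pKa standard error", call. = FALSE)
  df <- data.frame(pH = pH, alpha = alpha)
  fit <- minpack.lm::nlsLM(
    alpha ~ 10^(pH - pKa) / (1 + 10^(pH - pKa)),
    data = df, start = list(pKa = start),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- summary(fit)$coefficients
  structure(
    list(pKa = unname(est["pKa", "Estimate"]),
         stderr = unname(est["pKa", "Std. Error"]),
         data = data.frame(pH = pH, alpha_observed = alpha,
                           alpha_fitted = stats::fitted(fit))),
    class = "pka_fit"
  )
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("pKa = %.3f +/- %.3f (n = %d pH points)\n",
              x$pKa, x$stderr, nrow(x$data)))
  invisible(x)
}

#' Convert unmixed state fractions to product concentration
#'
#' For a phosphorolysis (or glycosylation) progress assay quantified by
#' spectral unmixing, the product concentration at each time point is the
#' product-state fraction times the initial substrate concentration.
#'
#' @param time_min Sampling times (min).
#' @param fractions Either a numeric vector of product fractions, or a list of
#'   [unmix()] results from which the `product` fraction is taken.
#' @param substrate_0 Initial substrate concentration (mM).
#' @param product Name of the product reference when `fractions` is a list of
#'   unmix results. Default `"product"`.
#'
#' @return Data frame with columns `time_min` and `product_mM`.
#' @export
progress_to_concentration <- function(time_min, fractions, substrate_0,
                                      product = "product") {
  if (is.list(fractions) && !is.numeric(fractions))
    fractions <- vapply(fractions, function(u) unname(u$fractions[product]),
                        numeric(1))
  stopifnot(length(time_min) == length(fractions),
            all(fractions >= 0 & fractions <= 1), substrate_0 >= 0)
  data.frame(time_min = time_min, product_mM = fractions * substrate_0)
}

#' Specific enzyme activity from a progress curve
#'
#' Fits an ordinary least-squares line (free intercept) through the initial
#' linear window of a product progress curve. One unit (U) is the amount of
#' enzyme converting 1 umol of substrate per minute, so
#' `units = rate [mM/min] x volume [mL]` and
#' `specific activity = units / enzyme mass [mg]`.
#'
#' @param course Data frame with columns `time_min` and `product_mM`.
#' @param substrate_0 Initial substrate concentration (mM), defining the
#'   linear window.
#' @param enzyme_conc Enzyme concentration (mg/mL).
#' @param volume Reaction volume (mL). Cancels out of the specific activity.
#' @param linear_fraction_max Upper edge of the initial window as a fraction
#'   of `substrate_0` converted. Default 0.15.
#'
#' @return An object of class `activity_result`: list with `initial_rate`
#'   (mM/min), `units` (U), `specific_activity` (U/mg), `window` (time range
#'   used) and `n_points`.
#' @export
specific_activity <- function(course, substrate_0, enzyme_conc, volume = 1,
                              linear_fraction_max = 0.15) {
  stopifnot(all(c("time_min", "product_mM") %in% names(course)),
            substrate_0 > 0, enzyme_conc > 0, volume > 0,
            linear_fraction_max > 0, linear_fraction_max < 1)
  win <- course[course$product_mM <= linear_fraction_max * substrate_0, ]
  if (nrow(win) < 3)
    stop("insufficient data: fewer than 3 points in the initial linear window",
         call. = FALSE)
  rate <- unname(stats::coef(stats::lm(product_mM ~ time_min, data = win))[2])
  units <- rate * volume  # mM/min * mL = umol/min
  structure(
    list(initial_rate = rate,
         units = units,
         specific_activity = units / (enzyme_conc * volume),
         window = range(win$time_min),
         n_points = nrow(win)),
    class = "activity_result"
  )
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("Initial rate %.4g mM/min; %.4g U; %.4g U/mg (%d points, t = %.3g-%.3g min)\n",
              x$initial_rate, x$units, x$specific_activity,
              x$n_points, x$window[1], x$window[2]))
  invisible(x)
}
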