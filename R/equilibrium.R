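# Coupled two-equilibrium model of one-pot transglycosylation.
#
# A nucleoside phosphorylase couples two reversible phosphorolysis reactions
# through a shared pentose-1-phosphate (S) / inorganic phosphate (Pi) pool:
#
#   donor phosphorolysis:   N_d + Pi <-> S + B_d      K_donor   = [S][B_d]/([N_d][Pi])
#   product glycosylation:  S + B_p  <-> N_p + Pi     K_product = [S][B_p]/([N_p][Pi])
#
# Both constants are written in the phosphorolysis direction (sugar phosphate
# and base over nucleoside and phosphate), concentration-based and
# dimensionless. Conversion is x = [N_p]/B0, the fraction of the acceptor
# nucleobase glycosylated at equilibrium.

#' Specify a transglycosylation reaction system
#'
#' Bundles initial loadings, the two phosphorolysis equilibrium constants and
#' (purely descriptive) reaction conditions into a single system object, the
#' full parameterization of the coupled-equilibrium model.
#'
#' @param donor_0 Initial sugar-donor nucleoside concentration (mM).
#' @param base_0 Initial acceptor nucleobase concentration (mM).
#' @param phosphate_0 Initial inorganic phosphate concentration (mM).
#' @param K_donor Equilibrium constant of phosphorolysis of the sugar donor,
#'   convention `[pentose-1-P][base]/([nucleoside][Pi])`; dimensionless, > 0.
#' @param K_product Equilibrium constant of phosphorolysis of the product
#'   nucleoside, same convention; dimensionless, > 0.
#' @param temperature,pH Optional metadata (deg C / pH units). Never enter the
#'   equilibrium math: the constants are condition-specific inputs.
#' @param donor_label,acceptor_label Optional compound labels.
#'
#' @return An object of class `transgly_system`: a list with elements `mix`
#'   (named loadings, mM), `constants` (`K_donor`, `K_product`) and
#'   `conditions`.
#' @examples
#' sys <- transgly_system(donor_0 = 5, base_0 = 1, phosphate_0 = 0.09,
#'                        K_donor = 0.336, K_product = 9.37)
#' solve_equilibrium(sys)$conversion
#' @export
transgly_system <- function(donor_0, base_0, phosphate_0,
                            K_donor, K_product,
                            temperature = NA_real_, pH = NA_real_,
                            donor_label = NA_character_,
                            acceptor_label = NA_character_) {
  mix <- c(donor_0 = donor_0, base_0 = base_0, phosphate_0 = phosphate_0)
  if (any(!is.finite(mix)) || any(mix < 0))
    stop("initial loadings must be finite and >= 0", call. = FALSE)
  if (!is.finite(K_donor) || !is.finite(K_product) ||
      K_donor <= 0 || K_product <= 0)
    stop("equilibrium constants must be finite and > 0", call. = FALSE)
  structure(
    list(
      mix = mix,
      constants = c(K_donor = K_donor, K_product = K_product),
      conditions = list(temperature = temperature, pH = pH,
                        donor = donor_label, acceptor = acceptor_label)
    ),
    class = "transgly_system"
  )
}

#' @export
print.transgly_system <- function(x, ...) {
  cat("Transglycosylation system\n")
  cat(sprintf("  loadings (mM): donor %.4g, base %.4g, phosphate %.4g\n",
              x$mix[["donor_0"]], x$mix[["base_0"]], x$mix[["phosphate_0"]]))
  cat(sprintf("  K_donor = %.4g, K_product = %.4g\n",
              x$constants[["K_donor"]], x$constants[["K_product"]]))
  invisible(x)
}

# Sugar-phosphate concentration implied by the product constraint at trial
# conversion x, using the phosphate balance [Pi] = P0 - [S]:
#   [S]/(P0 - [S]) = K_product * x/(1-x)
.s_from_product_constraint <- function(x, K_product, P0) {
  r <- K_product * x / (1 - x)
  P0 * r / (1 + r)
}

.equilibrium_state <- function(x, D0, B0, P0, K_product) {
  S  <- .s_from_product_constraint(x, K_product, P0)
  xi2 <- x * B0
  xi1 <- xi2 + S
  c(donor_nucleoside   = D0 - xi1,
    donor_base         = xi1,
    acceptor_base      = B0 - xi2,
    product_nucleoside = xi2,
    pentose1P          = S,
    phosphate          = P0 - S)
}

.residuals_of_state <- function(sp, K_donor, K_product) {
  Q1 <- sp[["pentose1P"]] * sp[["donor_base"]] /
    (sp[["donor_nucleoside"]] * sp[["phosphate"]])
  Q2 <- sp[["pentose1P"]] * sp[["acceptor_base"]] /
    (sp[["product_nucleoside"]] * sp[["phosphate"]])
  c(donor = Q1 / K_donor - 1, product = Q2 / K_product - 1)
}

.boundary_result <- function(D0, B0, P0, flag) {
  sp <- c(donor_nucleoside = D0, donor_base = 0, acceptor_base = B0,
          product_nucleoside = 0, pentose1P = 0, phosphate = P0)
  structure(
    list(species = sp, extent_phosphorolysis = 0, extent_glycosylation = 0,
         conversion = 0, residuals = c(donor = NA_real_, product = NA_real_),
         converged = FALSE, flag = flag),
    class = "equilibrium_result"
  )
}

#' Solve the coupled transglycosylation equilibrium
#'
#' Computes the equilibrium composition of the two coupled phosphorolysis
#' equilibria. For a trial conversion x the sugar-phosphate concentration
#' follows in closed form from the product constraint and the phosphate
#' balance, which reduces the problem to a one-dimensional, strictly monotone
#' residual in x for the donor constraint; that root is bracketed on
#' (0, min(1, D0/B0)) and solved deterministically.
#'
#' @param system A [transgly_system()].
#' @param rel_tol Relative tolerance on both equilibrium constraints, in
#'   (0, 1e-3]. Default `1e-9`.
#'
#' @return An object of class `equilibrium_result`: list with `species` (the
#'   six equilibrium concentrations, mM), `extent_phosphorolysis` and
#'   `extent_glycosylation` (mM), `conversion` (fraction of the acceptor base
#'   glycosylated), `residuals` (relative deviation of each constraint),
#'   `converged`, and `flag` (`"ok"` or `"boundary"` for degenerate inputs such
#'   as a zero donor or phosphate loading, where the trivial state x = 0 is
#'   returned).
#' @seealso [infer_K_product()], [infer_K_donor()], [conversion_curve()]
#' @export
solve_equilibrium <- function(system, rel_tol = 1e-9) {
  stopifnot(inherits(system, "transgly_system"))
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol > 1e-3)
    stop("rel_tol must lie in (0, 1e-3]", call. = FALSE)
  D0 <- system$mix[["donor_0"]]
  B0 <- system$mix[["base_0"]]
  P0 <- system$mix[["phosphate_0"]]
  Kd <- system$constants[["K_donor"]]
  Kp <- system$constants[["K_product"]]
  if (B0 <= 0)
    stop("base_0 must be > 0: conversion is defined relative to the acceptor base",
         call. = FALSE)
  if (D0 == 0 || P0 == 0)
    return(.boundary_result(D0, B0, P0, "boundary"))

  # donor-constraint residual in polynomial form; positive at x -> 0+,
  # negative at the feasibility boundary, with a single sign change
  f <- function(x) {
    S <- .s_from_product_constraint(x, Kp, P0)
    Kd * (D0 - x * B0 - S) * (P0 - S) - S * (x * B0 + S)
  }
  x_max <- min(1, D0 / B0)
  lo <- x_max * 1e-14
  hi <- x_max * (1 - 1e-12)
  if (f(lo) <= 0 || f(hi) >= 0)
    return(.boundary_result(D0, B0, P0, "boundary"))
  x <- stats::uniroot(f, c(lo, hi), tol = 1e-15, maxiter = 2000L)$root

  sp <- .equilibrium_state(x, D0, B0, P0, Kp)
  res <- .residuals_of_state(sp, Kd, Kp)
  structure(
    list(species = sp,
         extent_phosphorolysis = sp[["donor_base"]],
         extent_glycosylation = sp[["product_nucleoside"]],
         conversion = x,
         residuals = res,
         converged = all(abs(res) <= rel_tol),
         flag = "ok"),
    class = "equilibrium_result"
  )
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium conversion: %.4f (%.1f%%)%s\n", x$conversion,
              100 * x$conversion,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  print(round(x$species, 6))
  invisible(x)
}

# Admissible sugar-phosphate root of the donor constraint
#   K_donor (D0 - xB0 - S)(P0 - S) = S (xB0 + S)
# which is quadratic in S (linear when K_donor = 1); the admissible root lies
# in (0, min(P0, D0 - xB0)) and always exists for feasible x.
.s_from_donor_constraint <- function(x, K_donor, D0, B0, P0) {
  Dx <- D0 - x * B0
  if (abs(K_donor - 1) < 1e-12) {
    S <- K_donor * Dx * P0 / (K_donor * (Dx + P0) + x * B0)
  } else {
    a <- K_donor - 1
    b <- -(K_donor * (Dx + P0) + x * B0)
    cc <- K_donor * Dx * P0
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    # numerically stable pair of roots
    q <- -(b + sign(b) * sqrt(disc)) / 2
    roots <- c(q / a, cc / q)
    upper <- min(P0, Dx)
    roots <- roots[is.finite(roots) & roots > 0 & roots < upper]
    if (length(roots) == 0) return(NA_real_)
    S <- roots[1]
  }
  S
}

.check_observed_conversion <- function(mix, observed_conversion) {
  if (!is.numeric(observed_conversion) ||
      observed_conversion <= 0 || observed_conversion >= 1)
    stop("observed_conversion must lie strictly between 0 and 1", call. = FALSE)
  if (observed_conversion * mix[["base_0"]] >= mix[["donor_0"]])
    stop("inconsistent observation: x * B0 >= D0 violates the sugar mass balance",
         call. = FALSE)
  if (any(mix <= 0))
    stop("all loadings must be > 0 for equilibrium-constant inference",
         call. = FALSE)
}

#' Infer the product phosphorolysis constant from an observed conversion
#'
#' Inverts the coupled-equilibrium model: given the donor constant and the
#' observed equilibrium conversion, the sugar-phosphate concentration is the
#' admissible root of the (quadratic) donor constraint, after which the product
#' constant follows algebraically.
#'
#' @param mix Named numeric with `donor_0`, `base_0`, `phosphate_0` (mM), or a
#'   [transgly_system()] whose loadings are used.
#' @param K_donor Phosphorolysis equilibrium constant of the sugar donor.
#' @param observed_conversion Observed equilibrium conversion, in (0, 1).
#'
#' @return The product phosphorolysis constant (dimensionless scalar).
#' @export
infer_K_product <- function(mix, K_donor, observed_conversion) {
  mix <- .as_mix(mix)
  .check_observed_conversion(mix, observed_conversion)
  if (!is.finite(K_donor) || K_donor <= 0)
    stop("K_donor must be finite and > 0", call. = FALSE)
  x <- observed_conversion
  D0 <- mix[["donor_0"]]; B0 <- mix[["base_0"]]; P0 <- mix[["phosphate_0"]]
  S <- .s_from_donor_constraint(x, K_donor, D0, B0, P0)
  if (!is.finite(S))
    stop("inconsistent observation: no admissible sugar-phosphate root ",
         "(conversion thermodynamically incompatible with K_donor and loadings)",
         call. = FALSE)
  S * (1 - x) / (x * (P0 - S))
}

#' Infer the donor phosphorolysis constant from an observed conversion
#'
#' Calibration counterpart of [infer_K_product()], with the roles of the two
#' constraints swapped: the sugar-phosphate concentration follows in closed
#' form from the product constraint, after which the donor constant follows
#' algebraically. This is how the donor constant is calibrated from a printed
#' conversion and product constant.
#'
#' @inheritParams infer_K_product
#' @param K_product Phosphorolysis equilibrium constant of the product
#'   nucleoside.
#'
#' @return The donor phosphorolysis constant (dimensionless scalar).
#' @export
infer_K_donor <- function(mix, K_product, observed_conversion) {
  mix <- .as_mix(mix)
  .check_observed_conversion(mix, observed_conversion)
  if (!is.finite(K_product) || K_product <= 0)
    stop("K_product must be finite and > 0", call. = FALSE)
  x <- observed_conversion
  D0 <- mix[["donor_0"]]; B0 <- mix[["base_0"]]; P0 <- mix[["phosphate_0"]]
  S <- .s_from_product_constraint(x, K_product, P0)
  Nd <- D0 - x * B0 - S
  if (Nd <= 0)
    stop("inconsistent observation: implied donor nucleoside concentration <= 0",
         call. = FALSE)
  S * (x * B0 + S) / (Nd * (P0 - S))
}

.as_mix <- function(mix) {
  if (inherits(mix, "transgly_system")) return(mix$mix)
  need <- c("donor_0", "base_0", "phosphate_0")
  if (!is.numeric(mix) || !all(need %in% names(mix)))
    stop("mix must name donor_0, base_0 and phosphate_0 (mM)", call. = FALSE)
  mix[need]
}

#' Equilibrium conversion as a function of sugar-donor excess
#'
#' Scans the donor:base loading ratio and returns the equilibrium conversion at
#' each point. Under the default `"fixed"` phosphate policy the phosphate
#' loading stays at the absolute `phosphate_0` across the scan; under
#' `"proportional"` it scales with the donor (`phosphate_0 * excess`,
#' `phosphate_0` being the loading at unit excess).
#'
#' @param base_0 Acceptor nucleobase loading (mM).
#' @param phosphate_0 Phosphate loading (mM); see `phosphate_policy`.
#' @param constants Named numeric with `K_donor` and `K_product`.
#' @param excess_values Donor:base ratios to scan (> 0).
#' @param phosphate_policy `"fixed"` (default) or `"proportional"`.
#' @param rel_tol Solver tolerance, passed to [solve_equilibrium()].
#'
#' @return A data frame with columns `excess` and `conversion`. Under the
#'   fixed policy conversion is strictly increasing in excess.
#' @export
conversion_curve <- function(base_0, phosphate_0, constants, excess_values,
                             phosphate_policy = c("fixed", "proportional"),
                             rel_tol = 1e-9) {
  phosphate_policy <- match.arg(phosphate_policy)
  stopifnot(is.numeric(excess_values), all(excess_values > 0))
  conv <- vapply(excess_values, function(e) {
    P0 <- if (phosphate_policy == "fixed") phosphate_0 else phosphate_0 * e
    sys <- transgly_system(donor_0 = e * base_0, base_0 = base_0,
                           phosphate_0 = P0,
                           K_donor = constants[["K_donor"]],
                           K_product = constants[["K_product"]])
    solve_equilibrium(sys, rel_tol)$conversion
  }, numeric(1))
  data.frame(excess = excess_values, conversion = conv)
}

#' Smallest sugar-donor excess reaching a target conversion
#'
#' Bracketed search on the monotone conversion-versus-excess curve. If the
#' target is already attained at unit excess, 1 is returned; if it is still
#' unattained at `excess_cap`, an unattainable flag is returned rather than an
#' error, because practical excess ceilings are part of the optimization.
#'
#' @inheritParams conversion_curve
#' @param target_conversion Target conversion, in (0, 1).
#' @param excess_cap Largest excess considered (>= 1). Default 100.
#'
#' @return An object of class `required_excess`: list with `excess` (the
#'   smallest donor:base ratio attaining the target, or `NA` if unattainable),
#'   `attained` (logical), `target_conversion`, and `conversion_at_cap`.
#' @export
required_excess <- function(base_0, phosphate_0, constants, target_conversion,
                            excess_cap = 100,
                            phosphate_policy = c("fixed", "proportional"),
                            rel_tol = 1e-9) {
  phosphate_policy <- match.arg(phosphate_policy)
  if (!is.numeric(target_conversion) ||
      target_conversion <= 0 || target_conversion >= 1)
    stop("target_conversion must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(excess_cap) || excess_cap < 1)
    stop("excess_cap must be >= 1", call. = FALSE)
  conv_at <- function(e)
    conversion_curve(base_0, phosphate_0, constants, e,
                     phosphate_policy, rel_tol)$conversion
  out <- function(excess, attained, at_cap)
    structure(list(excess = excess, attained = attained,
                   target_conversion = target_conversion,
                   conversion_at_cap = at_cap),
              class = "required_excess")
  c_cap <- conv_at(excess_cap)
  if (c_cap < target_conversion) return(out(NA_real_, FALSE, c_cap))
  if (conv_at(1) >= target_conversion) return(out(1, TRUE, c_cap))
  e <- stats::uniroot(function(e) conv_at(e) - target_conversion,
                      c(1, excess_cap), tol = 1e-10)$root
  out(e, TRUE, c_cap)
}

#' @export
print.required_excess <- function(x, ...) {
  if (x$attained)
    cat(sprintf("Required donor excess for %.0f%% conversion: %.2f-fold\n",
                100 * x$target_conversion, x$excess))
  else
    cat(sprintf("Target %.0f%% unattainable within the excess cap (%.1f%% at cap)\n",
                100 * x$target_conversion, 100 * x$conversion_at_cap))
  invisible(x)
}

#' Brute-force grid oracle for the coupled equilibrium
#'
#' Exhaustive search over the two reaction extents (phosphorolysis,
#' glycosylation) on a feasible grid, minimizing the sum of squared
#' log-residuals of both equilibrium constraints. Deliberately independent of
#' [solve_equilibrium()]'s closed-form elimination; intended for validation,
#' agreeing with the solver to about `1/grid_n` in conversion.
#'
#' @param system A [transgly_system()].
#' @param grid_n Grid resolution per extent dimension (>= 200).
#'
#' @return A list mirroring `equilibrium_result`: `species`, extents,
#'   `conversion` and the achieved `loss`.
#' @export
gibbs_grid_oracle <- function(system, grid_n = 2000L) {
  stopifnot(inherits(system, "transgly_system"))
  if (grid_n < 200) stop("grid_n must be >= 200", call. = FALSE)
  D0 <- system$mix[["donor_0"]]
  B0 <- system$mix[["base_0"]]
  P0 <- system$mix[["phosphate_0"]]
  Kd <- system$constants[["K_donor"]]
  Kp <- system$constants[["K_product"]]
  stopifnot(D0 > 0, B0 > 0, P0 > 0)

  # glycosylation extent xi2 in (0, min(B0, D0)); for each, phosphorolysis
  # extent xi1 in (xi2, min(D0, xi2 + P0)) keeps all six species positive
  n <- as.integer(grid_n)
  xi2 <- seq(0, min(B0, D0), length.out = n + 2L)[2:(n + 1L)]
  tfrac <- seq(0, 1, length.out = n + 2L)[2:(n + 1L)]
  upper <- pmin(D0, xi2 + P0)
  xi1 <- outer(tfrac, upper - xi2) + rep(xi2, each = n)  # n x n, col = xi2
  S  <- xi1 - rep(xi2, each = n)
  Pi <- P0 - S
  logQ1 <- log(S) + log(xi1) - log(D0 - xi1) - log(Pi)
  logQ2 <- log(S) + rep(log(B0 - xi2), each = n) -
    rep(log(xi2), each = n) - log(Pi)
  loss <- (logQ1 - log(Kd))^2 + (logQ2 - log(Kp))^2
  i <- arrayInd(which.min(loss), dim(loss))
  b_xi1 <- xi1[i[1], i[2]]
  b_xi2 <- xi2[i[2]]
  sp <- c(donor_nucleoside = D0 - b_xi1,
          donor_base = b_xi1,
          acceptor_base = B0 - b_xi2,
          product_nucleoside = b_xi2,
          pentose1P = b_xi1 - b_xi2,
          phosphate = P0 - (b_xi1 - b_xi2))
  list(species = sp,
       extent_phosphorolysis = b_xi1,
       extent_glycosylation = b_xi2,
       conversion = b_xi2 / B0,
       loss = loss[i[1], i[2]])
}
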