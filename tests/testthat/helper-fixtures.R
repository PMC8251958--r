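# Shared fixtures built in code.

# Two well-separated Gaussian-band reference states: a protonated base
# absorbing near 270 nm and a deprotonated base with lambda_max at 307 nm.
two_state_refs <- function(grid = 250:350) {
  make_references(
    list(prot   = data.frame(center_nm = 270, width_nm = 12, amplitude_au = 0.8),
         deprot = data.frame(center_nm = 307, width_nm = 15, amplitude_au = 1.0)),
    grid = grid)
}

# Random transglycosylation system with constants and loadings log-uniform
# over 10^[lo, hi] (assumes the caller has seeded the RNG).
random_system <- function(lo = -2, hi = 2) {
  K <- 10^stats::runif(2, lo, hi)
  L <- 10^stats::runif(3, lo, hi)
  transgly_system(donor_0 = L[1], base_0 = L[2], phosphate_0 = L[3],
                  K_donor = K[1], K_product = K[2])
}

# The study's analytical mix: 1 mM acceptor base, 5-fold donor excess,
# 0.09 equivalents of phosphate vs the base.
study_mix <- c(donor_0 = 5, base_0 = 1, phosphate_0 = 0.09)

# Closed-form zero-phosphate limit of the conversion: root of
# K_donor/K_product = x^2 B0 / ((D0 - x B0)(1 - x)) in (0, min(1, D0/B0)).
closed_form_limit <- function(K_donor, K_product, D0, B0) {
  kap <- K_donor / K_product
  roots <- polyroot(c(kap * D0, -kap * (D0 + B0), B0 * (kap - 1)))
  x <- Re(roots[abs(Im(roots)) < 1e-9])
  x[x > 0 & x < min(1, D0 / B0)][1]
}

# Fresh scratch directory under the session tempdir.
local_scratch_dir <- function() {
  d <- tempfile("transglyq-test-")
  dir.create(d)
  d
}
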