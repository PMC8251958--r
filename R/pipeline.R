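# Config-driven orchestration: bundled study systems table, the
# calibrate-then-predict workflow over it, and thin pKa / activity runners
# producing machine-readable reports that embed their exact configuration.

#' Bundled transglycosylation systems table
#'
#' The four analytical transglycosylation systems of the study: 1 mM 2-Se
#' nucleobase (2-Se-uracil `1` or 2-Se-thymine `2`), fivefold sugar-donor
#' excess (uridine `a` or thymidine `b`, 5 mM) and 0.09 equivalents of
#' phosphate relative to the nucleobase (0.09 mM), with the observed
#' equilibrium conversions and the product phosphorolysis constants determined
#' from them. Donor constants are not tabulated; they are calibrated with
#' [infer_K_donor()].
#'
#' @param path Optional path to a systems-table CSV with columns `label`,
#'   `donor`, `acceptor`, `D0_mM`, `B0_mM`, `P0_mM`, and optionally `K_donor`,
#'   `K_product`, `observed_conversion_pct`. Default: the bundled table.
#' @return A data frame, one row per system.
#' @export
table1_systems <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transgly_systems.csv",
                        package = "transglyq", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("label", "donor", "acceptor", "D0_mM", "B0_mM", "P0_mM")
  if (!all(need %in% names(df)))
    stop("systems table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Calibrate donor constants and predict conversions at higher donor excess
#'
#' For each system row: calibrates the donor phosphorolysis constant from the
#' observed conversion and the product constant (unless `K_donor` is given),
#' forward-solves the coupled equilibrium at `predict_excess`-fold donor
#' excess (phosphate held at the row's absolute `P0_mM`), and finds the donor
#' excess required for `target_conversion`. Rows that fail validation produce
#' an error record; the run continues.
#'
#' @param systems Systems table as from [table1_systems()].
#' @param predict_excess Donor:base ratio for the forward prediction.
#'   Default 10.
#' @param target_conversion Target for the required-excess search.
#'   Default 0.5.
#' @param excess_cap Cap for the required-excess search. Default 100.
#' @param rel_tol Solver tolerance. Default 1e-9.
#' @return A data frame of class `table1_report` with one row per system:
#'   `label`, `K_donor`, `K_product`, `observed_conversion_pct`,
#'   `predicted_conversion_pct` (at `predict_excess`), `required_excess`
#'   (for `target_conversion`; `NA` if unattainable within the cap) and
#'   `error` (`NA` for clean rows). The configuration used is attached as the
#'   `config` attribute.
#' @examples
#' \donttest{
#' rep <- reproduce_table1()
#' rep[, c("label", "K_donor", "predicted_conversion_pct", "required_excess")]
#' }
#' @export
reproduce_table1 <- function(systems = table1_systems(), predict_excess = 10,
                             target_conversion = 0.5, excess_cap = 100,
                             rel_tol = 1e-9) {
  config <- list(predict_excess = predict_excess,
                 target_conversion = target_conversion,
                 excess_cap = excess_cap, rel_tol = rel_tol)
  if (nrow(systems) == 0) {
    warning("empty systems table: nothing to compute", call. = FALSE)
    out <- data.frame(label = character(), K_donor = numeric(),
                      K_product = numeric(),
                      observed_conversion_pct = numeric(),
                      predicted_conversion_pct = numeric(),
                      required_excess = numeric(), error = character())
    return(structure(out, class = c("table1_report", "data.frame"),
                     config = config))
  }
  rows <- lapply(seq_len(nrow(systems)), function(i) {
    row <- systems[i, ]
    rec <- data.frame(label = row$label, K_donor = NA_real_,
                      K_product = NA_real_,
                      observed_conversion_pct = NA_real_,
                      predicted_conversion_pct = NA_real_,
                      required_excess = NA_real_, error = NA_character_)
    tryCatch({
      mix <- c(donor_0 = row$D0_mM, base_0 = row$B0_mM,
               phosphate_0 = row$P0_mM)
      Kp <- row$K_product
      x_obs <- if (!is.null(row$observed_conversion_pct))
        row$observed_conversion_pct / 100 else NA_real_
      Kd <- if (!is.null(row$K_donor) && !is.na(row$K_donor)) row$K_donor
            else infer_K_donor(mix, Kp, x_obs)
      constants <- c(K_donor = Kd, K_product = Kp)
      sys10 <- transgly_system(donor_0 = predict_excess * row$B0_mM,
                               base_0 = row$B0_mM, phosphate_0 = row$P0_mM,
                               K_donor = Kd, K_product = Kp)
      pred <- solve_equilibrium(sys10, rel_tol)$conversion
      req <- required_excess(row$B0_mM, row$P0_mM, constants,
                             target_conversion, excess_cap,
                             rel_tol = rel_tol)
      rec$K_donor <- Kd
      rec$K_product <- Kp
      rec$observed_conversion_pct <- 100 * x_obs
      rec$predicted_conversion_pct <- 100 * pred
      rec$required_excess <- req$excess
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
  })
  structure(do.call(rbind, rows),
            class = c("table1_report", "data.frame"), config = config)
}

# -- run configuration ------------------------------------------------------

.runconfig_keys <- c(
  "titration_csv", "refs_csv", "timecourse_csv", "peaks_csv", "systems_csv",
  "out_json", "seed", "rel_tol", "deprot", "substrate_0_mM",
  "enzyme_conc_mg_ml", "volume_ml", "linear_fraction_max",
  "phosphate_policy", "predict_excess", "target_conversion", "excess_cap",
  "rt_tolerance_min", "target", "include", "wavelength_nm"
)

#' Validated run configuration
#'
#' Flat key-value configuration for the pipeline runners. Unknown keys are
#' rejected so typos fail loudly instead of silently falling back to a
#' default.
#'
#' @param ... Named configuration entries; see [run_pka()] and
#'   [run_activity()] for the keys each runner reads.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all configuration entries must be named", call. = FALSE)
  unknown <- setdiff(names(cfg), .runconfig_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

.cfg_get <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required)
    stop("configuration key '", key, "' is required", call. = FALSE)
  default
}

.require_file <- function(path, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  path
}

#' Run a pKa determination from files
#'
#' Reads a titration CSV (`wavelength_nm`, `absorbance_au`, `pH`) and a
#' reference CSV (`wavelength_nm` plus one column per reference state), fits
#' the protonation model and returns a report embedding the configuration.
#' Keys read: `titration_csv`, `refs_csv` (required), `deprot`, `out_json`.
#'
#' @param config A [run_config()].
#' @return List of class `pka_report` with `fit` (a [fit_pka()] result) and
#'   `config`; written to `out_json` as JSON when that key is set.
#' @export
run_pka <- function(config) {
  stopifnot(inherits(config, "run_config"))
  series <- read_titration_csv(
    .require_file(.cfg_get(config, "titration_csv", required = TRUE),
                  "titration"))
  refs <- read_reference_csv(
    .require_file(.cfg_get(config, "refs_csv", required = TRUE), "reference"))
  fit <- fit_pka(series, refs, deprot = .cfg_get(config, "deprot"))
  report <- structure(list(fit = fit, config = unclass(config)),
                      class = "pka_report")
  out <- .cfg_get(config, "out_json")
  if (!is.null(out)) write_report_json(report, out)
  report
}

#' Run a specific-activity determination from files
#'
#' Reads a time-course CSV (`time_min`, `product_mM`) and computes the
#' initial-rate specific activity. Keys read: `timecourse_csv`,
#' `substrate_0_mM`, `enzyme_conc_mg_ml` (required), `volume_ml`,
#' `linear_fraction_max`, `out_json`.
#'
#' @param config A [run_config()].
#' @return List of class `activity_report` with `result` (a
#'   [specific_activity()] result) and `config`; written to `out_json` as
#'   JSON when that key is set.
#' @export
run_activity <- function(config) {
  stopifnot(inherits(config, "run_config"))
  course <- utils::read.csv(
    .require_file(.cfg_get(config, "timecourse_csv", required = TRUE),
                  "time-course"))
  res <- specific_activity(
    course,
    substrate_0 = .cfg_get(config, "substrate_0_mM", required = TRUE),
    enzyme_conc = .cfg_get(config, "enzyme_conc_mg_ml", required = TRUE),
    volume = .cfg_get(config, "volume_ml", 1),
    linear_fraction_max = .cfg_get(config, "linear_fraction_max", 0.15))
  report <- structure(list(result = res, config = unclass(config)),
                      class = "activity_report")
  out <- .cfg_get(config, "out_json")
  if (!is.null(out)) write_report_json(report, out)
  report
}

# -- CSV / JSON interfaces --------------------------------------------------

#' Read a spectrum CSV (`wavelength_nm`, `absorbance_au`)
#' @param path File path.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  uv_spectrum(df$wavelength_nm, df$absorbance_au)
}

#' Read a reference-set CSV (`wavelength_nm` plus one column per reference)
#' @param path File path.
#' @return A [reference_set()].
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  do.call(reference_set,
          c(list(wavelength_nm = df$wavelength_nm),
            as.list(df[setdiff(names(df), "wavelength_nm")])))
}

#' Read a titration CSV (`wavelength_nm`, `absorbance_au`, `pH`)
#' @param path File path.
#' @return A `titration_series` data frame.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pH", "wavelength_nm", "absorbance_au")
  if (!all(need %in% names(df)))
    stop("titration CSV must have columns pH, wavelength_nm, absorbance_au",
         call. = FALSE)
  structure(df[need], class = c("titration_series", "data.frame"))
}

#' Read an HPLC peak-table CSV (`rt_min`, `wavelength_nm`, `area`)
#' @param path File path.
#' @return A [peak_table()].
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path)
  peak_table(df$rt_min, df$area, wavelength_nm = df$wavelength_nm,
             compound = if ("compound" %in% names(df)) df$compound
                        else NA_character_)
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Writes a generated data frame as CSV and its `ground_truth` attribute (plus
#' any extra provenance) as JSON next to it (`<path>.truth.json`), so every
#' synthetic dataset is self-describing.
#'
#' @param data A data frame from one of the `make_*` generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  truth <- attr(data, "ground_truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  invisible(path)
}

#' Write a pipeline report as JSON
#'
#' Serializes a report (including its embedded configuration, so the run is
#' round-trippable) with full numeric precision.
#'
#' @param report A report object (e.g. from [run_pka()], [run_activity()] or
#'   [reproduce_table1()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows", null = "null")
  invisible(path)
}
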