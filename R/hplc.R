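# HPLC peak-area conversion quantification. Species are identified by
# retention time; conversion of compound X is 100 * P_X / P_total where the
# peak areas are taken at a single quantification wavelength (307 nm for the
# selenium-containing species, both of which share lambda_max = 307 nm).

#' Construct an HPLC peak table
#'
#' @param rt_min Retention times (min, > 0).
#' @param area Integrated peak areas (AU*s, >= 0).
#' @param wavelength_nm Detection wavelength per peak. Default 307.
#' @param compound Optional compound labels (`NA` = unassigned).
#' @return A data frame of class `peak_table` with columns `rt_min`,
#'   `wavelength_nm`, `area`, `compound`.
#' @export
peak_table <- function(rt_min, area, wavelength_nm = 307,
                       compound = NA_character_) {
  stopifnot(all(rt_min > 0), all(area >= 0))
  structure(
    data.frame(rt_min = rt_min,
               wavelength_nm = rep_len(wavelength_nm, length(rt_min)),
               area = area,
               compound = rep_len(as.character(compound), length(rt_min)),
               stringsAsFactors = FALSE),
    class = c("peak_table", "data.frame")
  )
}

#' Typical retention times of the transglycosylation species
#'
#' Retention-time centers (min) for the 2-Se nucleobases (`1`, `2`), the sugar
#' donors uridine/thymidine (`a`, `b`), the free pentoses (`a''`, `b''`) and
#' the 2-Se nucleosides (`1a`, `1b`, `2a`, `2b`) under the isocratic/gradient
#' reversed-phase method used for quantification. The sugar-1-phosphates are
#' not UV-active and have no entry.
#'
#' @return Named numeric vector of retention-time centers (min).
#' @export
default_rt_map <- function() {
  c(`1` = 3.4, `2` = 6, a = 3.6, b = 8.6, `a''` = 3, `b''` = 4.5,
    `1a` = 7, `1b` = 12, `2a` = 12, `2b` = 13)
}

#' Assign peaks to compounds by retention-time windows
#'
#' Each peak is assigned to the unique window (center +/- tolerance)
#' containing its retention time; peaks in no window stay unassigned.
#' Overlapping windows are a configuration error.
#'
#' @param table A [peak_table()].
#' @param rt_map Named numeric vector of retention-time centers (min), e.g.
#'   [default_rt_map()].
#' @param tolerance Half-width of each window (min); a scalar or a named
#'   vector aligned with `rt_map`. Default 0.3.
#' @return The peak table with the `compound` column filled in.
#' @export
assign_peaks <- function(table, rt_map, tolerance = 0.3) {
  stopifnot(inherits(table, "peak_table"), is.numeric(rt_map),
            !is.null(names(rt_map)))
  tol <- rep_len(tolerance, length(rt_map))
  if (!is.null(names(tolerance))) tol <- tolerance[names(rt_map)]
  if (any(!is.finite(tol)) || any(tol <= 0))
    stop("tolerances must be > 0 for every compound", call. = FALSE)
  lo <- rt_map - tol
  hi <- rt_map + tol
  ord <- order(lo)
  if (any(hi[ord][-length(ord)] > lo[ord][-1]))
    stop("retention-time windows overlap; shrink the tolerances", call. = FALSE)
  table$compound <- vapply(table$rt_min, function(rt) {
    j <- which(rt >= lo & rt <= hi)
    if (length(j) == 1) names(rt_map)[j] else NA_character_
  }, character(1))
  table
}

# Se-species pairs for the default conversion denominator: each nucleobase
# with its nucleosides from either sugar donor.
.se_pair <- function(target) {
  pairs <- list(`1a` = c("1", "1a"), `1b` = c("1", "1b"),
                `2a` = c("2", "2a"), `2b` = c("2", "2b"),
                `1` = c("1", "1a", "1b"), `2` = c("2", "2a", "2b"))
  pairs[[target]]
}

#' Conversion from HPLC peak areas
#'
#' Computes `100 * P_target / P_total` at the quantification wavelength, where
#' `P_total` is the summed area of the included compounds. By default the
#' denominator is restricted to the selenium-containing species (the target
#' nucleoside and its parent nucleobase), since conversion is reported for the
#' nucleobase and the sugar donors absorb only weakly at 307 nm; pass
#' `include` explicitly for the literal all-peaks reading.
#'
#' @param table A [peak_table()] with assigned compounds.
#' @param target Compound label whose formation is quantified.
#' @param include Labels entering the denominator (must contain `target`).
#'   `NULL` (default) selects the Se-species pair for the standard labels.
#' @param wavelength Quantification wavelength (nm). Default 307.
#' @return An object of class `conversion_result`: list with `conversion_pct`,
#'   `numerator`, `denominator` and `included`.
#' @export
hplc_conversion <- function(table, target, include = NULL, wavelength = 307) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(include)) {
    include <- .se_pair(target)
    if (is.null(include))
      stop("no default denominator known for target '", target,
           "'; pass include= explicitly", call. = FALSE)
  }
  if (!target %in% include)
    stop("target must be among the included compounds", call. = FALSE)
  sub <- table[table$wavelength_nm == wavelength &
                 !is.na(table$compound) & table$compound %in% include, ]
  denom <- sum(sub$area)
  if (denom <= 0)
    stop("no signal: zero total peak area at the quantification wavelength",
         call. = FALSE)
  num <- sum(sub$area[sub$compound == target])
  structure(
    list(conversion_pct = 100 * num / denom,
         numerator = num, denominator = denom,
         included = sort(unique(sub$compound)),
         wavelength_nm = wavelength),
    class = "conversion_result"
  )
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf("Conversion: %.1f%% (areas %g / %g at %g nm; compounds: %s)\n",
              x$conversion_pct, x$numerator, x$denominator, x$wavelength_nm,
              paste(x$included, collapse = ", ")))
  invisible(x)
}
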