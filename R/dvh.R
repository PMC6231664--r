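#' Cumulative dose-volume histogram
#'
#' The central container of the package: for a single structure, the fraction
#' of structure volume receiving at least a given dose. Internally all DVHs
#' are relative (fractions in \[0, 1\]); the absolute structure volume is kept
#' alongside in `total_volume` so absolute queries (e.g. the reference-isodose
#' volume in cm^3 needed by conformity indices) remain available.
#'
#' @param structure_name Structure label, e.g. `"PTV"` or `"Rectum"`.
#' @param dose Numeric vector of dose points in Gy; strictly increasing,
#'   starting at 0.
#' @param fraction Numeric vector of cumulative volume fractions in \[0, 1\],
#'   one per dose point; must start at 1 and be monotone non-increasing.
#' @param total_volume Absolute structure volume in cm^3 (> 0).
#' @param air_excluded Optional flag recording whether an air cavity (e.g. an
#'   endorectal balloon) was excluded from the structure before DVH export.
#'   Carried as metadata only; no computation depends on it.
#'
#' @return An object of class `cumulative_dvh`.
#' @export
cumulative_dvh <- function(structure_name, dose, fraction, total_volume,
                           air_excluded = NA) {
  stopifnot(is.character(structure_name), length(structure_name) == 1L)
  dose <- as.numeric(dose)
  fraction <- as.numeric(fraction)
  if (length(dose) != length(fraction))
    stop("dose and fraction must have equal length", call. = FALSE)
  if (length(dose) < 1L) stop("empty DVH", call. = FALSE)
  if (anyNA(dose) || anyNA(fraction))
    stop("NA values in DVH", call. = FALSE)
  if (!is.numeric(total_volume) || length(total_volume) != 1L ||
      is.na(total_volume) || total_volume <= 0)
    stop("total_volume must be a single positive number (cm^3)", call. = FALSE)
  if (dose[1L] != 0)
    stop("dose points must start at 0 Gy", call. = FALSE)
  if (length(dose) > 1L) {
    dd <- diff(dose)
    if (any(dd <= 0)) {
      i <- which(dd <= 0)[1L]
      stop(sprintf("dose points not strictly increasing at index %d (%.6g then %.6g)",
                   i + 1L, dose[i], dose[i + 1L]), call. = FALSE)
    }
    df <- diff(fraction)
    if (any(df > 1e-12)) {
      i <- which(df > 1e-12)[1L]
      stop(sprintf(
        "cumulative volume fraction increases at index %d (%.9g then %.9g); %s",
        i + 1L, fraction[i], fraction[i + 1L],
        "cumulative DVHs must be monotone non-increasing"), call. = FALSE)
    }
  }
  if (abs(fraction[1L] - 1) > 1e-9)
    stop("cumulative fraction must start at 1.0 (whole structure receives >= 0 Gy)",
         call. = FALSE)
  if (fraction[length(fraction)] < -1e-12)
    stop("negative volume fraction", call. = FALSE)
  structure(
    list(structure_name = structure_name,
         dose = dose,
         fraction = pmin(1, pmax(0, fraction)),
         total_volume = total_volume,
         air_excluded = air_excluded),
    class = "cumulative_dvh")
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("<cumulative DVH> %s: %d points, %.2f cm^3, D in [0, %.2f] Gy\n",
              x$structure_name, length(x$dose), x$total_volume, max(x$dose)))
  invisible(x)
}

#' Differential dose-volume histogram
#'
#' Bin centers `D_i` (Gy) with fractional volumes `v_i` summing to 1 — the
#' direct input of the generalized-mean EUD computation.
#'
#' @param structure_name Structure label.
#' @param bin_centers Strictly increasing bin-center doses in Gy.
#' @param fractional_volumes Non-negative fractions summing to 1 (within 1e-9).
#' @return An object of class `differential_dvh`.
#' @export
differential_dvh <- function(structure_name, bin_centers, fractional_volumes) {
  stopifnot(is.character(structure_name), length(structure_name) == 1L)
  bin_centers <- as.numeric(bin_centers)
  fractional_volumes <- as.numeric(fractional_volumes)
  if (length(bin_centers) == 0L)
    stop("differential DVH must have at least one bin", call. = FALSE)
  if (length(bin_centers) != length(fractional_volumes))
    stop("bin_centers and fractional_volumes must have equal length", call. = FALSE)
  if (anyNA(bin_centers) || anyNA(fractional_volumes))
    stop("NA values in differential DVH", call. = FALSE)
  if (length(bin_centers) > 1L && any(diff(bin_centers) <= 0))
    stop("bin centers must be strictly increasing", call. = FALSE)
  if (any(fractional_volumes < 0))
    stop("fractional volumes must be non-negative", call. = FALSE)
  s <- sum(fractional_volumes)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("fractional volumes must sum to 1 (got %.12g)", s), call. = FALSE)
  structure(
    list(structure_name = structure_name,
         bin_centers = bin_centers,
         fractional_volumes = fractional_volumes),
    class = "differential_dvh")
}

#' @export
print.differential_dvh <- function(x, ...) {
  cat(sprintf("<differential DVH> %s: %d bins, D in [%.2f, %.2f] Gy\n",
              x$structure_name, length(x$bin_centers),
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' One patient-plan variant: algorithm label, grid size and its DVHs
#'
#' @param patient_id Patient identifier.
#' @param algorithm Dose-calculation algorithm label (e.g. `"AAA"`, `"AXB"`).
#' @param grid_mm Dose-calculation grid size in mm.
#' @param dvhs Named list of [cumulative_dvh] objects, keyed by structure name.
#' @param prescription_dose Prescription dose in Gy (default 78).
#' @param n_fractions Number of fractions (default 39).
#' @param allowed_variants Data frame with columns `algorithm`, `grid_mm`
#'   giving the admissible (algorithm, grid) combinations; defaults to
#'   [default_variants()]. Pass `NULL` to skip the check.
#' @return An object of class `plan_dvh_set`.
#' @export
plan_dvh_set <- function(patient_id, algorithm, grid_mm, dvhs,
                         prescription_dose = 78, n_fractions = 39,
                         allowed_variants = default_variants()) {
  stopifnot(length(patient_id) == 1L, length(algorithm) == 1L,
            length(grid_mm) == 1L)
  if (!is.list(dvhs) || is.null(names(dvhs)) || any(names(dvhs) == ""))
    stop("dvhs must be a named list of cumulative_dvh objects", call. = FALSE)
  ok <- vapply(dvhs, inherits, logical(1L), "cumulative_dvh")
  if (!all(ok))
    stop("dvhs entries must be cumulative_dvh objects: ",
         paste(names(dvhs)[!ok], collapse = ", "), call. = FALSE)
  if (!is.null(allowed_variants)) {
    hit <- allowed_variants$algorithm == algorithm &
      allowed_variants$grid_mm == grid_mm
    if (!any(hit))
      stop(sprintf("variant (%s, %g mm) not in the allowed set [%s]",
                   algorithm, grid_mm,
                   paste0(allowed_variants$algorithm, allowed_variants$grid_mm,
                          collapse = ", ")), call. = FALSE)
  }
  if (prescription_dose <= 0) stop("prescription_dose must be > 0", call. = FALSE)
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id),
         algorithm = as.character(algorithm),
         grid_mm = as.numeric(grid_mm),
         prescription_dose = prescription_dose,
         n_fractions = as.integer(n_fractions),
         dvhs = dvhs),
    class = "plan_dvh_set")
}

#' @export
print.plan_dvh_set <- function(x, ...) {
  cat(sprintf("<plan DVH set> patient %s, %s %g mm, %g Gy / %d fx, structures: %s\n",
              x$patient_id, x$algorithm, x$grid_mm, x$prescription_dose,
              x$n_fractions, paste(names(x$dvhs), collapse = ", ")))
  invisible(x)
}

#' Default admissible (algorithm, grid size) combinations
#'
#' Grids of 1, 3 and 5 mm for the convolution/superposition-like algorithm
#' (AAA) and 1, 2 and 3 mm for the Boltzmann-solver-like algorithm (AXB) —
#' the six plan variants the cohort workflow compares by default.
#'
#' @return Data frame with columns `algorithm` and `grid_mm`.
#' @export
default_variants <- function() {
  data.frame(algorithm = rep(c("AAA", "AXB"), each = 3L),
             grid_mm = c(1, 3, 5, 1, 2, 3))
}

#' Variant short code, e.g. "AXB1"
#' @param algorithm Algorithm label.
#' @param grid_mm Grid size in mm.
#' @return Character vector of codes.
#' @export
variant_code <- function(algorithm, grid_mm) paste0(algorithm, grid_mm)

# linear interpolation of the cumulative fraction at arbitrary doses;
# above the curve support the fraction is 0 by convention.
.cum_fraction_at <- function(cdvh, d) {
  n <- length(cdvh$dose)
  if (n == 1L) return(ifelse(d <= cdvh$dose, cdvh$fraction, 0))
  f <- stats::approx(cdvh$dose, cdvh$fraction, xout = pmin(d, max(cdvh$dose)),
                     method = "linear", rule = 2)$y
  f[d > max(cdvh$dose)] <- 0
  f[d < 0] <- 1
  f
}

#' Convert a cumulative DVH to a differential DVH
#'
#' The mass in each bin is the drop of the cumulative fraction across the bin
#' (cumulative interpolated linearly at bin edges); bin centers are the
#' arithmetic bin midpoints. Residual volume above the last dose point of the
#' curve — a cumulative curve that does not reach zero — is assigned to the
#' terminal bin so that the fractional volumes always sum to 1.
#'
#' @param cdvh A [cumulative_dvh].
#' @param bin_width Bin width in Gy (> 0); default 0.1 Gy, fine enough that
#'   EUD is bin-width stable to < 0.1\% for smooth curves.
#' @return A [differential_dvh].
#' @export
cumulative_to_differential <- function(cdvh, bin_width = 0.1) {
  stopifnot(inherits(cdvh, "cumulative_dvh"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number (Gy)", call. = FALSE)
  dmax <- max(cdvh$dose)
  n_bins <- max(1L, as.integer(ceiling(dmax / bin_width - 1e-12)))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  cf <- .cum_fraction_at(cdvh, pmin(edges, dmax))
  v <- -diff(cf)
  # residual volume at/above the final edge goes to the terminal bin
  v[n_bins] <- v[n_bins] + cf[n_bins + 1L]
  v[v < 0 & v > -1e-12] <- 0
  centers <- edges[-1L] - bin_width / 2
  # sum(v) telescopes to cf[1] = 1; division only sheds rounding residue
  differential_dvh(cdvh$structure_name, centers, v / sum(v))
}

#' Convert a differential DVH back to a cumulative DVH
#'
#' Bin mass is treated as concentrated at the bin center, so the cumulative
#' fraction at dose d is the tail sum of `v_i` over bins with center >= d.
#' Because cumulative dose points must be strictly increasing, the staircase
#' drop after each center is represented by a 1e-9-Gy-wide linear segment;
#' evaluated at bin edges the reconstruction is exact.
#'
#' @param ddvh A [differential_dvh].
#' @param total_volume Absolute volume (cm^3) for the resulting cumulative
#'   DVH; default 1.
#' @return A [cumulative_dvh].
#' @export
differential_to_cumulative <- function(ddvh, total_volume = 1) {
  stopifnot(inherits(ddvh, "differential_dvh"))
  cen <- ddvh$bin_centers
  v <- ddvh$fractional_volumes
  eps <- 1e-9
  if (length(cen) > 1L) eps <- min(eps, min(diff(cen)) / 4)
  tail_before <- rev(cumsum(rev(v)))      # fraction at each center (inclusive)
  tail_after <- c(tail_before[-1L], 0)    # fraction just above each center
  d <- as.numeric(rbind(cen, cen + eps))
  f <- as.numeric(rbind(tail_before, tail_after))
  if (cen[1L] > eps) {
    d <- c(0, d)
    f <- c(1, f)
  } else if (cen[1L] != 0) {
    stop("first bin center must be 0 or larger than the step width", call. = FALSE)
  }
  cumulative_dvh(ddvh$structure_name, d, f, total_volume)
}

#' Dose received by the hottest `fraction` of the structure (D_x)
#'
#' Smallest dose at which the cumulative fraction equals `fraction`, by linear
#' interpolation between bracketing curve points. On flat segments the lowest
#' dose is returned. `fraction = 0.5` is the median dose D50. `fraction = 1`
#' follows the plan-minimum-dose convention and returns the highest dose still
#' covering the full structure.
#'
#' @param cdvh A [cumulative_dvh].
#' @param fraction Volume fraction in (0, 1]. D2 is `fraction = 0.02`.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(cdvh, fraction) {
  stopifnot(inherits(cdvh, "cumulative_dvh"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  d <- cdvh$dose
  f <- cdvh$fraction
  if (fraction >= 1 - 1e-12) {
    return(d[max(which(f >= 1 - 1e-12))])
  }
  # first point at or below the requested fraction
  i <- which(f <= fraction)[1L]
  if (is.na(i)) return(d[length(d)])          # curve never reaches `fraction`
  if (f[i] == fraction) return(d[i])          # exact hit; ties -> lowest dose
  if (i == 1L) return(d[1L])
  d[i - 1L] + (f[i - 1L] - fraction) / (f[i - 1L] - f[i]) * (d[i] - d[i - 1L])
}

#' Fraction of structure volume receiving at least a dose
#'
#' @param cdvh A [cumulative_dvh].
#' @param dose Dose in Gy (>= 0). Doses above the curve support return 0.
#' @return Volume fraction in \[0, 1\].
#' @export
volume_at_dose <- function(cdvh, dose) {
  stopifnot(inherits(cdvh, "cumulative_dvh"))
  if (!is.numeric(dose) || anyNA(dose) || any(dose < 0))
    stop("dose must be non-negative (Gy)", call. = FALSE)
  .cum_fraction_at(cdvh, dose)
}

#' Percent volume receiving at least x percent of the prescription dose (V_x%)
#'
#' @param cdvh A [cumulative_dvh].
#' @param x Percent of the prescription dose (e.g. 95 for V_95%).
#' @param prescription Prescription dose in Gy.
#' @return Percent of structure volume (0-100).
#' @export
v_x_percent <- function(cdvh, x, prescription) {
  stopifnot(is.numeric(x), is.numeric(prescription), prescription > 0)
  100 * volume_at_dose(cdvh, x / 100 * prescription)
}

#' Summary doses of a cumulative DVH
#'
#' Median is the interpolated D50; mean is the exact integral of the
#' cumulative curve (the zero-bin-width limit of the differential-DVH mean
#' sum); minimum is the highest dose still covering the whole structure and
#' maximum the lowest dose at which the covered fraction reaches zero (the
#' curve end if it never does).
#'
#' @param cdvh A [cumulative_dvh] with at least two dose points.
#' @return Named list with elements `min`, `max`, `mean`, `median` (Gy).
#' @export
dvh_summary <- function(cdvh) {
  stopifnot(inherits(cdvh, "cumulative_dvh"))
  d <- cdvh$dose
  f <- cdvh$fraction
  if (length(d) < 2L)
    stop("degenerate single-point DVH: summary doses undefined", call. = FALSE)
  dmin <- d[max(which(f >= 1 - 1e-12))]
  zero <- which(f <= 1e-12)
  dmax <- if (length(zero)) d[zero[1L]] else d[length(d)]
  dmean <- sum(diff(d) * (f[-1L] + f[-length(f)]) / 2)  # trapezoid of E[D]
  list(min = dmin, max = dmax, mean = dmean, median = dose_at_volume(cdvh, 0.5))
}
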