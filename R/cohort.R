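#' Effect model of the synthetic plan-variant generator
#'
#' Encodes, in DVH space, the systematic differences between plan variants
#' that the cohort analysis is meant to detect. No radiation transport is
#' simulated: algorithm and grid effects are shape-parameter shifts applied
#' deterministically to each patient's base anatomy.
#'
#' Defaults are calibrated to cohort-level differences reported for a
#' published 20-patient prostate VMAT comparison of a
#' convolution/superposition algorithm (AAA-like) against a Boltzmann-solver
#' algorithm (AXB-like): a PTV V_95% gap of about 2.4 percentage points
#' (driven by the AAA-like algorithm over-predicting dose in the endorectal
#' balloon air cavity that overlaps the PTV), a rectal mean-dose gap of 2.87%
#' of the prescription dose, and a strong grid-size sensitivity of the
#' AAA-like algorithm's dose falloff.
#'
#' @param air_overlap_fraction Fraction of the PTV overlapping the rectal air
#'   cavity (the PTV subvolume that the Boltzmann-like algorithm reports as
#'   under-dosed); default 0.034.
#' @param aaa_air_coverage_boost Percentage points of PTV V_95% added to the
#'   AAA-like variants inside the overlap region; default 2.4.
#' @param grid_falloff_blur Named numeric: Gy of dose-edge softening per mm
#'   of grid beyond 1 mm, per algorithm; default `c(AAA = 0.8, AXB = 0.1)`.
#' @param rectum_dose_shift Percent of the prescription dose added to the
#'   AAA-like rectal dose (implemented as a uniform rightward shift of the
#'   rectal curve, so the cohort mean-dose gap equals this setting exactly);
#'   default 2.87.
#' @param patient_sd Per-patient random-effect scales: `ptv_center` (Gy),
#'   `ptv_width` (Gy), `air` (fraction), `rectum_shoulder` (fraction),
#'   `organ_scale` (log-scale).
#' @param variant_sd Per-(patient, variant) residual noise scales: `center`
#'   (Gy), `air` (fraction), `shift` (Gy).
#' @return List of class `effect_model`.
#' @export
effect_model <- function(air_overlap_fraction = 0.034,
                         aaa_air_coverage_boost = 2.4,
                         grid_falloff_blur = c(AAA = 0.8, AXB = 0.1),
                         rectum_dose_shift = 2.87,
                         patient_sd = list(ptv_center = 0.2, ptv_width = 0.1,
                                           air = 0.006, rectum_shoulder = 0.02,
                                           organ_scale = 0.05),
                         variant_sd = list(center = 0.03, air = 0.0015,
                                           shift = 0.08)) {
  stopifnot(air_overlap_fraction >= 0, air_overlap_fraction <= 1,
            aaa_air_coverage_boost >= 0,
            all(grid_falloff_blur >= 0), is.finite(rectum_dose_shift))
  if (air_overlap_fraction < aaa_air_coverage_boost / 100)
    stop("air_overlap_fraction must be >= aaa_air_coverage_boost/100 (the boost cannot exceed the air overlap)",
         call. = FALSE)
  structure(list(air_overlap_fraction = air_overlap_fraction,
                 aaa_air_coverage_boost = aaa_air_coverage_boost,
                 grid_falloff_blur = grid_falloff_blur,
                 rectum_dose_shift = rectum_dose_shift,
                 patient_sd = patient_sd, variant_sd = variant_sd),
            class = "effect_model")
}

#' Zero-effect, zero-noise effect model (null generator)
#' @return An [effect_model] in which every variant equals the patient base.
#' @export
null_effect_model <- function() {
  effect_model(air_overlap_fraction = 0.034, aaa_air_coverage_boost = 0,
               grid_falloff_blur = c(AAA = 0, AXB = 0), rectum_dose_shift = 0,
               patient_sd = list(ptv_center = 0, ptv_width = 0, air = 0,
                                 rectum_shoulder = 0, organ_scale = 0),
               variant_sd = list(center = 0, air = 0, shift = 0))
}

#' Specification of a synthetic patient cohort
#'
#' @param n_patients Number of patients (default 20).
#' @param seed Master seed; every random draw descends from it via
#'   counter-based stream splitting, so patient i is unchanged when patients
#'   are added.
#' @param prescription Prescription dose in Gy (default 78).
#' @param n_fractions Number of fractions (default 39).
#' @param variants Data frame of (algorithm, grid_mm) combinations; default
#'   [default_variants()].
#' @param effects An [effect_model].
#' @param dose_grid_points Dose axis of the generated cumulative DVHs (Gy).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20L, seed = 1L, prescription = 78,
                        n_fractions = 39L, variants = default_variants(),
                        effects = effect_model(),
                        dose_grid_points = seq(0, 90, by = 0.1)) {
  stopifnot(n_patients >= 1, inherits(effects, "effect_model"),
            prescription > 0, n_fractions >= 1)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 prescription = prescription,
                 n_fractions = as.integer(n_fractions),
                 variants = variants, effects = effects,
                 dose_grid_points = dose_grid_points),
            class = "cohort_spec")
}

# counter-based stream splitting: two Lehmer steps keep intermediate
# products below 2^53 and the result in [0, 2^31-2]
.sub_seed <- function(seed, patient, k) {
  m <- 2147483647
  h <- seed %% m
  h <- (h * 48271 + patient * 2 + 1) %% m
  h <- (h * 48271 + k * 2 + 1) %% m
  as.integer(h)
}

.blur_of <- function(effects, algorithm, grid_mm) {
  b <- effects$grid_falloff_blur
  bl <- if (algorithm %in% names(b)) b[[algorithm]] else 0
  bl * max(0, grid_mm - 1)
}

# survival function of a scaled beta component on [lo, hi]
.sbeta <- function(d, lo, hi, shape1, shape2) {
  1 - stats::pbeta(pmin(pmax((d - lo) / (hi - lo), 0), 1), shape1, shape2)
}

# patient-level anatomy/plan parameters, drawn from stream (seed, i, 0)
.draw_patient_base <- function(spec, i) {
  eff <- spec$effects
  psd <- eff$patient_sd
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  withr_seed <- .sub_seed(spec$seed, i, 0L)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  list(
    ptv_m = 79.6 + stats::rnorm(1) * psd$ptv_center,
    ptv_s = max(0.4, 0.8 + stats::rnorm(1) * psd$ptv_width),
    w_hot = clamp(0.02 + stats::rnorm(1) * 0.25 * psd$rectum_shoulder, 0.005, 0.05),
    w_air = clamp(eff$air_overlap_fraction + stats::rnorm(1) * psd$air,
                  eff$aaa_air_coverage_boost / 100, 0.08),
    rect_sh_w = clamp(0.12 + stats::rnorm(1) * psd$rectum_shoulder, 0.04, 0.25),
    rect_bulk_b = 2.5 * exp(stats::rnorm(1) * psd$organ_scale),
    blad_w_tail = clamp(0.05 + stats::rnorm(1) * 0.2 * psd$rectum_shoulder, 0.01, 0.12),
    blad_bulk_b = 3.6 * exp(stats::rnorm(1) * psd$organ_scale),
    fem_scale_l = exp(stats::rnorm(1) * psd$organ_scale),
    fem_scale_r = exp(stats::rnorm(1) * psd$organ_scale),
    tv = max(30, 88 + stats::rnorm(1) * 10),
    rect_vol = max(60, 120 + stats::rnorm(1) * 15),
    blad_vol = max(80, 200 + stats::rnorm(1) * 40),
    fem_vol_l = max(100, 180 + stats::rnorm(1) * 20),
    fem_vol_r = max(100, 180 + stats::rnorm(1) * 20),
    body_vol = max(4000, 9000 + stats::rnorm(1) * 600),
    spill_frac = clamp(0.095 + stats::rnorm(1) * 0.01, 0.02, 0.2))
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# shift a cumulative curve rightward by delta Gy (uniform dose offset);
# negative delta shifts left. Fraction at 0 Gy is pinned to 1.
.shift_curve <- function(d, f_of, delta) {
  .tidy_fraction(f_of(pmax(0, d - delta)))
}

# pin the 0-Gy point to 1 and clamp sub-1e-12 tail fractions to exact zero
# (keeps D_max at the physical curve end and text exports compact)
.tidy_fraction <- function(f) {
  f[f < 1e-12] <- 0
  f[1L] <- 1
  f
}

#' Generate one synthetic patient: all plan variants
#'
#' Draws the patient's base anatomy (PTV plateau position/width, air-overlap
#' fraction, rectal shoulder, organ volumes, ...) from the stream
#' (seed, patient_index, 0), then derives each plan variant deterministically
#' from the base via the [effect_model]: the AAA-like algorithm gains
#' coverage inside the air overlap and a uniform rectal dose shift; both
#' algorithms lose dose-edge sharpness with growing grid size. Reproducible:
#' the same (seed, patient_index) always yields bitwise-identical output.
#'
#' @param spec A [cohort_spec].
#' @param patient_index Patient number (1-based).
#' @return Named list (by variant code) of [plan_dvh_set] objects.
#' @export
generate_patient <- function(spec, patient_index) {
  stopifnot(inherits(spec, "cohort_spec"), patient_index >= 1)
  base <- .draw_patient_base(spec, patient_index)
  eff <- spec$effects
  vsd <- eff$variant_sd
  d <- spec$dose_grid_points
  pid <- sprintf("P%02d", patient_index)
  out <- list()
  for (k in seq_len(nrow(spec$variants))) {
    alg <- spec$variants$algorithm[k]
    grid <- spec$variants$grid_mm[k]
    old <- .Random.seed_store()
    set.seed(.sub_seed(spec$seed, patient_index, k))
    jit <- stats::rnorm(5L)
    .Random.seed_restore(old)
    jit_m <- jit[1L] * vsd$center
    jit_air <- jit[2L] * vsd$air
    jit_rect <- jit[3L] * vsd$shift
    jit_blad <- jit[4L] * vsd$shift * 0.5
    jit_fem <- jit[5L] * vsd$shift * 0.5

    blur <- .blur_of(eff, alg, grid)
    is_aaa <- alg == "AAA"

    # --- PTV: sharp plateau + hotspot tail + cold air-overlap component
    m_var <- base$ptv_m + jit_m
    s_var <- base$ptv_s + blur
    w_air_var <- max(0, base$w_air - is_aaa * eff$aaa_air_coverage_boost / 100 +
                       jit_air)
    w_main <- 1 - base$w_hot - w_air_var
    # two-piece plateau: grid blur softens only the falloff (cold) side —
    # volumetric averaging erodes coverage, it does not create hotspots
    c_ptv <- function(x)
      w_main * stats::pnorm(x, m_var, ifelse(x < m_var, s_var, base$ptv_s),
                            lower.tail = FALSE) +
      base$w_hot * .sbeta(x, m_var + 0.5, m_var + 5.2, 1.2, 2) +
      w_air_var * .sbeta(x, 60, 73.5, 2, 2)
    f_ptv <- .tidy_fraction(c_ptv(d))

    # --- Rectum: low-dose bulk + PTV-overlap shoulder; AAA-like shift
    s_sh <- 0.5 * blur
    c_rect <- function(x)
      (1 - base$rect_sh_w) * .sbeta(x, 1.5, 74, 2, base$rect_bulk_b) +
      base$rect_sh_w * .sbeta(x, 70 - s_sh, 81 + s_sh, 2, 2)
    delta_rect <- is_aaa * eff$rectum_dose_shift / 100 * spec$prescription +
      jit_rect
    f_rect <- .shift_curve(d, c_rect, delta_rect)

    # --- Bladder: low/mid bulk + small hot tail near prescription
    c_blad <- function(x)
      (1 - base$blad_w_tail) * .sbeta(x, 0.8, 74, 1.3, base$blad_bulk_b) +
      base$blad_w_tail * .sbeta(x, 72 - s_sh, 83 + s_sh, 2, 2)
    f_blad <- .shift_curve(d, c_blad, jit_blad)

    # --- Femoral heads: bounded mid-dose curves
    c_fem <- function(scale) function(x) .sbeta(x, 2, 38, 3, 2.5 * scale)
    f_fem_l <- .shift_curve(d, c_fem(base$fem_scale_l), jit_fem)
    f_fem_r <- .shift_curve(d, c_fem(base$fem_scale_r), jit_fem)

    # --- Body: PTV + near-prescription spill + low-dose normal tissue
    spill <- base$spill_frac * base$tv
    rest <- base$body_vol - base$tv - spill
    f_body <- (base$tv * f_ptv +
                 spill * stats::pnorm(d, 76, 1.8 + 0.3 * blur, lower.tail = FALSE) +
                 rest * .sbeta(d, 0, 70, 0.8, 6)) / base$body_vol
    f_body <- .tidy_fraction(f_body)

    dvhs <- list(
      PTV = cumulative_dvh("PTV", d, f_ptv, base$tv),
      Rectum = cumulative_dvh("Rectum", d, f_rect, base$rect_vol),
      Bladder = cumulative_dvh("Bladder", d, f_blad, base$blad_vol),
      FemoralHead_L = cumulative_dvh("FemoralHead_L", d, f_fem_l, base$fem_vol_l),
      FemoralHead_R = cumulative_dvh("FemoralHead_R", d, f_fem_r, base$fem_vol_r),
      BODY = cumulative_dvh("BODY", d, f_body, base$body_vol))
    out[[variant_code(alg, grid)]] <- plan_dvh_set(
      pid, alg, grid, dvhs,
      prescription_dose = spec$prescription, n_fractions = spec$n_fractions,
      allowed_variants = spec$variants)
  }
  out
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec].
#' @return Object of class `vmat_cohort`: list with `patients` (list of
#'   per-patient variant lists from [generate_patient()]) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- lapply(seq_len(spec$n_patients),
                     function(i) generate_patient(spec, i))
  names(patients) <- sprintf("P%02d", seq_len(spec$n_patients))
  structure(list(patients = patients, spec = spec), class = "vmat_cohort")
}

#' @export
print.vmat_cohort <- function(x, ...) {
  cat(sprintf("<vmat cohort> %d patients x %d variants, %g Gy / %d fx, seed %d\n",
              length(x$patients), nrow(x$spec$variants), x$spec$prescription,
              x$spec$n_fractions, x$spec$seed))
  invisible(x)
}

#' Specification of the synthetic 3D dose phantom
#'
#' An endorectal-balloon-like geometry on a voxel grid: a body cylinder, a
#' PTV ellipsoid, a posterior rectum containing a ~70 cm^3 air-cavity
#' ellipsoid that overlaps the PTV margin, a bladder and two femoral heads.
#' The dose field is a smooth plateau on the PTV with sigmoid falloff; the
#' AAA-like variants add a dose bump inside the air cavity, and grid size
#' widens the falloff.
#'
#' @param shape Voxel counts per axis (default `c(41, 41, 41)`).
#' @param spacing Voxel spacing in mm (default 4 mm isotropic).
#' @param variants Data frame of (algorithm, grid_mm); default
#'   [default_variants()].
#' @param air_bump Peak extra dose (Gy) inside the air cavity for AAA-like
#'   variants (default 2).
#' @param grid_blur Named mm-per-mm falloff widening per algorithm.
#' @param plateau_dose Plateau dose in Gy (default 80).
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(41L, 41L, 41L), spacing = c(4, 4, 4),
                         variants = default_variants(), air_bump = 2,
                         grid_blur = c(AAA = 0.8, AXB = 0.1),
                         plateau_dose = 80) {
  stopifnot(all(shape >= 5), all(spacing > 0), air_bump >= 0,
            all(grid_blur >= 0), plateau_dose > 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 variants = variants, air_bump = air_bump,
                 grid_blur = grid_blur, plateau_dose = plateau_dose),
            class = "phantom_spec")
}

#' Generate the dose phantom: one dose grid per variant plus structure masks
#'
#' @param spec A [phantom_spec].
#' @return List with `doses` (named list of [dose_grid] by variant code),
#'   `masks` (named list of [structure_mask]: PTV, Rectum, AirCavity,
#'   Bladder, FemoralHead_L, FemoralHead_R, BODY) and `origin`/`spacing`.
#' @export
generate_dose_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  sp <- spec$spacing
  origin <- -(sh - 1) / 2 * sp
  x <- origin[1] + (seq_len(sh[1]) - 1) * sp[1]
  y <- origin[2] + (seq_len(sh[2]) - 1) * sp[2]
  z <- origin[3] + (seq_len(sh[3]) - 1) * sp[3]
  X <- array(rep(x, times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(y, each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(z, each = sh[1] * sh[2]), dim = sh)

  ell <- function(c0, r) ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
    ((Z - c0[3]) / r[3])^2
  body <- (X^2 + Y^2) <= 76^2
  g_ptv <- sqrt(ell(c(0, -10, 0), c(28, 26, 28)))
  ptv <- g_ptv <= 1
  g_air <- ell(c(0, -48, 0), c(25, 25, 27))       # ~70.7 cm^3 air ellipsoid
  air <- g_air <= 1
  rectum <- ell(c(0, -48, 0), c(29, 29, 42)) <= 1
  bladder <- ell(c(0, 34, 4), c(30, 30, 25)) <= 1
  fem_l <- ell(c(-55, -18, 0), c(22, 22, 22)) <= 1
  fem_r <- ell(c(55, -18, 0), c(22, 22, 22)) <= 1

  if (!all(air[!body] == FALSE) || !any(ptv & air))
    stop("inconsistent phantom geometry: air cavity must lie inside the body and overlap the PTV margin",
         call. = FALSE)

  dist_mm <- (g_ptv - 1) * mean(c(28, 26, 28))
  bump_field <- spec$air_bump * pmax(0, 1 - g_air)

  doses <- list()
  for (k in seq_len(nrow(spec$variants))) {
    alg <- spec$variants$algorithm[k]
    grid <- spec$variants$grid_mm[k]
    bl <- if (alg %in% names(spec$grid_blur)) spec$grid_blur[[alg]] else 0
    w <- 3 + bl * max(0, grid - 1)
    base <- spec$plateau_dose / (1 + exp(dist_mm / w))
    if (alg == "AAA") base <- base + bump_field
    doses[[variant_code(alg, grid)]] <- dose_grid(base, origin, sp)
  }
  mk <- function(m) structure_mask(m, origin, sp)
  list(doses = doses,
       masks = list(PTV = mk(ptv), Rectum = mk(rectum), AirCavity = mk(air),
                    Bladder = mk(bladder), FemoralHead_L = mk(fem_l),
                    FemoralHead_R = mk(fem_r), BODY = mk(body)),
       origin = origin, spacing = sp)
}
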