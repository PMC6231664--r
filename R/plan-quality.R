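#' Homogeneity index
#'
#' HI = (D2 - D98) / D50, where D2, D98 and D50 are the doses to 2%, 98% and
#' 50% of the target volume. Lower values mean a more homogeneous target dose;
#' 0 is the homogeneous limit. Scale-invariant in dose.
#'
#' @param d2,d98,d50 Doses in Gy; `d50` must be positive and `d2 >= d98`.
#' @return Unitless index (>= 0).
#' @export
homogeneity_index <- function(d2, d98, d50) {
  if (!all(is.finite(c(d2, d98, d50))))
    stop("doses must be finite", call. = FALSE)
  if (d50 <= 0) stop("D50 must be positive", call. = FALSE)
  if (d2 < d98) stop("D2 must be >= D98 on a cumulative DVH", call. = FALSE)
  (d2 - d98) / d50
}

#' Conformity index
#'
#' CI = V_RI / TV: the reference-isodose volume inside the body divided by the
#' target volume. 1 is ideal; > 1 means the reference isodose spills beyond a
#' target-sized volume.
#'
#' @param v_ri Reference-isodose volume on the body (cm^3, >= 0).
#' @param tv Target (PTV) volume (cm^3, > 0).
#' @return Unitless index.
#' @export
conformity_index <- function(v_ri, tv) {
  if (tv <= 0) stop("target volume must be positive", call. = FALSE)
  if (v_ri < 0) stop("reference isodose volume must be >= 0", call. = FALSE)
  v_ri / tv
}

#' Conformation number
#'
#' CN = (TV_RI / TV) x (TV_RI / V_RI): target coverage by the reference
#' isodose times the fraction of the reference isodose that actually lies in
#' the target. In \[0, 1\]; 1 iff the reference isodose coincides with the
#' target.
#'
#' @param tv_ri Target volume covered by the reference isodose (cm^3).
#' @param tv Target volume (cm^3, > 0).
#' @param v_ri Reference-isodose volume (cm^3, > 0 — unlike [conformity_index],
#'   CN is undefined for an empty reference isodose).
#' @return Unitless index in \[0, 1\].
#' @export
conformation_number <- function(tv_ri, tv, v_ri) {
  if (tv <= 0) stop("target volume must be positive", call. = FALSE)
  if (v_ri <= 0)
    stop("conformation number undefined for empty reference isodose (V_RI = 0)",
         call. = FALSE)
  if (tv_ri < 0 || tv_ri > min(tv, v_ri) + 1e-9)
    stop("TV_RI must satisfy 0 <= TV_RI <= min(TV, V_RI)", call. = FALSE)
  (tv_ri / tv) * (tv_ri / v_ri)
}

#' Percent deviation of a metric from its reference value
#'
#' |Ref - Eval| / |Ref| x 100. Used to score each plan variant against the
#' reference variant (by default the Boltzmann-solver algorithm at the finest
#' grid).
#'
#' @param ref Reference metric value (nonzero).
#' @param eval Evaluated metric value.
#' @return Percent deviation (>= 0).
#' @export
percent_deviation <- function(ref, eval) {
  if (!all(is.finite(c(ref, eval)))) stop("values must be finite", call. = FALSE)
  if (ref == 0)
    stop("percent deviation undefined for a zero reference value", call. = FALSE)
  abs(ref - eval) / abs(ref) * 100
}

#' Target-dose indices from a PTV (and optionally body) DVH
#'
#' Derives the inputs of the homogeneity/conformity indices from cumulative
#' DVHs: D2/D98/D50 from the PTV curve, TV from the PTV volume, TV_RI from the
#' PTV volume fraction at the reference-isodose dose, and V_RI from the body
#' DVH at the same dose. Alternatively `v_ri` may be supplied directly (e.g.
#' computed from a dose grid).
#'
#' @param ptv_dvh [cumulative_dvh] of the target.
#' @param body_dvh Optional [cumulative_dvh] of the body contour (used for
#'   V_RI). One of `body_dvh` / `v_ri` must be given for CI and CN.
#' @param prescription Prescription dose in Gy.
#' @param reference_isodose_pct Reference isodose level as percent of the
#'   prescription dose; default 95 (i.e. RI dose = 0.95 x prescription).
#' @param v_ri Optional reference-isodose volume (cm^3) overriding `body_dvh`.
#' @return Named list: `d2`, `d98`, `d50` (Gy), `tv`, `tv_ri`, `v_ri` (cm^3,
#'   `v_ri` may be NA), `hi`, `ci`, `cn` (NA where V_RI is unavailable).
#' @export
target_indices <- function(ptv_dvh, body_dvh = NULL, prescription,
                           reference_isodose_pct = 95, v_ri = NULL) {
  stopifnot(inherits(ptv_dvh, "cumulative_dvh"), prescription > 0,
            reference_isodose_pct > 0)
  ri_dose <- reference_isodose_pct / 100 * prescription
  d2 <- dose_at_volume(ptv_dvh, 0.02)
  d98 <- dose_at_volume(ptv_dvh, 0.98)
  d50 <- dose_at_volume(ptv_dvh, 0.50)
  tv <- ptv_dvh$total_volume
  tv_ri <- volume_at_dose(ptv_dvh, ri_dose) * tv
  if (is.null(v_ri) && !is.null(body_dvh)) {
    stopifnot(inherits(body_dvh, "cumulative_dvh"))
    v_ri <- volume_at_dose(body_dvh, ri_dose) * body_dvh$total_volume
  }
  hi <- homogeneity_index(d2, d98, d50)
  if (is.null(v_ri)) {
    ci <- NA_real_
    cn <- NA_real_
    v_ri <- NA_real_
  } else {
    ci <- conformity_index(v_ri, tv)
    # clamp tiny interpolation overshoot of TV_RI above V_RI
    cn <- conformation_number(min(tv_ri, v_ri), tv, v_ri)
  }
  list(d2 = d2, d98 = d98, d50 = d50, tv = tv, tv_ri = tv_ri, v_ri = v_ri,
       hi = hi, ci = ci, cn = cn)
}
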