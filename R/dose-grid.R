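#' Axis-aligned 3D dose grid
#'
#' Voxel-center convention: voxel (i, j, k) sits at
#' `origin + (c(i, j, k) - 1) * spacing` in patient-space mm. No
#' direction-cosine rotations are supported — all frames are axis-aligned.
#' `NA` voxels mean "missing" (e.g. outside the support of a resampled
#' source grid), never zero dose.
#'
#' @param values 3D numeric array of dose in Gy (>= 0 or NA).
#' @param origin Length-3 numeric, mm position of the first voxel center.
#' @param spacing Length-3 numeric, strictly positive voxel spacing in mm.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  .check_frame(values, origin, spacing)
  if (any(values < 0, na.rm = TRUE))
    stop("dose values must be >= 0", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_grid")
}

#' Binary structure mask on a dose-grid frame
#'
#' @param values 3D logical (or 0/1) array.
#' @inheritParams dose_grid
#' @return Object of class `structure_mask`.
#' @export
structure_mask <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be binary", call. = FALSE)
    values <- array(values != 0, dim = dim(values))
  }
  .check_frame(values, origin, spacing)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "structure_mask")
}

.check_frame <- function(values, origin, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array", call. = FALSE)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("origin and spacing must be length-3", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose grid> %s voxels, spacing (%s) mm, dose [%.3g, %.3g] Gy, %d missing\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing, collapse = ", "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure mask> %s voxels, %d set (%.1f cm^3)\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              sum(x$values) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Do two grids share a frame?
#' @param a,b `dose_grid` or `structure_mask` objects.
#' @param tol Tolerance in mm on origin/spacing.
#' @return Logical.
#' @export
frames_equal <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

#' Frame specification of a grid
#' @param origin,spacing Length-3 numerics (mm).
#' @param shape Length-3 integer voxel counts.
#' @return List with elements `origin`, `spacing`, `shape`.
#' @export
grid_frame <- function(origin, spacing, shape) {
  if (any(shape < 1)) stop("shape must be >= 1 per axis", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  list(origin = as.numeric(origin), spacing = as.numeric(spacing),
       shape = as.integer(shape))
}

#' Resample a dose grid onto a target frame by trilinear interpolation
#'
#' Dose is interpolated at the target voxel centers. Target voxels outside
#' the source support are flagged missing (`NA`), not zero-filled, so that
#' grid-boundary effects cannot masquerade as dose differences downstream.
#'
#' @param grid A [dose_grid].
#' @param target_frame A [grid_frame()].
#' @return A [dose_grid] on the target frame.
#' @export
resample_to_frame <- function(grid, target_frame) {
  stopifnot(inherits(grid, "dose_grid"))
  tf <- target_frame
  src_dim <- dim(grid$values)
  # overlap check in physical space
  src_lo <- grid$origin
  src_hi <- grid$origin + (src_dim - 1L) * grid$spacing
  tgt_lo <- tf$origin
  tgt_hi <- tf$origin + (tf$shape - 1L) * tf$spacing
  if (any(tgt_hi < src_lo - 1e-9) || any(tgt_lo > src_hi + 1e-9))
    stop("target frame does not overlap the source grid", call. = FALSE)

  # fractional source index per target coordinate, per axis (1-based)
  ax <- lapply(1:3, function(k) {
    x <- tf$origin[k] + (seq_len(tf$shape[k]) - 1L) * tf$spacing[k]
    t <- (x - grid$origin[k]) / grid$spacing[k] + 1
    inside <- t >= 1 - 1e-9 & t <= src_dim[k] + 1e-9
    t <- pmin(pmax(t, 1), src_dim[k])
    i0 <- pmin(floor(t), max(src_dim[k] - 1L, 1L))
    list(i0 = i0, w = t - i0, inside = inside)
  })
  w1 <- lapply(ax, `[[`, "w")
  i0 <- lapply(ax, `[[`, "i0")
  i1 <- lapply(seq_along(i0), function(k) pmin(i0[[k]] + 1L, src_dim[k]))

  out <- array(0, dim = tf$shape)
  v <- grid$values
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) i1[[1]] else i0[[1]]
    iy <- if (cy) i1[[2]] else i0[[2]]
    iz <- if (cz) i1[[3]] else i0[[3]]
    wx <- if (cx) w1[[1]] else 1 - w1[[1]]
    wy <- if (cy) w1[[2]] else 1 - w1[[2]]
    wz <- if (cz) w1[[3]] else 1 - w1[[3]]
    wt <- outer(outer(wx, wy), wz)  # shape nx x ny x nz
    out <- out + wt * v[ix, iy, iz, drop = FALSE]
  }
  outside <- !outer(outer(ax[[1]]$inside, ax[[2]]$inside, `&`), ax[[3]]$inside, `&`)
  out[outside] <- NA_real_
  dose_grid(out, origin = tf$origin, spacing = tf$spacing)
}

#' Voxel-wise signed dose difference a - b
#'
#' Frames must match; pass `resample = TRUE` to first resample `b` onto `a`'s
#' frame. Missing voxels propagate as missing.
#'
#' @param a,b [dose_grid] objects.
#' @param resample Resample `b` onto `a`'s frame if frames differ.
#' @return A [dose_grid]-framed object of class `dose_diff` holding the
#'   signed difference (values may be negative).
#' @export
subtract_grids <- function(a, b, resample = FALSE) {
  stopifnot(inherits(a, "dose_grid"), inherits(b, "dose_grid"))
  if (!frames_equal(a, b)) {
    if (!resample)
      stop("grid frames differ; resample first (resample = TRUE)", call. = FALSE)
    b <- resample_to_frame(b, grid_frame(a$origin, a$spacing, dim(a$values)))
  }
  structure(list(values = a$values - b$values, origin = a$origin,
                 spacing = a$spacing),
            class = c("dose_diff", "dose_grid"))
}

#' Cumulative DVH of a masked region of a dose grid
#'
#' Counts masked voxels with dose at or above each bin edge; total volume is
#' the masked voxel count times the voxel volume. Missing voxels (NA dose)
#' are excluded from the count and reported via the `n_missing` attribute.
#'
#' @param grid A [dose_grid].
#' @param mask A [structure_mask] on the same frame.
#' @param bin_width DVH dose resolution in Gy (default 0.1).
#' @param structure_name Name for the resulting DVH.
#' @return A [cumulative_dvh].
#' @export
dvh_from_grid <- function(grid, mask, bin_width = 0.1,
                          structure_name = "structure") {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!frames_equal(grid, mask))
    stop("grid and mask frames differ", call. = FALSE)
  doses <- grid$values[mask$values]
  n_missing <- sum(is.na(doses))
  doses <- doses[!is.na(doses)]
  if (length(doses) == 0L)
    stop("empty mask (or all masked voxels missing)", call. = FALSE)
  n_bins <- max(1L, as.integer(ceiling(max(doses) / bin_width - 1e-12)))
  edges <- seq(0, by = bin_width, length.out = n_bins + 2L)
  cnt <- length(doses) -
    findInterval(edges - 1e-12, sort(doses))  # voxels with dose >= edge
  cdvh <- cumulative_dvh(structure_name, edges, cnt / length(doses),
                         total_volume = length(doses) * prod(grid$spacing) / 1000)
  attr(cdvh, "n_missing") <- n_missing
  cdvh
}

#' Summary statistics of a dose-difference map inside a structure
#'
#' Mean/min/max of the signed difference restricted to the mask, plus the
#' fraction of (non-missing) masked voxels exceeding each threshold in either
#' direction. Missing voxels are excluded and their fraction reported.
#'
#' @param diff A signed difference map from [subtract_grids()] (any
#'   [dose_grid]-framed object).
#' @param mask A [structure_mask] on the same frame.
#' @param thresholds Positive thresholds in Gy (default `c(0.5, 1, 2)`).
#' @return List: `mean`, `min`, `max`, `n`, `excluded_fraction`, and a data
#'   frame `exceedance` with columns `threshold`, `frac_above` (diff >
#'   +threshold), `frac_below` (diff < -threshold), `frac_abs_above`.
#' @export
masked_difference_stats <- function(diff, mask, thresholds = c(0.5, 1, 2)) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!frames_equal(diff, mask))
    stop("difference map and mask frames differ", call. = FALSE)
  if (!any(mask$values)) stop("empty mask", call. = FALSE)
  vals <- diff$values[mask$values]
  n_all <- length(vals)
  miss <- is.na(vals)
  vals <- vals[!miss]
  if (length(vals) == 0L)
    stop("all masked voxels are missing", call. = FALSE)
  exc <- data.frame(
    threshold = thresholds,
    frac_above = vapply(thresholds, function(t) mean(vals > t), numeric(1L)),
    frac_below = vapply(thresholds, function(t) mean(vals < -t), numeric(1L)),
    frac_abs_above = vapply(thresholds, function(t) mean(abs(vals) > t),
                            numeric(1L)))
  list(mean = mean(vals), min = min(vals), max = max(vals), n = length(vals),
       excluded_fraction = mean(miss), exceedance = exc)
}

#' Write / read a dose grid or mask as a self-describing text file
#'
#' NRRD-style plain-text container: a small `key: value` header (type, shape,
#' origin, spacing) followed by one value per line, printed with 17
#' significant digits so that write-then-read round-trips are bit-exact.
#' Values are stored in x-fastest (R array) order.
#'
#' @param x A [dose_grid] or [structure_mask].
#' @param path Output file path.
#' @return `write_dose_grid` returns `path` invisibly; `read_dose_grid`
#'   returns the reconstructed object.
#' @export
write_dose_grid <- function(x, path) {
  is_mask <- inherits(x, "structure_mask")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "vmatqa-grid: 1",
    paste0("type: ", if (is_mask) "mask" else "dose"),
    paste0("shape: ", paste(dim(x$values), collapse = " ")),
    paste0("origin: ", paste(sprintf("%.17g", x$origin), collapse = " ")),
    paste0("spacing: ", paste(sprintf("%.17g", x$spacing), collapse = " ")),
    "data:"), con)
  vals <- as.vector(x$values)
  writeLines(if (is_mask) as.character(as.integer(vals))
             else sprintf("%.17g", vals), con)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L || !startsWith(lines[1L], "vmatqa-grid:"))
    stop("not a vmatqa grid file: ", path, call. = FALSE)
  hdr_end <- match("data:", lines)
  if (is.na(hdr_end)) stop("grid file has no data section", call. = FALSE)
  hdr <- lines[2:(hdr_end - 1L)]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0(key, ":"))]
    if (length(ln) != 1L) stop("missing header field: ", key, call. = FALSE)
    strsplit(sub(paste0("^", key, ": *"), "", ln), " +")[[1L]]
  }
  type <- get("type")
  shape <- as.integer(get("shape"))
  origin <- as.numeric(get("origin"))
  spacing <- as.numeric(get("spacing"))
  vals <- as.numeric(lines[(hdr_end + 1L):length(lines)])
  if (length(vals) != prod(shape))
    stop(sprintf("grid data length %d does not match shape (%s)",
                 length(vals), paste(shape, collapse = "x")), call. = FALSE)
  arr <- array(vals, dim = shape)
  if (type == "mask") structure_mask(arr != 0, origin, spacing)
  else dose_grid(arr, origin, spacing)
}
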