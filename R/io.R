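# condition helpers: the CLI maps these to exit codes 2 (validation) and 3 (parse)
stop_validation <- function(...) {
  stop(structure(class = c("vmatqa_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}
stop_parse <- function(...) {
  stop(structure(class = c("vmatqa_parse_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

#' Parse a DVH export file
#'
#' Two dialects are auto-detected:
#' \describe{
#'   \item{CSV}{Header `structure,dose_gy,volume_fraction` (optional fourth
#'     column `total_cm3`); one row per curve point.}
#'   \item{TPS text}{Per-structure header blocks (`Structure: <name>`,
#'     `Volume [cm3]: <v>`) followed by a two-column table whose header names
#'     the units — dose in `[Gy]` or `[%]` (percent of the prescription
#'     dose), volume in `[%]` or `[cm3]` (converted to fractions using the
#'     structure volume).}
#' }
#' Relative-dose exports require `prescription`; either dialect yields
#' identical internal DVHs for the same plan.
#'
#' @param path File path.
#' @param prescription Prescription dose in Gy; needed only for
#'   percent-dose exports (a file-level `Prescribed dose [Gy]:` line also
#'   works).
#' @return Named list of [cumulative_dvh] objects; attribute `skipped` lists
#'   any structure blocks that could not be parsed.
#' @export
parse_dvh_export <- function(path, prescription = NULL) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) stop_parse("empty DVH file: %s", path)
  first <- lines[nonblank[1L]]
  if (grepl("^\\s*structure\\s*,\\s*dose_gy\\s*,\\s*volume_fraction", first,
            ignore.case = TRUE)) {
    return(.parse_dvh_csv(path))
  }
  if (grepl("^\\s*(Structure|Prescribed dose)\\s*[:\\[]", first)) {
    return(.parse_dvh_tps(lines, prescription, path))
  }
  stop_parse("unknown DVH dialect in %s; first unrecognized line %d: '%s'",
             path, nonblank[1L], first)
}

.parse_dvh_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_parse("malformed CSV %s: %s", path,
                                                conditionMessage(e)))
  need <- c("structure", "dose_gy", "volume_fraction")
  if (!all(need %in% names(df)))
    stop_parse("CSV DVH must have columns %s", paste(need, collapse = ","))
  out <- list()
  for (st in unique(df$structure)) {
    sub <- df[df$structure == st, , drop = FALSE]
    vol <- if ("total_cm3" %in% names(df)) sub$total_cm3[1L] else 1
    out[[st]] <- .as_clean_cdvh(st, sub$dose_gy, sub$volume_fraction, vol, path)
  }
  attr(out, "skipped") <- character(0)
  out
}

.parse_dvh_tps <- function(lines, prescription, path) {
  # file-level prescription header
  rx_presc <- "^\\s*Prescribed dose \\[Gy\\]\\s*:\\s*([0-9.]+)"
  hit <- grep(rx_presc, lines)
  if (length(hit)) prescription <- as.numeric(sub(rx_presc, "\\1", lines[hit[1L]]))
  starts <- grep("^\\s*Structure\\s*:", lines)
  if (length(starts) == 0L)
    stop_parse("no 'Structure:' blocks in %s", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  skipped <- character(0)
  for (b in seq_along(starts)) {
    blk <- lines[starts[b]:ends[b]]
    st <- trimws(sub("^\\s*Structure\\s*:", "", blk[1L]))
    res <- tryCatch(.parse_tps_block(st, blk, prescription, starts[b]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (inherits(res, "vmatqa_parse_error")) stop(res)
      skipped <- c(skipped, sprintf("%s (%s)", st, conditionMessage(res)))
    } else out[[st]] <- res
  }
  if (length(out) == 0L)
    stop_parse("no parsable structure blocks in %s", path)
  attr(out, "skipped") <- skipped
  out
}

.parse_tps_block <- function(st, blk, prescription, line0) {
  rx_vol <- "^\\s*Volume \\[cm.?3?.?\\]\\s*:\\s*([0-9.]+)"
  vol_line <- grep(rx_vol, blk)
  total <- if (length(vol_line)) as.numeric(sub(rx_vol, "\\1", blk[vol_line[1L]]))
           else NA_real_
  colhdr <- grep("Dose", blk[-1L], fixed = TRUE) + 1L
  if (length(colhdr) == 0L)
    stop_parse("structure '%s': no column header naming Dose units (line %d)",
               st, line0)
  if (colhdr[1L] >= length(blk))
    stop_parse("structure '%s': truncated block, no data rows after line %d",
               st, line0 + colhdr[1L] - 1L)
  hdr <- blk[colhdr[1L]]
  dose_rel <- grepl("Dose \\[%\\]", hdr)
  vol_abs <- grepl("(cm.?3)", sub(".*Dose[^V]*", "", hdr)) &&
    !grepl("\\[%\\]\\s*$", hdr)
  rows <- blk[(colhdr[1L] + 1L):length(blk)]
  rows <- rows[trimws(rows) != ""]
  if (length(rows) == 0L)
    stop_parse("structure '%s': truncated block, no data rows after line %d",
               st, line0 + colhdr[1L] - 1L)
  mat <- lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1L]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop_parse("structure '%s': unparsable data row at line %d: '%s'",
                 st, line0 + colhdr[1L] + i - 1L, rows[i])
    v[1:2]
  })
  m <- do.call(rbind, mat)
  dose <- m[, 1L]
  volume <- m[, 2L]
  if (dose_rel) {
    if (is.null(prescription) || is.na(prescription))
      stop_parse("structure '%s': percent-dose export needs a prescription dose",
                 st)
    dose <- dose / 100 * prescription
  }
  if (vol_abs) {
    if (is.na(total)) total <- max(volume)
    fraction <- volume / total
  } else {
    fraction <- volume / 100
    if (is.na(total)) total <- 1
  }
  .as_clean_cdvh(st, dose, fraction, total, "")
}

# tolerate tiny numerical wobble from text exports, reject real violations
.as_clean_cdvh <- function(st, dose, fraction, total, path) {
  if (any(diff(fraction) > 1e-6))
    stop_parse("structure '%s': cumulative volume increases by more than 1e-6 at index %d",
               st, which(diff(fraction) > 1e-6)[1L] + 1L)
  fraction <- cummin(pmin(1, fraction))
  if (dose[1L] > 0) {
    dose <- c(0, dose)
    fraction <- c(1, fraction)
  }
  fraction[1L] <- 1
  cumulative_dvh(st, dose, fraction, total)
}

#' Write a cohort to a directory of DVH CSV files plus a manifest
#'
#' One `P<nn>_<variant>.csv` per patient-variant in the standard CSV dialect
#' (with `total_cm3`), plus `manifest.json` recording the seed, prescription,
#' fractions and the variant table — everything [read_cohort()] needs to
#' rebuild the cohort from files.
#'
#' @param cohort A `vmat_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vmat_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (pid in names(cohort$patients)) {
    for (vc in names(cohort$patients[[pid]])) {
      plan <- cohort$patients[[pid]][[vc]]
      rows <- do.call(rbind, lapply(plan$dvhs, function(cd)
        data.frame(structure = cd$structure_name, dose_gy = cd$dose,
                   volume_fraction = cd$fraction, total_cm3 = cd$total_volume)))
      fn <- sprintf("%s_%s.csv", pid, vc)
      utils::write.csv(format(rows, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       file.path(dir, fn), row.names = FALSE, quote = FALSE)
      files[[length(files) + 1L]] <- list(
        file = fn, patient = pid, algorithm = plan$algorithm,
        grid_mm = plan$grid_mm)
    }
  }
  manifest <- list(
    prescription = cohort$spec$prescription,
    n_fractions = cohort$spec$n_fractions,
    seed = cohort$spec$seed,
    variants = cohort$spec$variants,
    plans = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory containing `manifest.json`.
#' @return A `vmat_cohort` (with a minimal spec reconstructed from the
#'   manifest).
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop_parse("no manifest.json in %s", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  variants <- as.data.frame(mf$variants)
  patients <- list()
  for (i in seq_len(nrow(mf$plans))) {
    rec <- mf$plans[i, ]
    dvhs <- parse_dvh_export(file.path(dir, rec$file),
                             prescription = mf$prescription)
    attr(dvhs, "skipped") <- NULL
    plan <- plan_dvh_set(rec$patient, rec$algorithm, rec$grid_mm, dvhs,
                         prescription_dose = mf$prescription,
                         n_fractions = mf$n_fractions,
                         allowed_variants = variants)
    patients[[rec$patient]][[variant_code(rec$algorithm, rec$grid_mm)]] <- plan
  }
  spec <- cohort_spec(n_patients = length(patients),
                      seed = if (!is.null(mf$seed)) mf$seed else 0L,
                      prescription = mf$prescription,
                      n_fractions = mf$n_fractions, variants = variants)
  structure(list(patients = patients, spec = spec), class = "vmat_cohort")
}

#' Analysis configuration
#'
#' @param prescription Prescription dose in Gy (default 78).
#' @param n_fractions Number of fractions (default 39).
#' @param reference_isodose_pct Reference isodose level in percent of the
#'   prescription dose (default 95; conformity indices are evaluated at this
#'   dose).
#' @param reference_variant Length-2 (algorithm, grid_mm) reference of the
#'   deviation table; default AXB at 1 mm (the most accurate combination).
#' @param apply_eqd2 Apply the EQD2 correction before EUD (default TRUE).
#' @param registry A `param_registry` (default [default_param_registry()]).
#' @param contrasts Variant contrasts; default [default_contrasts()].
#' @param bin_width Differential DVH bin width in Gy (default 0.1).
#' @param v_x_levels Percent levels reported for OAR V_x\% (default 30/50/70).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(prescription = 78, n_fractions = 39,
                            reference_isodose_pct = 95,
                            reference_variant = c("AXB", "1"),
                            apply_eqd2 = TRUE,
                            registry = default_param_registry(),
                            contrasts = default_contrasts(),
                            bin_width = 0.1,
                            v_x_levels = c(30, 50, 70)) {
  stopifnot(prescription > 0, n_fractions >= 1, reference_isodose_pct > 0,
            length(reference_variant) == 2L, bin_width > 0)
  structure(list(prescription = prescription, n_fractions = n_fractions,
                 reference_isodose_pct = reference_isodose_pct,
                 reference_variant = reference_variant,
                 apply_eqd2 = isTRUE(apply_eqd2), registry = registry,
                 contrasts = contrasts, bin_width = bin_width,
                 v_x_levels = v_x_levels),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Recognized keys mirror the [analysis_config()] arguments; unknown keys are
#' rejected. `param_registry_path` may point to a registry CSV.
#'
#' @param path JSON file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_parse("config file not found: %s", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_parse("malformed config JSON %s: %s",
                                                 path, conditionMessage(e)))
  known <- c("prescription", "n_fractions", "reference_isodose_pct",
             "reference_variant", "apply_eqd2", "param_registry_path",
             "contrasts", "bin_width", "v_x_levels")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_validation("unknown config keys: %s", paste(bad, collapse = ", "))
  args <- raw[setdiff(names(raw), "param_registry_path")]
  if (!is.null(raw$param_registry_path))
    args$registry <- read_param_registry(raw$param_registry_path)
  if (!is.null(args$contrasts))
    args$contrasts <- lapply(seq_len(nrow(args$contrasts)),
                             function(i) unlist(args$contrasts[i, ]))
  do.call(analysis_config, args)
}

# stable content hash (FNV-1a over the serialized config) for run logs
.config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, xdr = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
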