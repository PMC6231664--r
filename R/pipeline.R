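#' Dosimetric and radiobiological metrics of one plan variant
#'
#' PTV block: V_95\% (percent), median/mean/max/min dose (Gy), HI, CI, CN
#' (conformity indices need a `BODY` structure for the reference-isodose
#' volume; they are NA without one). OAR block (every non-PTV, non-BODY
#' structure): max/min/mean/median dose as percent of the prescription dose
#' and V_x\% at the configured levels. Radiobiology block: EUD-based TCP/NTCP
#' (percent) for every registry organ present.
#'
#' @param plan A [plan_dvh_set].
#' @param config An [analysis_config()].
#' @return Tidy data frame: `patient`, `algorithm`, `grid_mm`, `variant`,
#'   `structure`, `metric`, `value`.
#' @export
compute_plan_metrics <- function(plan, config = analysis_config()) {
  stopifnot(inherits(plan, "plan_dvh_set"), inherits(config, "analysis_config"))
  presc <- plan$prescription_dose
  rows <- list()
  add <- function(structure, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      patient = plan$patient_id, algorithm = plan$algorithm,
      grid_mm = plan$grid_mm,
      variant = variant_code(plan$algorithm, plan$grid_mm),
      structure = structure, metric = metric, value = value,
      stringsAsFactors = FALSE)

  ptv <- plan$dvhs[["PTV"]]
  if (!is.null(ptv)) {
    s <- dvh_summary(ptv)
    add("PTV", "V95", v_x_percent(ptv, 95, presc))
    add("PTV", "D_median", s$median)
    add("PTV", "D_mean", s$mean)
    add("PTV", "D_max", s$max)
    add("PTV", "D_min", s$min)
    ti <- target_indices(ptv, body_dvh = plan$dvhs[["BODY"]],
                         prescription = presc,
                         reference_isodose_pct = config$reference_isodose_pct)
    add("PTV", "HI", ti$hi)
    add("PTV", "CI", ti$ci)
    add("PTV", "CN", ti$cn)
  }
  for (st in setdiff(names(plan$dvhs), c("PTV", "BODY"))) {
    cd <- plan$dvhs[[st]]
    s <- dvh_summary(cd)
    add(st, "D_max_pct", s$max / presc * 100)
    add(st, "D_min_pct", s$min / presc * 100)
    add(st, "D_mean_pct", s$mean / presc * 100)
    add(st, "D_median_pct", s$median / presc * 100)
    for (x in config$v_x_levels)
      add(st, sprintf("V%d", x), v_x_percent(cd, x, presc))
  }
  rb <- suppressWarnings(
    evaluate_plan_radiobiology(plan, config$registry,
                               apply_eqd2 = config$apply_eqd2,
                               bin_width = config$bin_width))
  if (!is.null(rb))
    for (i in seq_len(nrow(rb)))
      add(rb$structure[i], rb$metric[i], rb$probability[i] * 100)
  do.call(rbind, rows)
}

#' Metrics of every plan of every patient in a cohort
#'
#' @param cohort A `vmat_cohort`.
#' @param config An [analysis_config()].
#' @return Tidy data frame as in [compute_plan_metrics()], one block per
#'   patient-variant.
#' @export
compute_cohort_metrics <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "vmat_cohort"))
  do.call(rbind, lapply(cohort$patients, function(pt)
    do.call(rbind, lapply(pt, compute_plan_metrics, config = config))))
}

#' Cohort mean (SD) summary table, one row per structure-metric
#'
#' The cohort-report layout: rows are (structure, metric), columns are plan
#' variants, cells are the across-patient mean with SD. Full-precision
#' columns `mean_<variant>` / `sd_<variant>` accompany the rounded 2-decimal
#' display column `disp_<variant>`.
#'
#' @param metrics Tidy metrics from [compute_cohort_metrics()].
#' @return Wide data frame.
#' @export
summary_table <- function(metrics) {
  variants <- unique(metrics$variant)
  keys <- unique(metrics[, c("structure", "metric")])
  out <- keys
  for (vc in variants) {
    mu <- sd_ <- disp <- numeric(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      v <- metrics$value[metrics$variant == vc &
                           metrics$structure == keys$structure[i] &
                           metrics$metric == keys$metric[i]]
      mu[i] <- mean(v)
      sd_[i] <- stats::sd(v)
    }
    out[[paste0("mean_", vc)]] <- mu
    out[[paste0("sd_", vc)]] <- sd_
    out[[paste0("disp_", vc)]] <- sprintf("%.2f (%.2f)", mu, sd_)
  }
  rownames(out) <- NULL
  out
}

#' Percent-deviation table against the reference variant
#'
#' For each (structure, dose metric) the across-patient cohort means are
#' computed per variant and every non-reference variant is scored as
#' |Ref - Eval| / Ref x 100 against the reference variant's cohort mean —
#' the feasibility view of how far coarser grids or the other algorithm
#' drift from the most accurate combination.
#'
#' @param metrics Tidy metrics from [compute_cohort_metrics()].
#' @param config An [analysis_config()]; `config$reference_variant` picks
#'   the reference (default AXB 1 mm).
#' @param metrics_included Metric names entering the table; defaults to the
#'   summary-dose metrics.
#' @return Tidy data frame: `structure`, `metric`, `variant`,
#'   `deviation_pct`.
#' @export
deviation_table <- function(metrics, config = analysis_config(),
                            metrics_included = c("D_max", "D_min", "D_mean",
                                                 "D_median", "D_max_pct",
                                                 "D_min_pct", "D_mean_pct",
                                                 "D_median_pct")) {
  ref_vc <- variant_code(config$reference_variant[1L],
                         config$reference_variant[2L])
  if (!ref_vc %in% metrics$variant)
    stop_validation("reference variant %s absent from the cohort", ref_vc)
  sub <- metrics[metrics$metric %in% metrics_included, , drop = FALSE]
  rows <- list()
  for (st in unique(sub$structure)) {
    for (me in unique(sub$metric[sub$structure == st])) {
      cell <- sub[sub$structure == st & sub$metric == me, , drop = FALSE]
      ref <- mean(cell$value[cell$variant == ref_vc])
      for (vc in setdiff(unique(cell$variant), ref_vc)) {
        ev <- mean(cell$value[cell$variant == vc])
        # a zero reference makes the relative deviation undefined unless the
        # evaluated value is also zero (then the plans agree: 0% deviation)
        dev <- if (ref == 0 && ev == 0) 0
               else if (ref == 0) NA_real_
               else percent_deviation(ref, ev)
        rows[[length(rows) + 1L]] <- data.frame(
          structure = st, metric = me, variant = vc,
          deviation_pct = dev, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# cohort balance check: every patient must hold every variant
.check_balance <- function(cohort, contrasts) {
  needed <- unique(unlist(contrasts))
  problems <- character(0)
  for (pid in names(cohort$patients)) {
    missing <- setdiff(needed, names(cohort$patients[[pid]]))
    if (length(missing))
      problems <- c(problems, sprintf("%s: missing %s", pid,
                                      paste(missing, collapse = ", ")))
  }
  if (length(problems))
    stop_validation("unbalanced cohort:\n  %s",
                    paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Run the full plan-evaluation workflow on a cohort
#'
#' Validates cohort balance, computes all per-plan metrics, and emits the
#' five result tables as tidy CSVs: PTV summary (`table_ptv.csv`), OAR
#' summary (`table_oar.csv`), percent deviations (`table_deviation.csv`),
#' TCP/NTCP summary (`table_radiobio.csv`) and Wilcoxon p-values
#' (`table_pvalues.csv`), plus `run_log.json` with the configuration, its
#' hash and seed provenance. Re-running with identical inputs reproduces the
#' outputs byte for byte.
#'
#' @param cohort A `vmat_cohort` object or a cohort directory path readable
#'   by [read_cohort()].
#' @param config An [analysis_config()].
#' @param output_dir Where to write the tables; `NULL` skips writing.
#' @return Invisibly, a list of the five tables (`ptv`, `oar`, `deviation`,
#'   `radiobio`, `pvalues`) plus the tidy `metrics`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config(),
                              output_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "vmat_cohort"))
  .check_balance(cohort, config$contrasts)
  ref_vc <- variant_code(config$reference_variant[1L],
                         config$reference_variant[2L])
  if (!all(vapply(cohort$patients, function(p) ref_vc %in% names(p), logical(1))))
    stop_validation("reference variant %s not present for every patient", ref_vc)

  metrics <- compute_cohort_metrics(cohort, config)
  is_rb <- metrics$metric %in% c("TCP", "NTCP")
  ptv_tab <- summary_table(metrics[metrics$structure == "PTV" & !is_rb, ])
  oar_tab <- summary_table(metrics[metrics$structure != "PTV" & !is_rb, ])
  rb_tab <- summary_table(metrics[is_rb, ])
  dev_tab <- deviation_table(metrics, config)
  p_tab <- comparison_table(metrics[!(metrics$metric %in% c("CI", "CN") &
                                        is.na(metrics$value)), ],
                            contrasts = config$contrasts)

  tables <- list(ptv = ptv_tab, oar = oar_tab, deviation = dev_tab,
                 radiobio = rb_tab, pvalues = p_tab, metrics = metrics)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, fn)
      utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                       file.path(output_dir, fn), row.names = FALSE)
    wr(ptv_tab, "table_ptv.csv")
    wr(oar_tab, "table_oar.csv")
    wr(dev_tab, "table_deviation.csv")
    wr(rb_tab, "table_radiobio.csv")
    wr(p_tab, "table_pvalues.csv")
    log <- list(config = unclass(config)[setdiff(names(config), "registry")],
                registry = lapply(config$registry, unclass),
                config_hash = .config_hash(config),
                cohort_seed = cohort$spec$seed,
                n_patients = length(cohort$patients),
                package_version = as.character(utils::packageVersion("vmatqa")))
    jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tables)
}

#' Published reference cohort summary values
#'
#' Cohort mean (and SD where published) dosimetric and radiobiological
#' summary values from a published 20-patient prostate-VMAT comparison of
#' dose-calculation algorithms and grid sizes, shipped as plain CSVs. They
#' serve as worked-example inputs — e.g. recomputing cross-table percent
#' deviations — not as outputs this package claims to reproduce (the
#' underlying patient DVHs were never deposited).
#'
#' @param which `"ptv"` (PTV dosimetric summary, Gy / percent / unitless),
#'   `"oar"` (OAR summary doses in percent of prescription) or
#'   `"radiobio"` (TCP/NTCP percent).
#' @return Data frame.
#' @export
reference_cohort_summary <- function(which = c("ptv", "oar", "radiobio")) {
  which <- match.arg(which)
  fn <- system.file("extdata", paste0("reference_summary_", which, ".csv"),
                    package = "vmatqa", mustWork = TRUE)
  utils::read.csv(fn, stringsAsFactors = FALSE)
}
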