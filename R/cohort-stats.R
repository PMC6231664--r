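#' Paired Wilcoxon signed-rank test with exact tie-aware p-values
#'
#' Signed-rank statistic W+ (sum of midranks of positive differences) with an
#' exact two-sided p-value obtained from the full distribution of W+ over all
#' 2^n sign assignments. Ties receive midranks; the exact distribution is
#' computed by the shift algorithm over doubled ranks, which is identical to
#' brute-force sign enumeration but costs O(n * sum(ranks)) instead of 2^n.
#' For n above the exact cutoff a normal approximation with tie and
#' continuity correction is used.
#'
#' Zero differences are dropped before ranking by default (the classical
#' convention, also what SPSS does); `zero_method = "pratt"` instead ranks
#' zeros with the rest and then discards their contribution. If every
#' difference is zero the result is flagged degenerate with p = 1.
#'
#' @param x Numeric vector: first member of each pair, or the paired
#'   differences themselves if `y` is NULL.
#' @param y Optional numeric vector: second member of each pair.
#' @param mode `"auto"` (exact for n <= 25, else normal), `"exact"`, or
#'   `"normal_approx"`.
#' @param zero_method `"wilcox"` (drop zeros) or `"pratt"`.
#' @param exact_cutoff Largest n for which `"auto"` uses the exact
#'   distribution (default 25).
#' @return List of class `wsr_test`: `statistic` (W+), `p_value` (two-sided),
#'   `n_used`, `n_zero`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("auto", "exact", "normal_approx"),
                                 zero_method = c("wilcox", "pratt"),
                                 exact_cutoff = 25L) {
  mode <- match.arg(mode)
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y))
      stop("paired vectors must have equal length", call. = FALSE)
    as.numeric(x) - as.numeric(y)
  }
  if (anyNA(d)) stop("missing pairs are not allowed", call. = FALSE)
  if (length(d) < 1L) stop("need at least one pair", call. = FALSE)

  n_zero <- sum(d == 0)
  if (n_zero == length(d)) {
    return(structure(list(statistic = 0, p_value = 1, n_used = 0L,
                          n_zero = n_zero, method = "degenerate",
                          degenerate = TRUE), class = "wsr_test"))
  }
  if (zero_method == "wilcox") {
    dn <- d[d != 0]
    r <- rank(abs(dn))
  } else {
    r_all <- rank(abs(d))
    dn <- d[d != 0]
    r <- r_all[d != 0]
  }
  w <- sum(r[dn > 0])
  n <- length(dn)

  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = n <= exact_cutoff)
  p <- if (use_exact) .wsr_exact_p(r, w) else .wsr_normal_p(r, w)
  structure(list(statistic = w, p_value = p, n_used = n, n_zero = n_zero,
                 method = if (use_exact) "exact" else "normal_approx",
                 degenerate = FALSE),
            class = "wsr_test")
}

#' @export
print.wsr_test <- function(x, ...) {
  if (x$degenerate)
    cat("<Wilcoxon signed-rank> degenerate: all differences zero, p = 1\n")
  else
    cat(sprintf("<Wilcoxon signed-rank> W+ = %g, n = %d (%d zeros dropped), %s p = %.4g\n",
                x$statistic, x$n_used, x$n_zero, x$method, x$p_value))
  invisible(x)
}

# exact two-sided p over all 2^n sign assignments via the shift algorithm.
# Ranks may be half-integers (midranks), so work on doubled ranks.
.wsr_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  w2 <- round(2 * w)
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s+1] = #assignments with doubled W+ = s
  f[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), f[seq_len(total + 1L - rk)])
    f <- f + shifted
  }
  n2 <- 2^length(r2)
  idx <- 0:total
  p_ge <- sum(f[idx >= w2 - 1e-9]) / n2
  p_le <- sum(f[idx <= w2 + 1e-9]) / n2
  min(1, 2 * min(p_ge, p_le))
}

# normal approximation with midrank tie handling (Var = sum r_i^2 / 4) and
# continuity correction
.wsr_normal_p <- function(r, w) {
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  if (sigma == 0) return(1)
  z <- (abs(w - mu) - 0.5) / sigma
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

#' Paired cohort comparison table of plan variants
#'
#' The cohort-analysis workhorse: for every (structure, metric) and every
#' contrast of plan-variant codes, pairs the per-patient metric values and
#' runs the paired Wilcoxon signed-rank test. The shipped default contrasts
#' compare algorithms at matched grid size and grid sizes within algorithm:
#' AAA1-AXB1, AAA3-AXB3, AAA1-AAA3, AAA1-AAA5, AXB1-AXB2, AXB1-AXB3.
#'
#' @param metrics Tidy data frame with columns `patient`, `variant`,
#'   `structure`, `metric`, `value` (e.g. from [compute_cohort_metrics()]).
#' @param contrasts List of length-2 character vectors of variant codes;
#'   default [default_contrasts()].
#' @param mode,zero_method Passed to [wilcoxon_signed_rank()].
#' @param p_adjust `"none"` (default — mirrors common single-table reporting)
#'   or `"holm"`. Holm adjustment is applied across all cells of the table;
#'   with many correlated DVH metrics it is conservative.
#' @return Data frame: `structure`, `metric`, `contrast`, `p_raw`,
#'   `p_display` (formatted, `"< .01"` below 0.01), `degenerate`, `n_pairs`.
#' @export
comparison_table <- function(metrics, contrasts = default_contrasts(),
                             mode = "auto", zero_method = "wilcox",
                             p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("patient", "variant", "structure", "metric", "value")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  patients <- sort(unique(metrics$patient))
  rows <- list()
  for (ct in contrasts) {
    if (length(ct) != 2L || ct[1L] == ct[2L])
      stop("each contrast must be two distinct variant codes", call. = FALSE)
    sub <- metrics[metrics$variant %in% ct, , drop = FALSE]
    for (st in unique(sub$structure)) {
      for (me in unique(sub$metric[sub$structure == st])) {
        cell <- sub[sub$structure == st & sub$metric == me, , drop = FALSE]
        a <- cell[cell$variant == ct[1L], ]
        b <- cell[cell$variant == ct[2L], ]
        a <- a[match(patients, a$patient), "value"]
        b <- b[match(patients, b$patient), "value"]
        if (anyNA(a) || anyNA(b)) {
          missing_pat <- patients[is.na(a) | is.na(b)]
          stop(sprintf("unbalanced cohort: missing (%s or %s) for patient(s) %s on %s/%s",
                       ct[1L], ct[2L], paste(missing_pat, collapse = ", "),
                       st, me), call. = FALSE)
        }
        ts <- wilcoxon_signed_rank(a, b, mode = mode, zero_method = zero_method)
        rows[[length(rows) + 1L]] <- data.frame(
          structure = st, metric = me,
          contrast = paste(ct, collapse = " vs "),
          p_raw = ts$p_value, degenerate = ts$degenerate,
          n_pairs = length(patients), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "holm")
    out$p_raw <- stats::p.adjust(out$p_raw, method = "holm")
  out$p_display <- ifelse(out$degenerate, "1 (degenerate)",
                          ifelse(out$p_raw < 0.01, "< .01",
                                 sprintf("%.2f", out$p_raw)))
  out[, c("structure", "metric", "contrast", "p_raw", "p_display",
          "degenerate", "n_pairs")]
}

#' Default plan-variant contrasts of the cohort comparison
#' @return List of length-2 character vectors of variant codes.
#' @export
default_contrasts <- function() {
  list(c("AAA1", "AXB1"), c("AAA3", "AXB3"), c("AAA1", "AAA3"),
       c("AAA1", "AAA5"), c("AXB1", "AXB2"), c("AXB1", "AXB3"))
}
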