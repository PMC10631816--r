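#' Per-visit, per-location aggregation of a study table
#'
#' Computes arithmetic means with standard errors and counts for each
#' (visit, location) cell of a longitudinal study table, plus grand per-visit
#' means pooling the four locations (reported with \code{location = "all"}).
#' Cells with fewer than 2 patients get an \code{NA} standard error; absent
#' cells are simply not reported (never imputed).
#'
#' @param table a \code{study_table} data.frame (columns patient_id, visit,
#'   location, and the metric).
#' @param metric column to aggregate, e.g. \code{"bvd"} or \code{"vet_um"}.
#' @return data.frame with columns visit, location, mean, se, n.
#' @export
aggregate_study <- function(table, metric) {
  stopifnot(metric %in% names(table))
  x <- table[[metric]]
  cell <- function(idx) {
    v <- x[idx]
    data.frame(mean = mean(v),
               se = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }
  groups <- split(seq_len(nrow(table)),
                  list(visit = table$visit, location = table$location),
                  drop = TRUE)
  per_cell <- do.call(rbind, lapply(groups, cell))
  keys <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  per_cell <- cbind(data.frame(visit = as.integer(keys[, 1]),
                               location = keys[, 2]), per_cell)
  grand <- do.call(rbind, lapply(split(seq_len(nrow(table)), table$visit),
                                 cell))
  grand <- cbind(data.frame(visit = as.integer(rownames(grand)),
                            location = "all"), grand)
  out <- rbind(per_cell, grand)
  out <- out[order(out$location != "all", out$location, out$visit), ]
  rownames(out) <- NULL
  out
}

#' Significance stars for a p-value
#'
#' The conventional annotation: \code{***} for p < 0.001, \code{**} for
#' p < 0.01, \code{*} for p < 0.05, otherwise \code{ns}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of star annotations.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Paired comparisons of each visit against baseline
#'
#' For every location and every visit after the first, tests the per-patient
#' change in the metric against zero: two-sided paired t-test on the deltas
#' (default) or Wilcoxon signed-rank. Patients missing either visit are
#' excluded pairwise. With \code{comparison = "consecutive"} each visit is
#' instead compared with the previous one.
#'
#' @param table a \code{study_table}.
#' @param metric metric column name.
#' @param test \code{"paired-t"} (default) or \code{"wilcoxon"}.
#' @param comparison \code{"baseline"} (default: visit v vs visit 1) or
#'   \code{"consecutive"} (visit v vs visit v - 1).
#' @return data.frame with visit, location, n_pairs, mean_delta, p_value,
#'   stars.
#' @export
compare_to_baseline <- function(table, metric,
                                test = c("paired-t", "wilcoxon"),
                                comparison = c("baseline", "consecutive")) {
  test <- match.arg(test); comparison <- match.arg(comparison)
  stopifnot(metric %in% names(table))
  visits <- sort(unique(table$visit))
  locs <- sort(unique(as.character(table$location)))
  rows <- list()
  for (v in visits[visits > min(visits)]) {
    ref <- if (comparison == "baseline") min(visits) else
      max(visits[visits < v])
    for (l in locs) {
      a <- table[table$visit == ref & table$location == l, ]
      b <- table[table$visit == v & table$location == l, ]
      common <- intersect(a$patient_id, b$patient_id)
      if (length(common) < 3L)
        stop(sprintf("insufficient pairs for visit %s at %s (need >= 3)",
                     v, l))
      d <- b[[metric]][match(common, b$patient_id)] -
        a[[metric]][match(common, a$patient_id)]
      p <- delta_test_p(d, test)
      rows[[length(rows) + 1L]] <-
        data.frame(visit = v, location = l, n_pairs = length(common),
                   mean_delta = mean(d), p_value = p, stars = p_stars(p))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# two-sided p for deltas; degenerate all-equal deltas are resolved by the
# sign of the common value (p = 1 when every delta is exactly 0)
delta_test_p <- function(d, test) {
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  if (test == "paired-t") stats::t.test(d)$p.value
  else stats::wilcox.test(d, exact = FALSE)$p.value
}

#' Classify the strength of a Pearson correlation
#'
#' Uses the absolute coefficient with left-closed bands: |r| < 0.1
#' negligible, 0.1 to 0.3 weak, 0.3 to 0.5 moderate, 0.5 and above strong.
#' The boundaries belong to the higher class (0.310 is moderate, 0.5 is
#' strong).
#'
#' @param r Pearson coefficient(s) in [-1, 1].
#' @return character vector in \{negligible, weak, moderate, strong\}.
#' @export
classify_correlation <- function(r) {
  a <- abs(r)
  stopifnot(all(a <= 1 + 1e-12))
  ifelse(a >= 0.5, "strong",
         ifelse(a >= 0.3, "moderate",
                ifelse(a >= 0.1, "weak", "negligible")))
}

#' Pearson correlation between two study metrics
#'
#' Computes the Pearson coefficient over pooled records (all visits and
#' locations by default, or within groups) and classifies its magnitude.
#'
#' @param table a \code{study_table}.
#' @param metric_a,metric_b metric column names.
#' @param group optional column name to compute the correlation within each
#'   level of (e.g. \code{"visit"}); default pooled.
#' @return for pooled: a \code{correlation_result} list (r, abs_r, strength,
#'   n); with \code{group}: a data.frame of the same fields per level.
#' @export
correlate_metrics <- function(table, metric_a, metric_b, group = NULL) {
  stopifnot(metric_a %in% names(table), metric_b %in% names(table))
  one <- function(df) {
    ok <- stats::complete.cases(df[[metric_a]], df[[metric_b]])
    a <- df[[metric_a]][ok]; b <- df[[metric_b]][ok]
    if (length(a) < 3L) stop("need at least 3 complete pairs")
    if (sd(a) == 0 || sd(b) == 0)
      stop("zero variance: correlation undefined")
    r <- stats::cor(a, b)
    structure(list(r = r, abs_r = abs(r),
                   strength = classify_correlation(r), n = length(a)),
              class = "correlation_result")
  }
  if (is.null(group)) return(one(table))
  res <- lapply(split(table, table[[group]]), one)
  data.frame(group = names(res),
             r = vapply(res, `[[`, 0, "r"),
             abs_r = vapply(res, `[[`, 0, "abs_r"),
             strength = vapply(res, `[[`, "", "strength"),
             n = vapply(res, `[[`, 0L, "n"), row.names = NULL)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (|r| = %.3f, %s, n = %d)\n",
              x$r, x$abs_r, x$strength, x$n))
  invisible(x)
}
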