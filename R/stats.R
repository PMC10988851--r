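# The study's statistical layer: regional means over selected coronal
# slices, two-rater intraclass correlation, per-timepoint one-way ANOVA with
# LSD post-hoc pairwise comparisons, Pearson correlation of imaging metrics
# against fibrosis scores, and the assembled report.

#' Regional metric means over central slices
#'
#' Arithmetic mean of non-sentinel voxels per labeled region, restricted to
#' the `n_slices` central contiguous slices along `slice_axis` (the ROI
#' protocol: three contiguous coronal images). Sentinel (NA) voxels are
#' excluded; the used voxel count is reported.
#'
#' @param maps a `parameter_maps` object.
#' @param labels a `label_map` aligned with the maps.
#' @param slice_axis array axis of the slice direction (default 2, the
#'   coronal axis of the synthetic phantom).
#' @param n_slices number of central slices (default 3); clipped to the
#'   volume extent with a warning.
#' @return Data frame with columns region, metric, value, n_voxels.
#' @export
roi_means <- function(maps, labels, slice_axis = 2, n_slices = 3) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(labels, "label_map"))
  dims <- dim(maps$mk)
  if (!identical(dim(labels$labels), dims))
    stop("maps and labels must share one grid")
  extent <- dims[slice_axis]
  if (n_slices > extent) {
    warning("n_slices (", n_slices, ") exceeds volume extent (", extent,
            "); using the full volume")
    n_slices <- extent
  }
  lo <- floor((extent - n_slices) / 2) + 1
  keep <- seq(lo, lo + n_slices - 1)
  slicer <- rep(list(quote(expr = )), 3)
  slicer[[slice_axis]] <- keep
  sub <- function(a) do.call(`[`, c(list(a), slicer, drop = FALSE))
  lab <- sub(labels$labels)

  regions <- setdiff(unique(as.integer(labels$labels)), 0L)
  out <- list()
  for (metric in c("MK", "FA", "MD")) {
    m <- sub(maps[[tolower(metric)]])
    for (code in sort(regions)) {
      vals <- m[lab == code]
      vals <- vals[!is.na(vals)]
      region <- labels$legend[[as.character(code)]]
      if (!length(vals))
        stop("region-missing: no usable ", region, " voxels in the selected slices")
      out[[length(out) + 1]] <- data.frame(
        region = region, metric = metric,
        value = mean(vals), n_voxels = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-way random-effects absolute-agreement single-measure ICC
#'
#' ICC(2,1) from the two-way ANOVA mean squares of a subjects x raters table:
#' (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n), with the standard
#' F-based 95\% confidence interval.
#'
#' @param table ROI table restricted to one (region, metric) with a `rater`
#'   column covering every subject, or a numeric subjects x raters matrix.
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `lower`, `upper`, `n_subjects`, `n_raters`.
#' @export
icc_absolute_agreement <- function(table, conf = 0.95) {
  if (is.data.frame(table)) {
    validate_roi_table(table)
    if (!"rater" %in% names(table)) stop("table lacks a rater column")
    m <- tapply(table$value, list(table$subject, table$rater), mean)
    if (anyNA(m)) stop("every subject must be measured by both raters")
  } else {
    m <- as.matrix(table)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("insufficient-data: ICC needs >= 3 subjects")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) 1 else (msr - mse) / denom

  alpha <- 1 - conf
  if (icc >= 1) {
    lower <- upper <- icc <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(icc = icc, lower = min(lower, icc), upper = max(upper, icc),
       n_subjects = n, n_raters = k)
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares decomposition; P from the F
#' distribution with (k - 1, N - k) degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 levels, each with >= 2 values).
#' @return List with `f`, `p`, `df_between`, `df_within`, `mse` (pooled
#'   within-group mean square), `group_means`, `group_n`, and `degenerate`
#'   (TRUE when the within-group variance is zero).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  n_i <- tabulate(groups)
  if (k < 2 || any(n_i < 2))
    stop("need >= 2 groups with >= 2 values each")
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df_b <- k - 1; df_w <- n - k
  mse <- ss_within / df_w
  degenerate <- mse == 0
  if (degenerate && ss_between == 0) {
    f <- 0; p <- 1
  } else if (degenerate) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_between / df_b) / mse
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(f = f, p = p, df_between = df_b, df_within = df_w, mse = mse,
       group_means = means, group_n = n_i, degenerate = degenerate)
}

#' Least-significant-difference post-hoc comparisons
#'
#' Unadjusted pairwise t tests using the ANOVA pooled error: for groups a, b,
#' t = (m_a - m_b) / sqrt(MSE (1/n_a + 1/n_b)), two-sided P from t with
#' N - k degrees of freedom. No multiplicity adjustment (the LSD definition).
#'
#' @inheritParams anova_oneway
#' @return Data frame with columns group_a, group_b, mean_diff, t, p.
#' @export
lsd_posthoc <- function(values, groups) {
  a <- anova_oneway(values, groups)
  lev <- names(a$group_means)
  pairs <- utils::combn(seq_along(lev), 2)
  out <- data.frame(
    group_a = lev[pairs[1, ]], group_b = lev[pairs[2, ]],
    mean_diff = a$group_means[pairs[1, ]] - a$group_means[pairs[2, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(a$mse * (1 / a$group_n[pairs[1, ]] + 1 / a$group_n[pairs[2, ]]))
  out$t <- ifelse(se == 0, ifelse(out$mean_diff == 0, 0, Inf * sign(out$mean_diff)),
                  out$mean_diff / se)
  out$p <- ifelse(is.infinite(out$t), 0,
                  2 * stats::pt(abs(out$t), a$df_within, lower.tail = FALSE))
  out$p[out$t == 0] <- 1
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-sided P
#'
#' Sample correlation with P from the t transform, t = r sqrt((n-2)/(1-r^2)),
#' on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined: zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Assemble the cohort statistics report
#'
#' Builds the full statistical surface of the study design from a tidy ROI
#' table: per-cell mean +/- SD summary, per (timepoint, region, metric)
#' one-way ANOVA across groups with LSD post-hoc pairs, two-rater ICC per
#' (region, metric) when a rater table is given, and Pearson correlations of
#' each (metric, region) against fibrosis scores when given.
#'
#' @param table ROI table (single-rater measurements).
#' @param rater_table optional ROI table with a `rater` column (ICC input);
#'   by convention computed on one group (the disease group).
#' @param fibrosis optional data frame with columns subject, timepoint,
#'   region, mod — matched to the table rows by those keys.
#' @param icc_group group on which ICC is computed (default "HUA").
#' @param correlation_timepoints timepoints pooled into the correlation
#'   analysis (default the histology timepoints 1d/5d/9d).
#' @return A list of class `stats_report` with data frames `summary_table`,
#'   `anova_table`, `posthoc_table`, `icc_table`, `correlation_table`.
#' @export
summary_report <- function(table, rater_table = NULL, fibrosis = NULL,
                           icc_group = "HUA",
                           correlation_timepoints = c("1d", "5d", "9d")) {
  validate_roi_table(table)
  if (!nrow(table)) stop("empty ROI table")

  agg <- stats::aggregate(value ~ group + timepoint + region + metric,
                          data = table,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  summary_table <- data.frame(agg[1:4],
                              mean = agg$value[, "mean"],
                              sd = agg$value[, "sd"],
                              n = agg$value[, "n"])
  summary_table$label <- sprintf("%.3f ± %.3f", summary_table$mean,
                                 summary_table$sd)

  anova_rows <- list(); posthoc_rows <- list()
  strata <- unique(table[c("timepoint", "region", "metric")])
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    sub <- table[table$timepoint == st$timepoint & table$region == st$region &
                   table$metric == st$metric, ]
    if (length(unique(sub$group)) < 2) next
    a <- anova_oneway(sub$value, sub$group)
    anova_rows[[length(anova_rows) + 1]] <-
      data.frame(st, f = a$f, p = a$p, stringsAsFactors = FALSE)
    ph <- lsd_posthoc(sub$value, sub$group)
    posthoc_rows[[length(posthoc_rows) + 1]] <- data.frame(st, ph, row.names = NULL)
  }
  anova_table <- if (length(anova_rows)) do.call(rbind, anova_rows) else
    data.frame(timepoint = character(), region = character(),
               metric = character(), f = numeric(), p = numeric())
  posthoc_table <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else NULL

  icc_table <- NULL
  if (!is.null(rater_table)) {
    rt <- rater_table[rater_table$group == icc_group, ]
    combos <- unique(rt[c("region", "metric")])
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      sub <- rt[rt$region == combos$region[i] & rt$metric == combos$metric[i], ]
      # subject x timepoint remeasurements are distinct "targets" for agreement
      sub$subject <- paste(sub$subject, sub$timepoint, sep = "@")
      sub <- sub[c("subject", "group", "timepoint", "region", "metric",
                   "value", "rater")]
      res <- icc_absolute_agreement(sub)
      data.frame(region = combos$region[i], metric = combos$metric[i],
                 icc = res$icc, lower = res$lower, upper = res$upper,
                 n = res$n_subjects)
    })
    icc_table <- do.call(rbind, rows)
  }

  correlation_table <- NULL
  if (!is.null(fibrosis)) {
    sub <- table[table$timepoint %in% correlation_timepoints, ]
    merged <- merge(sub, fibrosis,
                    by = intersect(names(sub), c("subject", "timepoint", "region")))
    combos <- unique(merged[c("region", "metric")])
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      mm <- merged[merged$region == combos$region[i] &
                     merged$metric == combos$metric[i], ]
      if (nrow(mm) < 3) return(NULL)
      pc <- pearson_cor(mm$value, mm$mod)
      data.frame(region = combos$region[i], metric = combos$metric[i],
                 r = pc$r, p = pc$p, n = pc$n)
    })
    rows <- Filter(Negate(is.null), rows)
    correlation_table <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  structure(list(summary_table = summary_table, anova_table = anova_table,
                 posthoc_table = posthoc_table, icc_table = icc_table,
                 correlation_table = correlation_table),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report\n")
  sig <- x$anova_table[x$anova_table$p < 0.05, , drop = FALSE]
  cat(" ANOVA strata:", nrow(x$anova_table), "; significant (P < 0.05):",
      nrow(sig), "\n")
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  * %s %s %s: F = %.2f, P = %.4g\n", sig$metric[i],
                  sig$region[i], sig$timepoint[i], sig$f[i], sig$p[i]))
  }
  if (!is.null(x$icc_table)) {
    cat(" ICC range:", sprintf("%.3f-%.3f", min(x$icc_table$icc),
                               max(x$icc_table$icc)), "\n")
  }
  if (!is.null(x$correlation_table)) {
    for (i in seq_len(nrow(x$correlation_table)))
      cat(sprintf(" r(%s_%s, MOD) = %.3f (P = %.4g, n = %d)\n",
                  x$correlation_table$metric[i], x$correlation_table$region[i],
                  x$correlation_table$r[i], x$correlation_table$p[i],
                  x$correlation_table$n[i]))
  }
  invisible(x)
}

#' Serialize a stats report
#'
#' Writes each populated sub-table as CSV plus a combined JSON file.
#'
#' @param report a `stats_report`.
#' @param directory output directory (created on demand).
#' @return Named vector of written paths, invisibly.
#' @export
write_stats_report <- function(report, directory) {
  stopifnot(inherits(report, "stats_report"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    if (is.null(report[[nm]])) next
    p <- file.path(directory, paste0(sub("_table$", "", nm), ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  jp <- file.path(directory, "report.json")
  jsonlite::write_json(Filter(Negate(is.null), unclass(report)), jp,
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  paths["json"] <- jp
  invisible(paths)
}
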