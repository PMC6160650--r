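# Tabular statistics downstream of the imaging: per-subject outcome tables,
# group comparisons of change scores, correlation matrices with
# average-linkage clustering for heat maps, and baseline comparisons.

#' Assemble the per-subject outcome table
#'
#' One row per subject with group, baseline and final values, and absolute
#' change (final minus baseline) for each measure: region (TIS) volume,
#' whole GM, WM, CSF, lesion volumes, PASAT2/3, 9HPT, T25FW, MSFC and EDSS
#' analogues carried in the cohort's covariates.
#'
#' @param dataset a `cohort_dataset`.
#' @param tis_series optional `region_volume_series` supplying the TIS
#'   volume columns.
#' @return data.frame of class `outcome_table`.
#' @export
outcome_table <- function(dataset, tis_series = NULL) {
  cov <- dataset$covariates
  months <- sort(unique(cov$month))
  m0 <- months[1]; m1 <- months[length(months)]
  measures <- intersect(c("gm_ml", "wm_ml", "csf_ml", "gd_ml", "flair_ml",
                          "pasat2", "pasat3", "hpt9", "t25fw", "msfc", "edss"),
                        names(cov))
  out <- do.call(rbind, lapply(split(cov, cov$subject), function(df) {
    if (!any(df$month == m0) || !any(df$month == m1)) return(NULL)
    row <- data.frame(subject = df$subject[1], group = df$group[1])
    for (m in measures) {
      b <- df[[m]][df$month == m0][1]
      f <- df[[m]][df$month == m1][1]
      row[[paste0(m, "_baseline")]] <- b
      row[[paste0(m, "_final")]] <- f
      row[[paste0(m, "_change")]] <- f - b
    }
    row
  }))
  rownames(out) <- NULL
  if (!is.null(tis_series)) {
    s <- tis_series$subjects
    i <- match(out$subject, s$subject)
    out$tis_ml_baseline <- s$baseline_ml[i]
    out$tis_ml_final <- s$final_ml[i]
    out$tis_ml_change <- s$change_ml[i]
  }
  class(out) <- c("outcome_table", class(out))
  out
}

#' Mean absolute changes per group and overall
#'
#' The conventional trial change table: for every `*_change` column, the
#' mean over all subjects and within each arm, plus the group-difference
#' regression p-value.
#'
#' @param outcomes an `outcome_table`.
#' @return data.frame with one row per measure: overall and per-group mean
#'   change and the two-sided p for the group difference.
#' @export
change_table <- function(outcomes) {
  chg_cols <- grep("_change$", names(outcomes), value = TRUE)
  groups <- sort(unique(outcomes$group))
  rows <- lapply(chg_cols, function(cc) {
    x <- outcomes[[cc]]
    if (all(is.na(x))) {
      warning("change column ", cc, " is entirely missing; omitted")
      return(NULL)
    }
    row <- data.frame(measure = sub("_change$", "", cc),
                      mean_all = mean(x, na.rm = TRUE))
    for (g in groups)
      row[[paste0("mean_", g)]] <- mean(x[outcomes$group == g], na.rm = TRUE)
    p <- tryCatch(group_difference_regression(x, outcomes$group)$p,
                  error = function(e) NA_real_)
    row$p_value <- p
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group difference in a change score by linear regression
#'
#' OLS of the change on a treated-arm indicator (plus optional covariates);
#' the estimate is the adjusted between-group difference (second sorted
#' group level minus first), with its SE and two-sided t-test p-value.
#'
#' @param change numeric vector of change scores.
#' @param group two-level group labels.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list(estimate, se, p, treated_level).
#' @export
group_difference_regression <- function(change, group, covariates = NULL) {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) < 2L) stop("need two groups")
  if (length(lev) > 2L) stop("more than two groups")
  keep <- !is.na(change)
  dat <- data.frame(change = change[keep],
                    g = as.integer(group[keep] == lev[2]))
  if (nrow(dat) < 3L) stop("need at least 3 observations")
  form <- change ~ g
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates[keep, , drop = FALSE])
    form <- stats::reformulate(c("g", colnames(covariates)),
                               response = "change")
  }
  fit <- summary(stats::lm(form, data = dat))$coefficients
  list(estimate = fit["g", "Estimate"], se = fit["g", "Std. Error"],
       p = fit["g", "Pr(>|t|)"], treated_level = lev[2])
}

#' Pearson correlation matrix over change scores, with clustering order
#'
#' Pairwise-complete Pearson r and two-sided p per pair, plus an
#' average-linkage hierarchical clustering on distance 1 - r supplying the
#' ordering used for heat-map display.
#'
#' @param outcomes an `outcome_table` (its `*_change` columns are used) or a
#'   plain numeric data.frame.
#' @param by_group when TRUE, returns one result per group level.
#' @return list of class `correlation_result`: `r`, `p` (matrices),
#'   `order` (display order), `hclust`; or a named list of such per group.
#' @export
pearson_matrix <- function(outcomes, by_group = FALSE) {
  if (by_group) {
    groups <- sort(unique(outcomes$group))
    res <- lapply(groups, function(g)
      pearson_matrix(outcomes[outcomes$group == g, , drop = FALSE],
                     by_group = FALSE))
    names(res) <- groups
    return(res)
  }
  if (inherits(outcomes, "outcome_table")) {
    cols <- grep("_change$", names(outcomes), value = TRUE)
    dat <- outcomes[cols]
    names(dat) <- sub("_change$", "", cols)
  } else dat <- as.data.frame(outcomes)
  dat <- dat[vapply(dat, is.numeric, logical(1))]
  k <- ncol(dat)
  r <- matrix(NA_real_, k, k, dimnames = list(names(dat), names(dat)))
  p <- r
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(dat[[i]], dat[[j]])
    if (sum(ok) < 3L) next
    if (stats::sd(dat[[i]][ok]) == 0 || stats::sd(dat[[j]][ok]) == 0) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(dat[[i]][ok], dat[[j]][ok])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  usable <- !apply(is.na(r), 1, all)
  hc <- NULL; ord <- seq_len(k)
  if (sum(usable) >= 2L) {
    ru <- r[usable, usable, drop = FALSE]
    ru[is.na(ru)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - ru), method = "average")
    ord <- which(usable)[hc$order]
  }
  structure(list(r = r, p = p, order = ord, hclust = hc),
            class = "correlation_result")
}

#' Baseline group comparison
#'
#' Continuous measures: Wilcoxon rank-sum with the normal approximation and
#' tie correction; categorical: Pearson chi-square on the contingency table
#' (no continuity correction by default).
#'
#' @param values vector of baseline values (numeric, or labels for
#'   categorical).
#' @param group two-level group labels.
#' @param type "continuous" or "categorical".
#' @param correct apply Yates continuity correction to the chi-square.
#' @return list(p, statistic, method).
#' @export
baseline_compare <- function(values, group,
                             type = c("continuous", "categorical"),
                             correct = FALSE) {
  type <- match.arg(type)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) < 2L || any(table(group) == 0)) stop("need two non-empty groups")
  if (type == "continuous") {
    wt <- stats::wilcox.test(values[group == lev[1]], values[group == lev[2]],
                             exact = FALSE, correct = FALSE)
    list(p = wt$p.value, statistic = unname(wt$statistic),
         method = "wilcoxon_rank_sum")
  } else {
    tab <- table(values, group)
    if (nrow(tab) < 2L) stop("degenerate contingency table (single category)")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(p = ct$p.value, statistic = unname(ct$statistic),
         method = "chi_square")
  }
}

#' Correlation heat map
#'
#' Renders a `correlation_result` with average-linkage ordering, positive
#' correlations in yellow and negative in red, written as a PNG.
#'
#' @param corr a `correlation_result`.
#' @param file output PNG path.
#' @param title plot title.
#' @return `file`, invisibly.
#' @export
correlation_heatmap <- function(corr, file, title = "correlation of changes") {
  r <- corr$r
  r[is.na(r)] <- 0
  pal <- grDevices::colorRampPalette(c("#8b0000", "#ff0000", "#000000",
                                       "#ffff00", "#ffffb0"))(101)
  grDevices::png(file, width = 900, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  if (!is.null(corr$hclust)) {
    pheatmap::pheatmap(r, color = pal, breaks = seq(-1, 1, length.out = 102),
                       clustering_method = "average",
                       clustering_distance_rows = stats::as.dist(1 - r),
                       clustering_distance_cols = stats::as.dist(1 - r),
                       main = title, silent = FALSE)
  } else {
    pheatmap::pheatmap(r, color = pal, breaks = seq(-1, 1, length.out = 102),
                       cluster_rows = FALSE, cluster_cols = FALSE,
                       main = title, silent = FALSE)
  }
  invisible(file)
}
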