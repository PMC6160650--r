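# Mass-univariate general linear model over in-mask voxels.
#
# The longitudinal design follows the standard SPM-style two-level-in-one
# layout: intercept-free subject indicator columns absorb every
# subject-constant effect (individual anatomy, group membership), site
# indicators (reference-coded) absorb scanner offsets, a numeric time
# regressor (years) carries the common atrophy trend, and the group x time
# interaction is the effect of interest -- its coefficient is the annualized
# difference in GM change between arms. Because site is constant within
# subject the site columns are linearly dependent on the subject columns;
# fitting uses the Moore-Penrose pseudoinverse, the numerical rank sets the
# residual degrees of freedom, and contrasts are checked for estimability.

#' Build a longitudinal VBM design matrix
#'
#' @param covariates data.frame with columns `subject`, `group`, `site`,
#'   `month`, one row per scan.
#' @param score_column optional name of a covariate-of-interest column
#'   (e.g. "pasat2") appended as the last regressor.
#' @param interaction include the group x time interaction column
#'   (reference arm = first level alphabetically, so "placebo"; the column
#'   is time-in-years for the other arm).
#' @param global_column optional name of a per-scan global GM column used
#'   for ANCOVA-style global normalization; dropped with a message when it
#'   adds no rank (e.g. in noise-free degenerate designs).
#' @return list of class `design_matrix`: `X` (matrix with named columns),
#'   `rank` (numerical rank), `roles` (column roles), `treated_level`.
#' @export
build_design <- function(covariates, score_column = NULL, interaction = TRUE,
                         global_column = NULL) {
  req <- c("subject", "group", "site", "month")
  if (!all(req %in% names(covariates)))
    stop("covariates must contain columns: ", paste(req, collapse = ", "))
  if (anyNA(covariates[req])) stop("missing values in subject/group/site/month")
  groups <- sort(unique(covariates$group))
  if (interaction && length(groups) != 2L)
    stop("exactly two groups are required for a group x time interaction")
  subj <- factor(covariates$subject)
  if (interaction) {
    per_group <- tapply(covariates$subject, covariates$group,
                        function(s) length(unique(s)))
    if (any(per_group < 1L) || length(per_group) < 2L)
      stop("need subjects in both groups")
  }

  S <- stats::model.matrix(~ 0 + subj)
  colnames(S) <- paste0("subj_", levels(subj))
  roles <- rep("subject", ncol(S))
  X <- S

  site <- factor(covariates$site)
  if (nlevels(site) > 1L) {
    Z <- stats::model.matrix(~ site)[, -1, drop = FALSE]
    colnames(Z) <- paste0("site_", levels(site)[-1])
    X <- cbind(X, Z)
    roles <- c(roles, rep("site", ncol(Z)))
  } else {
    warning("single-site cohort: site columns omitted")
  }

  time_years <- covariates$month / 12
  X <- cbind(X, time_years = time_years)
  roles <- c(roles, "time")

  treated_level <- if (length(groups) == 2L) groups[2] else NA_character_
  if (interaction) {
    gt <- time_years * (covariates$group == treated_level)
    if (all(gt == 0))
      stop("degenerate group x time interaction (constant zero column)")
    X <- cbind(X, group_time = gt)
    roles <- c(roles, "interaction")
  }

  if (!is.null(global_column)) {
    if (!global_column %in% names(covariates))
      stop("global column '", global_column, "' not found")
    gl <- covariates[[global_column]]
    if (qr(cbind(X, gl))$rank > qr(X)$rank) {
      X <- cbind(X, gl)
      colnames(X)[ncol(X)] <- global_column
      roles <- c(roles, "global")
    } else {
      message("global covariate adds no rank; omitted")
    }
  }

  if (!is.null(score_column)) {
    if (!score_column %in% names(covariates))
      stop("score column '", score_column, "' not found")
    sc <- covariates[[score_column]]
    if (anyNA(sc)) stop("missing values in score column")
    if (stats::sd(sc) == 0) stop("score column is constant")
    X <- cbind(X, sc)
    colnames(X)[ncol(X)] <- score_column
    roles <- c(roles, "score")
  }

  rank_full <- qr(X)$rank
  # redundancy from site-within-subject nesting is expected; anything beyond
  # that means genuinely confounded regressors
  n_site_cols <- sum(roles == "site")
  expected_min <- ncol(X) - n_site_cols
  if (rank_full < expected_min) {
    # identify offending non-factor columns by leave-one-out rank
    keep <- which(!roles %in% c("subject", "site"))
    bad <- character(0)
    for (j in keep) {
      if (qr(X[, -j, drop = FALSE])$rank == rank_full) bad <- c(bad, colnames(X)[j])
    }
    stop("rank-deficient design beyond factor redundancy; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, rank = rank_full, roles = roles,
                 treated_level = treated_level,
                 score_column = score_column),
            class = "design_matrix")
}

#' Fit the GLM at every in-mask voxel
#'
#' Ordinary least squares through the design's pseudoinverse (identity
#' residual covariance, the default scheme), or whitened least squares under
#' a single global exchangeable within-subject correlation estimated by
#' pooled method of moments over in-mask voxels.
#'
#' @param dataset a `cohort_dataset` (smooth it first for VBM-style maps).
#' @param design a `design_matrix` whose rows align with the dataset's scans.
#' @param scheme "identity" (pure OLS) or "exchangeable".
#' @return list of class `voxel_fit`: coefficients, residual variance,
#'   residual degrees of freedom (scans - rank), the in-mask voxel index,
#'   and a flag for zero-variance voxels (excluded from inference).
#' @export
fit_voxelwise <- function(dataset, design, scheme = c("identity", "exchangeable")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(design, "design_matrix"))
  X <- design$X
  n_scan <- dim(dataset$images)[4]
  if (nrow(X) != n_scan) stop("design rows do not match the number of scans")
  mask_idx <- which(dataset$brain_mask$data == 1L)
  if (length(mask_idx) == 0L) stop("empty brain mask")
  Y <- t(matrix(dataset$images, ncol = n_scan)[mask_idx, , drop = FALSE])

  if (scheme == "exchangeable") {
    w <- exchangeable_whitener(Y, X, dataset$covariates$subject)
    X <- w$WX; Y <- w$WY
  }

  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  rank <- sum(pos)
  df <- n_scan - rank
  if (df <= 0) stop("non-positive residual degrees of freedom")
  Ut_Y <- crossprod(sv$u[, pos, drop = FALSE], Y)
  beta <- sv$v[, pos, drop = FALSE] %*% (Ut_Y / sv$d[pos])
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  cm <- colMeans(Y)
  zero_var <- (colSums(Y^2) - nrow(Y) * cm^2) <= 0
  xtx_pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
  rowspace <- sv$v[, pos, drop = FALSE]
  structure(list(beta = beta, sigma2 = sigma2, df = df, rank = rank,
                 xtx_pinv = xtx_pinv, rowspace = rowspace,
                 colnames = colnames(design$X), design = design,
                 mask_idx = mask_idx, grid = dim(dataset$images)[1:3],
                 affine = dataset$affine,
                 voxel_size_mm = dataset$voxel_size_mm,
                 zero_var = zero_var, scheme = scheme,
                 residual_ss = sigma2 * df),
            class = "voxel_fit")
}

# Pooled method-of-moments estimate of a single exchangeable within-subject
# residual correlation, applied by block whitening of both sides of the model.
exchangeable_whitener <- function(Y, X, subject) {
  qrX <- qr(X)
  R <- qr.resid(qrX, Y)
  subj <- factor(subject)
  num <- 0; den <- 0; n_pair <- 0
  for (s in levels(subj)) {
    rows <- which(subj == s)
    if (length(rows) < 2L) next
    Rs <- R[rows, , drop = FALSE]
    cp <- crossprod(t(Rs))  # within-subject scan x scan cross-products over voxels
    num <- num + sum(cp[upper.tri(cp)])
    n_pair <- n_pair + sum(upper.tri(cp))
    den <- den + sum(diag(cp)) / length(rows) * 1
  }
  rho <- (num / n_pair) / (den / length(levels(subj)))
  rho <- min(max(rho, -0.49), 0.99)
  WX <- X; WY <- Y
  for (s in levels(subj)) {
    rows <- which(subj == s)
    k <- length(rows)
    V <- matrix(rho, k, k); diag(V) <- 1
    e <- eigen(V, symmetric = TRUE)
    W <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-8)), k) %*% t(e$vectors)
    WX[rows, ] <- W %*% X[rows, , drop = FALSE]
    WY[rows, ] <- W %*% Y[rows, , drop = FALSE]
  }
  list(WX = WX, WY = WY, rho = rho)
}

#' Contrast t-map from a voxelwise fit
#'
#' Computes t = c'beta / sqrt(sigma2 * c'(X'X)^+ c) per voxel, one-sided p
#' from Student's t at the fit's residual df, and the Z-equivalent
#' (standard-normal quantile of 1 - p, computed on the log scale so extreme
#' t values keep finite, accurate Z scores).
#'
#' @param fit a `voxel_fit`.
#' @param weights named or positional contrast vector over design columns,
#'   or the name of a single column (weight 1 on it).
#' @return list of class `stat_map`: 3D `t`, `p`, `z` arrays (NA off-mask),
#'   scalar `df`, the contrast, and grid geometry.
#' @export
contrast_t <- function(fit, weights) {
  stopifnot(inherits(fit, "voxel_fit"))
  p <- length(fit$colnames)
  if (is.character(weights) && length(weights) == 1L) {
    cname <- weights
    weights <- numeric(p); names(weights) <- fit$colnames
    if (!cname %in% fit$colnames) stop("no design column '", cname, "'")
    weights[cname] <- 1
  }
  if (!is.null(names(weights)) && !all(names(weights) %in% fit$colnames))
    stop("unknown contrast column names")
  cvec <- numeric(p)
  if (is.null(names(weights))) {
    if (length(weights) != p) stop("contrast length must match design columns")
    cvec <- as.numeric(weights)
  } else cvec[match(names(weights), fit$colnames)] <- weights
  if (all(cvec == 0)) stop("contrast weights are all zero")
  # estimable iff c lies in the design's row space
  proj <- fit$rowspace %*% crossprod(fit$rowspace, cvec)
  if (max(abs(proj - cvec)) > 1e-8 * max(1, max(abs(cvec))))
    stop("contrast is not estimable in this design")

  est <- as.numeric(crossprod(cvec, fit$beta))
  cvar <- as.numeric(crossprod(cvec, fit$xtx_pinv %*% cvec))
  se <- sqrt(fit$sigma2 * cvar)
  tval <- est / se
  tval[fit$zero_var | se == 0] <- NA_real_
  logp <- stats::pt(tval, fit$df, lower.tail = FALSE, log.p = TRUE)
  pval <- exp(logp)
  zval <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)

  to_map <- function(v) {
    m <- array(NA_real_, fit$grid); m[fit$mask_idx] <- v; m
  }
  structure(list(t = to_map(tval), p = to_map(pval), z = to_map(zval),
                 df = fit$df,
                 contrast = list(name = paste(fit$colnames[cvec != 0],
                                              collapse = "+"),
                                 weights = stats::setNames(cvec, fit$colnames)),
                 mask_idx = fit$mask_idx, grid = fit$grid,
                 affine = fit$affine, voxel_size_mm = fit$voxel_size_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  tv <- x$t[x$mask_idx]
  cat("stat_map (", x$contrast$name, "): df ", x$df, ", t range ",
      paste(signif(range(tv, na.rm = TRUE), 3), collapse = " .. "), "\n",
      sep = "")
  invisible(x)
}

#' Voxelwise partial-correlation map for a clinical score
#'
#' Refits the longitudinal GLM with the score as the covariate of interest,
#' controlling subject, site, time, the group x time trend, and (by
#' default) the per-scan global GM as nuisance. The returned map carries the
#' score regressor's t statistic and the corresponding partial correlation
#' r = t / sqrt(t^2 + df); positive values mean higher GM goes with a higher
#' score.
#'
#' @param dataset a `cohort_dataset` (smoothed).
#' @param score_column name of the score column (e.g. "pasat2").
#' @param scheme residual covariance scheme passed to [fit_voxelwise()].
#' @param global_normalization include the per-scan in-mask mean GM as an
#'   ANCOVA nuisance covariate.
#' @return A `stat_map` with an extra 3D `r` array.
#' @export
correlation_map <- function(dataset, score_column,
                            scheme = c("identity", "exchangeable"),
                            global_normalization = TRUE) {
  scheme <- match.arg(scheme)
  cov <- dataset$covariates
  gcol <- NULL
  if (global_normalization) {
    cov$gm_global <- scan_global_means(dataset)
    gcol <- "gm_global"
  }
  design <- build_design(cov, score_column = score_column,
                         interaction = TRUE, global_column = gcol)
  fit <- fit_voxelwise(dataset, design, scheme = scheme)
  sm <- contrast_t(fit, score_column)
  tv <- sm$t[sm$mask_idx]
  r <- tv / sqrt(tv^2 + sm$df)
  rm <- array(NA_real_, sm$grid); rm[sm$mask_idx] <- r
  sm$r <- rm
  sm
}

# Per-scan mean GM over the brain mask, the standard "global" used for
# ANCOVA-style global normalization of modulated VBM data.
scan_global_means <- function(dataset) {
  idx <- which(dataset$brain_mask$data == 1L)
  n_scan <- dim(dataset$images)[4]
  colMeans(matrix(dataset$images, ncol = n_scan)[idx, , drop = FALSE])
}
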