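#' Fisher Z-transform of correlation values
#'
#' `z = atanh(r)`, strictly monotone and odd. Values at exactly +/-1 are
#' clipped to +/-(1 - 1e-7) before transforming; the number of clipped
#' entries is reported in attribute `"n_clipped"`.
#'
#' @param r Numeric vector/matrix of correlations in `[-1, 1]`.
#' @return Transformed object of the same shape.
#' @export
fisher_z <- function(r) {
  clip <- abs(r) >= 1
  if (any(clip)) r[clip] <- sign(r[clip]) * (1 - 1e-7)
  out <- atanh(r)
  attr(out, "n_clipped") <- sum(clip)
  out
}

#' Voxel-wise one-sample tests with family-wise-error control
#'
#' Tests each voxel's across-subject mean (Fisher-Z) value against zero and
#' Bonferroni-corrects the two-sided p-values over the in-mask voxels — a
#' conservative family-wise-error control. Voxels with zero across-subject
#' variance are flagged and excluded from inference.
#'
#' @param z_maps `S x V` matrix of subject-level values (subjects in rows).
#' @param alpha Corrected significance level (default 0.05).
#' @param mask Optional logical length-`V` analysis mask; correction counts
#'   only in-mask voxels.
#' @return A `venc_group_map` tibble: `voxel`, `mean_z`, `t`, `df`, `p`,
#'   `p_corrected`, `significant`, `flagged`.
#' @export
one_sample_fwe <- function(z_maps, alpha = 0.05, mask = NULL) {
  z_maps <- as.matrix(z_maps)
  s <- nrow(z_maps)
  if (s < 3) stop_venc("need at least 3 subjects")
  v <- ncol(z_maps)
  mask <- mask %||% rep(TRUE, v)
  mu <- colMeans(z_maps)
  sdv <- apply(z_maps, 2, sd)
  flagged <- sdv <= sqrt(VAR_EPS) | !mask
  tstat <- rep(NA_real_, v)
  tstat[!flagged] <- mu[!flagged] / (sdv[!flagged] / sqrt(s))
  p <- 2 * pt(-abs(tstat), df = s - 1)
  n_tests <- sum(mask & sdv > sqrt(VAR_EPS))
  p_corr <- pmin(1, p * n_tests)
  out <- tibble::tibble(
    voxel = seq_len(v), mean_z = mu, t = tstat, df = s - 1, p = p,
    p_corrected = p_corr,
    significant = !flagged & !is.na(p_corr) & p_corr < alpha,
    flagged = flagged
  )
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  class(out) <- c("venc_group_map", class(out))
  out
}

#' Two-sample test on ROI-mean values
#'
#' Classic pooled-variance two-sample t-test on subject-level ROI means,
#' e.g. dorsal vs ventral mean Fisher-Z prediction accuracy.
#'
#' @param x,y Numeric vectors of subject-level ROI means (size >= 2 each).
#' @return Tibble with `estimate` (mean difference), `t`, `df`, `p`.
#' @export
two_sample_roi_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_venc("both samples need at least 2 values")
  ht <- t.test(x, y, var.equal = TRUE)
  tibble::tibble(estimate = unname(ht$estimate[1] - ht$estimate[2]),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

# One-sample t-test that tolerates zero-variance inputs: a vector of
# identical values is either exactly null (p = 1) or a constant effect every
# subject shows (t infinite, p = 0).
paired_t_safe <- function(d) {
  if (sd(d) <= sqrt(VAR_EPS)) {
    if (abs(mean(d)) <= sqrt(VAR_EPS)) {
      return(list(t = 0, df = length(d) - 1, p = 1))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0))
  }
  ht <- t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

# Orthonormal within-factor contrast basis (k - 1 columns).
ortho_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Greenhouse-Geisser epsilon from subject-level scores on an orthonormal
# contrast basis: (tr S)^2 / (m * tr(S^2)).
gg_epsilon <- function(scores) {
  m <- ncol(scores)
  if (m == 1L) return(1)
  s <- stats::cov(scores)
  sum(diag(s))^2 / (m * sum(s^2))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for one or two factors on a complete balanced
#' design. Each effect is tested against its effect-by-subject interaction;
#' degrees of freedom are multiplied by the Greenhouse-Geisser epsilon
#' (computed from the sample covariance of the subject-level orthonormal
#' contrast scores), and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Tidy tibble/data.frame with a subject column, one column per
#'   within-subject factor, and a value column.
#' @param factors Character vector naming the factor column(s) (1 or 2).
#' @param subject,value Names of the subject and value columns.
#' @return A `venc_anova` tibble: one row per effect with `ss`, `ss_error`,
#'   `df1`, `df2` (corrected), `epsilon`, `statistic`, `partial_eta_sq`, `p`.
#' @export
rm_anova_gg <- function(data, factors, subject = "subject", value = "value") {
  data <- as.data.frame(data)
  if (!all(c(subject, value, factors) %in% names(data))) {
    stop_venc("missing columns in `data`")
  }
  if (length(factors) < 1 || length(factors) > 2) {
    stop_venc("one or two within-subject factors supported")
  }
  subj <- factor(data[[subject]])
  f1 <- factor(data[[factors[1]]])
  y <- data[[value]]
  ns <- nlevels(subj)
  two <- length(factors) == 2
  f2 <- if (two) factor(data[[factors[2]]])
  a <- nlevels(f1); b <- if (two) nlevels(f2) else 1L
  cells <- if (two) table(subj, f1, f2) else table(subj, f1)
  if (any(cells != 1)) stop_venc("design must be complete and balanced (one value per cell)")
  # subject x a x b cell array
  yarr <- array(NA_real_, c(ns, a, b))
  i1 <- as.integer(f1); i2 <- if (two) as.integer(f2) else 1L
  yarr[cbind(as.integer(subj), i1, i2)] <- y
  g <- mean(yarr)
  m_s <- apply(yarr, 1, mean)
  m_a <- apply(yarr, 2, mean)
  m_b <- apply(yarr, 3, mean)
  m_sa <- apply(yarr, c(1, 2), mean)
  m_sb <- apply(yarr, c(1, 3), mean)
  m_ab <- apply(yarr, c(2, 3), mean)

  eff <- function(name, ss, ss_err, df1, df2, eps) {
    tibble::tibble(effect = name, ss = ss, ss_error = ss_err,
                   df1 = eps * df1, df2 = eps * df2, epsilon = eps,
                   statistic = (ss / df1) / (ss_err / df2),
                   partial_eta_sq = ss / (ss + ss_err),
                   p = pf((ss / df1) / (ss_err / df2), eps * df1, eps * df2,
                          lower.tail = FALSE))
  }
  ca <- ortho_contrasts(a)
  ss_a <- ns * b * sum((m_a - g)^2)
  ss_as <- b * sum(sweep(sweep(m_sa, 2, m_a), 1, m_s - g)^2)
  res <- eff(factors[1], ss_a, ss_as, a - 1, (a - 1) * (ns - 1),
             gg_epsilon(m_sa %*% ca))
  if (two) {
    cb <- ortho_contrasts(b)
    ss_b <- ns * a * sum((m_b - g)^2)
    ss_bs <- a * sum(sweep(sweep(m_sb, 2, m_b), 1, m_s - g)^2)
    res <- rbind(res, eff(factors[2], ss_b, ss_bs, b - 1, (b - 1) * (ns - 1),
                          gg_epsilon(m_sb %*% cb)))
    dev_ab <- sweep(sweep(m_ab, 1, m_a), 2, m_b) + g
    ss_ab <- ns * sum(dev_ab^2)
    resid <- yarr
    for (s in seq_len(ns)) {
      resid[s, , ] <- yarr[s, , ] - m_sa[s, ] %o% rep(1, b) -
        rep(1, a) %o% m_sb[s, ] - m_ab + outer(m_a, rep(1, b)) +
        outer(rep(1, a), m_b) + m_s[s] - g
    }
    ss_abs <- sum(resid^2)
    cab <- kronecker(cb, ca) # matches vec(a x b) with a fastest
    scores <- t(apply(yarr, 1, function(mat) as.vector(mat))) %*% cab
    res <- rbind(res, eff(paste0(factors[1], ":", factors[2]), ss_ab, ss_abs,
                          (a - 1) * (b - 1), (a - 1) * (b - 1) * (ns - 1),
                          gg_epsilon(scores)))
  }
  class(res) <- c("venc_anova", class(res))
  attr(res, "n_subjects") <- ns
  res
}

#' Within-subject contrast tests with multiplicity correction
#'
#' Each contrast is evaluated as a per-subject score (weighted sum of that
#' subject's condition means, weights summing to zero), tested against zero
#' with a one-sample t-test, and corrected across contrasts.
#'
#' @param data Tidy tibble with subject, condition, and value columns.
#' @param contrasts Named list of weight vectors. Weights may be named by
#'   condition level; unnamed weights are matched to the sorted levels.
#' @param correction Multiplicity correction (default `"bonferroni"`); any
#'   [stats::p.adjust()] method.
#' @param subject,condition,value Column names.
#' @return Tibble: `contrast`, `estimate`, `t`, `df`, `p`, `p_adjusted`.
#' @export
contrast_tests <- function(data, contrasts, correction = "bonferroni",
                           subject = "subject", condition = "condition",
                           value = "value") {
  data <- as.data.frame(data)
  cond <- factor(data[[condition]])
  subj <- factor(data[[subject]])
  lv <- levels(cond)
  cellmeans <- tapply(data[[value]], list(subj, cond), mean)
  rows <- lapply(names(contrasts) %||% seq_along(contrasts), function(nm) {
    w <- contrasts[[nm]]
    if (!is.null(names(w))) {
      ww <- numeric(length(lv)); names(ww) <- lv
      if (length(setdiff(names(w), lv))) stop_venc("contrast names unknown: %s", nm)
      ww[names(w)] <- w
      w <- ww
    }
    if (length(w) != length(lv)) stop_venc("contrast '%s' has wrong length", nm)
    if (abs(sum(w)) > 1e-10) stop_venc("contrast '%s' weights do not sum to zero", nm)
    score <- drop(cellmeans %*% w)
    ht <- paired_t_safe(score)
    tibble::tibble(contrast = as.character(nm), estimate = mean(score),
                   t = ht$t, df = ht$df, p = ht$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = correction)
  out
}

#' Normalized within-subject confidence intervals
#'
#' Removes between-subject offsets before computing condition-wise intervals
#' (subtract each subject's mean, add back the grand mean) and multiplies
#' the half-width by `sqrt(M / (M - 1))` for `M` conditions, correcting the
#' variance deflation of the subject-centering step.
#'
#' @param data `S x M` matrix of subject-by-condition means, or a tidy
#'   tibble with subject/condition/value columns.
#' @param level Confidence level (default 0.95).
#' @param subject,condition,value Column names for tidy input.
#' @return Tibble: `condition`, `mean`, `ci_half_width`, `lower`, `upper`.
#' @export
normalized_ci <- function(data, level = 0.95, subject = "subject",
                          condition = "condition", value = "value") {
  if (!is.matrix(data)) {
    df <- as.data.frame(data)
    data <- tapply(df[[value]], list(factor(df[[subject]]), factor(df[[condition]])),
                   mean)
  }
  m <- ncol(data)
  if (m < 2) stop_venc("normalization undefined for a single condition")
  if (any(is.na(data))) stop_venc("missing cells in the subject x condition table")
  ns <- nrow(data)
  adj <- data - rowMeans(data) + mean(data)
  mu <- colMeans(adj)
  se <- apply(adj, 2, sd) / sqrt(ns)
  half <- qt((1 + level) / 2, ns - 1) * se * sqrt(m / (m - 1))
  tibble::tibble(condition = colnames(data) %||% as.character(seq_len(m)),
                 mean = colMeans(data), ci_half_width = half,
                 lower = colMeans(data) - half, upper = colMeans(data) + half)
}
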