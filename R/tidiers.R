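# broom-style methods for the package's result objects.

#' Tidy per-session correlations of an encoding result
#'
#' @param x A `venc_encoding` from [encode_all_voxels()].
#' @param ... Unused.
#' @return Long tibble: `voxel`, `session`, `r`.
#' @export
tidy.venc_encoding <- function(x, ...) {
  r <- x$r_by_session
  tibble::tibble(
    voxel = rep(x$voxel, times = ncol(r)),
    session = rep(seq_len(ncol(r)), each = nrow(r)),
    r = as.vector(r)
  )
}

#' One-row summary of an encoding result
#' @param x A `venc_encoding`.
#' @param ... Unused.
#' @return Tibble with voxel count, mean/max accuracy, penalty, fit mode.
#' @export
glance.venc_encoding <- function(x, ...) {
  tibble::tibble(
    n_voxels = nrow(x),
    mean_r = mean(x$mean_r),
    max_r = max(x$mean_r),
    lambda = attr(x, "lambda"),
    fit_mode = attr(x, "fit_mode"),
    layer_selection = attr(x, "layer_selection"),
    n_zero_variance = sum(x$n_zero_variance)
  )
}

#' Tidy a cross-validated single-voxel fit
#' @param x A `venc_cv` from [cross_validate_voxel()].
#' @param ... Unused.
#' @return Tibble: `session`, `r`, `zero_variance`.
#' @export
tidy.venc_cv <- function(x, ...) {
  tibble::tibble(session = seq_along(x$r_per_session), r = x$r_per_session,
                 zero_variance = x$zero_variance)
}

#' @export
glance.venc_cv <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, lambda = x$lambda,
                 n_active = sum(x$mean_coefficients != 0))
}

#' Tidy a repeated-measures ANOVA table
#' @param x A `venc_anova`.
#' @param ... Unused.
#' @return The effect table as a plain tibble.
#' @export
tidy.venc_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("effect", "df1", "df2", "epsilon",
                                 "statistic", "partial_eta_sq", "p")])
}

#' @export
glance.venc_anova <- function(x, ...) {
  tibble::tibble(n_subjects = attr(x, "n_subjects"), n_effects = nrow(x),
                 min_p = min(x$p))
}

#' @export
print.venc_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  df <- as.data.frame(x)
  df$df1 <- round(df$df1, 2); df$df2 <- round(df$df2, 2)
  df$epsilon <- round(df$epsilon, 3)
  df$statistic <- round(df$statistic, 2)
  df$partial_eta_sq <- round(df$partial_eta_sq, 3)
  df$p <- signif(df$p, 3)
  print(df[c("effect", "df1", "df2", "epsilon", "statistic", "partial_eta_sq", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Tidy a group-level map
#' @param x A `venc_group_map`.
#' @param ... Unused.
#' @return The voxel table as a plain tibble.
#' @export
tidy.venc_group_map <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.venc_group_map <- function(x, ...) {
  tibble::tibble(n_voxels = nrow(x), n_significant = sum(x$significant),
                 n_flagged = sum(x$flagged), alpha = attr(x, "alpha"),
                 n_tests = attr(x, "n_tests"))
}
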