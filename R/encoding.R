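#' Encoding-model configuration
#'
#' @param lambda_grid Ascending grid of L1 penalties; defaults to 25
#'   log-spaced values spanning `[0.005, 0.5]`.
#' @param plateau_band_fraction Band below the curve maximum (as a fraction
#'   of it) that still counts as the performance plateau (default 0.01).
#' @param fixed_lambda Penalty used for all voxels once fixed; default 0.07,
#'   the midpoint of the `[0.04, 0.1]` plateau.
#' @param n_folds Sessions / cross-validation folds (default 5).
#' @param tol Coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep.
#' @param max_iter Maximum full sweeps.
#' @param fit_mode `"per_session_average"`: fit each training session
#'   separately and average the coefficient vectors (default), or
#'   `"concatenated"`: stack the training sessions and fit once.
#' @param seed Integer seed for any randomized sub-steps.
#' @return A `venc_encoding_config` list.
#' @export
encoding_config <- function(lambda_grid = exp(seq(log(0.005), log(0.5), length.out = 25)),
                            plateau_band_fraction = 0.01, fixed_lambda = 0.07,
                            n_folds = 5L, tol = 1e-6, max_iter = 10000L,
                            fit_mode = c("per_session_average", "concatenated"),
                            seed = 1L) {
  if (is.unsorted(lambda_grid) || any(lambda_grid <= 0)) {
    stop_venc("`lambda_grid` must be positive and ascending")
  }
  if (fixed_lambda < min(lambda_grid) || fixed_lambda > max(lambda_grid)) {
    stop_venc("`fixed_lambda` must lie within the grid range")
  }
  structure(list(lambda_grid = lambda_grid,
                 plateau_band_fraction = plateau_band_fraction,
                 fixed_lambda = fixed_lambda, n_folds = as.integer(n_folds),
                 tol = tol, max_iter = as.integer(max_iter),
                 fit_mode = match.arg(fit_mode), seed = as.integer(seed)),
            class = "venc_encoding_config")
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' L1-regularized least squares by cyclic coordinate descent
#'
#' Minimizes `1/(2N) * ||y - X b||^2 + lambda * ||b||_1` with no intercept
#' (inputs are assumed standardized/centred). `y` may be a matrix, in which
#' case every column (voxel) is fit simultaneously against the shared design
#' — the cyclic updates are vectorized across responses.
#'
#' @param x `N x P` predictor matrix (observations in rows).
#' @param y Length-`N` response, or `N x V` response matrix.
#' @param lambda Non-negative L1 penalty on the `1/(2N)` loss scale.
#' @param tol Convergence tolerance: maximum absolute coefficient change in a
#'   full sweep.
#' @param max_iter Maximum sweeps; non-convergence raises a warning and sets
#'   the `"converged"` attribute to `FALSE`.
#' @param init Optional warm-start coefficient matrix/vector (the optimum is
#'   unique, so this changes the path, not the solution).
#' @return Coefficient vector (or `P x V` matrix), with attribute
#'   `"converged"`.
#' @export
lasso_fit <- function(x, y, lambda, tol = 1e-6, max_iter = 10000L, init = NULL) {
  x <- as.matrix(x)
  y_mat <- is.matrix(y)
  y <- as.matrix(y)
  if (nrow(y) != nrow(x)) stop_venc("`x` and `y` have different numbers of observations")
  if (lambda < 0) stop_venc("`lambda` must be non-negative")
  check_finite(x, "x"); check_finite(y, "y")
  n <- nrow(x); p <- ncol(x); v <- ncol(y)
  # covariance-form updates: the sweeps see only X'X/N and X'y/N, so the
  # per-coordinate cost is independent of N; the cyclic loop itself runs in
  # compiled code, with converged response columns retired from the sweep.
  # Columns are processed in cache-sized blocks (they are independent
  # problems, so blocking changes nothing but memory locality).
  xtx <- crossprod(x) / n
  xty <- crossprod(x, y) / n
  if (any(diag(xtx) <= 0)) {
    stop_venc("all-zero predictor column %d", which(diag(xtx) <= 0)[1])
  }
  init_m <- if (!is.null(init)) matrix(init, p, v)
  block <- max(64L, as.integer(65536 / p))
  starts <- seq(1L, v, by = block)
  b <- matrix(0, p, v)
  converged <- TRUE
  for (s0 in starts) {
    s1 <- min(s0 + block - 1L, v)
    binit <- if (is.null(init_m)) matrix(0, p, s1 - s0 + 1L)
    else init_m[, s0:s1, drop = FALSE]
    fit <- .lasso_cd_engine(xtx, xty[, s0:s1, drop = FALSE], binit,
                            lambda, tol, as.integer(max_iter))
    b[, s0:s1] <- fit$b
    converged <- converged && fit$converged
  }
  if (!converged) {
    rlang::warn(sprintf("lasso did not converge in %d sweeps", max_iter))
  }
  out <- if (y_mat) b else drop(b)
  attr(out, "converged") <- converged
  out
}

#' Pearson correlation between predicted and measured series
#'
#' If either series has zero variance (e.g. a fully shrunk model predicting a
#' constant), the correlation is defined as 0 and the `"zero_variance"`
#' attribute flags the fallback, so maps stay complete and shrunk-to-zero
#' fits are penalized rather than dropped.
#'
#' @param pred,actual Equal-length numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]` with attribute `"zero_variance"`.
#' @export
pearson_r <- function(pred, actual) {
  if (length(pred) != length(actual)) stop_venc("length mismatch between series")
  if (length(pred) < 3) stop_venc("need at least 3 samples for a correlation")
  if (var(pred) <= VAR_EPS || var(actual) <= VAR_EPS) {
    out <- 0
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  out <- cor(pred, actual)
  attr(out, "zero_variance") <- FALSE
  out
}

# Column-wise correlation of predictions (N x V) with responses (N x V);
# zero-variance columns on either side score 0 and are flagged.
cor_cols <- function(pred, actual) {
  pc <- sweep(pred, 2, colMeans(pred))
  ac <- sweep(actual, 2, colMeans(actual))
  vp <- colSums(pc^2); va <- colSums(ac^2)
  bad <- vp <= VAR_EPS * (nrow(pred) - 1) | va <= VAR_EPS * (nrow(pred) - 1)
  denom <- sqrt(vp * va)
  denom[bad] <- 1
  r <- colSums(pc * ac) / denom
  r[bad] <- 0
  attr(r, "zero_variance") <- bad
  r
}

#' Fix the regularization strength at the plateau midpoint
#'
#' The plateau is the longest contiguous run of grid points whose mean
#' cross-validated correlation stays within `band_fraction` of the curve
#' maximum; the returned penalty is the midpoint of that run's endpoints.
#'
#' @param grid Ascending penalty grid.
#' @param mean_r_curve Mean correlation at each grid point.
#' @param band_fraction Plateau band as a fraction of the maximum.
#' @return The fixed penalty (midpoint of the plateau interval), with the
#'   plateau endpoints in attribute `"plateau"`.
#' @export
select_lambda <- function(grid, mean_r_curve, band_fraction = 0.01) {
  if (length(grid) == 0) stop_venc("empty penalty grid")
  if (length(grid) != length(mean_r_curve)) stop_venc("curve and grid lengths differ")
  if (!all(is.finite(mean_r_curve))) stop_venc("non-finite values in the mean-r curve")
  ok <- mean_r_curve >= (1 - band_fraction) * max(mean_r_curve)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  lo <- grid[starts[best]]; hi <- grid[ends[best]]
  out <- (lo + hi) / 2
  attr(out, "plateau") <- c(lo, hi)
  out
}

check_design_list <- function(designs, n_folds) {
  stopifnot(all(vapply(designs, inherits, TRUE, "venc_design")))
  if (length(designs) != n_folds) {
    stop_venc("expected %d session designs, got %d", n_folds, length(designs))
  }
  ref <- paste(designs[[1]]$predictor_layer, designs[[1]]$unit_index)
  for (s in seq_along(designs)[-1]) {
    if (!identical(paste(designs[[s]]$predictor_layer, designs[[s]]$unit_index), ref)) {
      stop_venc("predictor identity differs between sessions 1 and %d", s)
    }
  }
  invisible(TRUE)
}

# Core CV engine shared by cross_validate_voxel() and encode_all_voxels().
# yl: list of N x V response matrices per session. Returns list with r
# (V x n_folds), mean coefficient matrix, flags.
cv_engine <- function(designs, yl, cfg, lambda = NULL, return_coefficients = FALSE) {
  nf <- cfg$n_folds
  lambda <- lambda %||% cfg$fixed_lambda
  xl <- lapply(designs, function(d) t(d$values))
  v <- ncol(yl[[1]])
  r <- matrix(NA_real_, v, nf)
  zero_var <- matrix(FALSE, v, nf)
  coefs <- if (return_coefficients) array(0, c(nrow(designs[[1]]$values), v, nf))
  fit_cache <- new.env(parent = emptyenv()) # each session is fit at most once
  session_fit <- function(s) {
    key <- as.character(s)
    got <- fit_cache[[key]]
    if (is.null(got)) {
      got <- lasso_fit(xl[[s]], yl[[s]], lambda,
                       tol = cfg$tol, max_iter = cfg$max_iter)
      fit_cache[[key]] <- got
    }
    got
  }
  for (test in seq_len(nf)) {
    train <- setdiff(seq_len(nf), test)
    if (cfg$fit_mode == "per_session_average") {
      bsum <- 0
      for (s in train) bsum <- bsum + session_fit(s)
      bbar <- bsum / length(train)
    } else {
      bbar <- lasso_fit(do.call(rbind, xl[train]), do.call(rbind, yl[train]),
                        lambda, tol = cfg$tol, max_iter = cfg$max_iter)
    }
    if (!is.matrix(bbar)) bbar <- matrix(bbar, ncol = v)
    pred <- xl[[test]] %*% bbar
    rr <- cor_cols(pred, yl[[test]])
    r[, test] <- rr
    zero_var[, test] <- attr(rr, "zero_variance")
    if (return_coefficients) coefs[, , test] <- bbar
  }
  list(r = r, coefficients = coefs, zero_variance = zero_var)
}

#' Cross-validate the encoding model for one voxel
#'
#' Session-wise cross-validation: each session serves once as the test set.
#' For each fold, the model is fit (by default) separately on each of the
#' remaining sessions; the per-session coefficient vectors are averaged, the
#' held-out response is predicted from the held-out design with those
#' averaged coefficients, and prediction accuracy is the Pearson correlation.
#'
#' @param designs List of `venc_design`, one per session, with identical
#'   predictor identity.
#' @param y List of per-session response vectors.
#' @param cfg A `venc_encoding_config`.
#' @param lambda Penalty; defaults to `cfg$fixed_lambda`.
#' @return A `venc_cv` list: `r_per_session`, `mean_r`, `coefficients`
#'   (`P x n_folds`, fold-averaged), `mean_coefficients`, and fallback flags.
#' @export
cross_validate_voxel <- function(designs, y, cfg = encoding_config(), lambda = NULL) {
  check_design_list(designs, cfg$n_folds)
  stopifnot(length(y) == cfg$n_folds)
  yl <- lapply(y, function(yy) matrix(yy, ncol = 1))
  fit <- cv_engine(designs, yl, cfg, lambda, return_coefficients = TRUE)
  coefs <- matrix(fit$coefficients[, 1, ], ncol = cfg$n_folds)
  structure(
    list(r_per_session = drop(fit$r), mean_r = mean(fit$r),
         coefficients = coefs, mean_coefficients = rowMeans(coefs),
         zero_variance = drop(fit$zero_variance),
         lambda = lambda %||% cfg$fixed_lambda),
    class = "venc_cv"
  )
}

#' Fit the encoding model for every voxel
#'
#' Runs the session-wise cross-validation of [cross_validate_voxel()] for a
#' whole voxel set at once; the coordinate-descent updates are shared across
#' voxels, so the per-voxel results are identical to looping but far faster.
#'
#' @param designs List of per-session `venc_design`.
#' @param voxels List of per-session `V x N` matrices, or `venc_voxels`
#'   objects (already residualized).
#' @param cfg A `venc_encoding_config`.
#' @param layer_selection Label recorded with the result.
#' @param lambda Penalty; defaults to `cfg$fixed_lambda`.
#' @return A `venc_encoding` tibble with one row per voxel: `voxel`,
#'   per-session correlations (`r_by_session` matrix column), `mean_r`, and
#'   the count of zero-variance prediction fallbacks.
#' @export
encode_all_voxels <- function(designs, voxels, cfg = encoding_config(),
                              layer_selection = designs[[1]]$layer_selection,
                              lambda = NULL) {
  check_design_list(designs, cfg$n_folds)
  yl <- lapply(voxels, function(v) {
    m <- if (inherits(v, "venc_voxels")) v$values else as.matrix(v)
    t(m)
  })
  nvx <- ncol(yl[[1]])
  if (!all(vapply(yl, ncol, 1L) == nvx)) stop_venc("voxel counts differ across sessions")
  for (s in seq_along(yl)) {
    if (nrow(yl[[s]]) != ncol(designs[[s]]$values)) {
      stop_venc("session %d: %d volumes in voxels vs %d in design",
                s, nrow(yl[[s]]), ncol(designs[[s]]$values))
    }
  }
  # per-fold fits require standardized responses; center/scale each series
  yl <- lapply(yl, function(y) {
    mu <- colMeans(y)
    yc <- sweep(y, 2, mu)
    sdv <- sqrt(colSums(yc^2) / (nrow(y) - 1))
    sdv[sdv <= sqrt(VAR_EPS)] <- 1
    sweep(yc, 2, sdv, `/`)
  })
  fit <- cv_engine(designs, yl, cfg, lambda)
  out <- tibble::tibble(
    voxel = seq_len(nvx),
    mean_r = rowMeans(fit$r),
    n_zero_variance = rowSums(fit$zero_variance)
  )
  out$r_by_session <- fit$r
  attr(out, "layer_selection") <- layer_selection
  attr(out, "lambda") <- lambda %||% cfg$fixed_lambda
  attr(out, "fit_mode") <- cfg$fit_mode
  class(out) <- c("venc_encoding", class(out))
  out
}

#' Trace the mean cross-validated correlation over a penalty grid
#'
#' Convenience wrapper running [encode_all_voxels()] at every grid penalty
#' and averaging `mean_r` over voxels; feed the result to [select_lambda()].
#'
#' @inheritParams encode_all_voxels
#' @param grid Penalty grid; defaults to `cfg$lambda_grid`.
#' @return Tibble with `lambda` and `mean_r`.
#' @export
lambda_curve <- function(designs, voxels, cfg = encoding_config(), grid = NULL) {
  grid <- grid %||% cfg$lambda_grid
  mean_r <- vapply(grid, function(l) {
    mean(encode_all_voxels(designs, voxels, cfg, lambda = l)$mean_r)
  }, numeric(1))
  out <- tibble::tibble(lambda = grid, mean_r = mean_r)
  class(out) <- c("venc_lambda_curve", class(out))
  out
}
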