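#' Acquisition parameters
#'
#' @param tr_seconds Repetition time in seconds (default 0.987).
#' @param stim_rate_hz Stimulus sampling rate in Hz (default 45).
#' @param highpass_cutoff_seconds High-pass cutoff period (default 128).
#' @param n_volumes Volumes per session; if `NULL`, derived from the stimulus
#'   duration as `floor(duration / tr_seconds)`.
#' @return A `venc_acquisition` list.
#' @export
acquisition_spec <- function(tr_seconds = 0.987, stim_rate_hz = 45,
                             highpass_cutoff_seconds = 128, n_volumes = NULL) {
  if (tr_seconds <= 0) stop_venc("`tr_seconds` must be positive")
  if (highpass_cutoff_seconds <= 2 * tr_seconds) {
    stop_venc("high-pass cutoff must exceed 2 * TR = %g s", 2 * tr_seconds)
  }
  structure(list(tr_seconds = tr_seconds, stim_rate_hz = stim_rate_hz,
                 highpass_cutoff_seconds = highpass_cutoff_seconds,
                 n_volumes = n_volumes),
            class = "venc_acquisition")
}

#' Hemodynamic response parameters (canonical double gamma)
#'
#' Defaults follow the canonical parameterization: response peak modelled by
#' a gamma density with shape `peak_delay` (scale 1 s, mode at
#' `peak_delay - peak_dispersion` s), an undershoot gamma with shape
#' `undershoot_delay`, mixed at ratio 1:`peak_undershoot_ratio`, over a 32 s
#' window.
#'
#' @param peak_delay,undershoot_delay Gamma shape parameters in seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma scale parameters.
#' @param peak_undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param duration Kernel length in seconds.
#' @return A `venc_hrf` list.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16, peak_dispersion = 1,
                     undershoot_dispersion = 1, peak_undershoot_ratio = 6,
                     duration = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, peak_undershoot_ratio, duration)
  if (any(vals <= 0)) stop_venc("all HRF parameters must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 duration = duration),
            class = "venc_hrf")
}

#' Sample the hemodynamic response kernel
#'
#' Difference of two gamma densities sampled at `rate_hz` over the kernel
#' duration. With the default parameters the mode lies at 5 s.
#'
#' @param hrf A `venc_hrf`.
#' @param rate_hz Sampling rate in Hz.
#' @return Numeric kernel, first sample at t = 0.
#' @export
hrf_kernel <- function(hrf = hrf_spec(), rate_hz = 45) {
  if (rate_hz <= 0) stop_venc("`rate_hz` must be positive")
  t <- seq(0, hrf$duration, by = 1 / rate_hz)
  dgamma(t, shape = hrf$peak_delay / hrf$peak_dispersion,
         scale = hrf$peak_dispersion) -
    dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_dispersion,
           scale = hrf$undershoot_dispersion) / hrf$peak_undershoot_ratio
}

# Causal row-wise convolution of a U x T matrix with a kernel, via FFT.
convolve_rows <- function(m, kernel) {
  tt <- ncol(m)
  n <- stats::nextn(tt + length(kernel) - 1L, 2)
  kf <- stats::fft(c(kernel, numeric(n - length(kernel))))
  xf <- stats::mvfft(rbind(t(m), matrix(0, n - tt, nrow(m))))
  full <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / n
  t(full[seq_len(tt), , drop = FALSE])
}

#' Number of volumes covering a stimulus series
#'
#' Floor convention: `floor(duration_seconds / tr_seconds)` volumes, the
#' k-th (1-based) acquired at `(k - 1) * TR`.
#'
#' @param n_samples Stimulus samples in the series.
#' @param rate_hz Stimulus rate in Hz.
#' @param tr_seconds Repetition time.
#' @return Integer volume count.
#' @export
n_volumes_for <- function(n_samples, rate_hz = 45, tr_seconds = 0.987) {
  as.integer(floor((n_samples / rate_hz) / tr_seconds))
}

#' Downsample a stimulus-rate matrix to the acquisition grid
#'
#' One sample per volume at times `(k - 1) * TR`, by linear interpolation
#' between neighbouring stimulus samples (sample `i` sits at `(i - 1) / rate`).
#'
#' @param m `U x T` matrix sampled at `rate_hz`.
#' @param acq A `venc_acquisition`; `n_volumes` defaults to the floor
#'   convention of [n_volumes_for()].
#' @param rate_hz Stimulus rate of `m`.
#' @return `U x n_volumes` matrix.
#' @export
resample_to_tr <- function(m, acq = acquisition_spec(), rate_hz = 45) {
  m <- as.matrix(m)
  tt <- ncol(m)
  nv <- acq$n_volumes %||% n_volumes_for(tt, rate_hz, acq$tr_seconds)
  times <- (seq_len(nv) - 1) * acq$tr_seconds
  pos <- times * rate_hz + 1 # fractional index into the stimulus grid
  if (max(pos) > tt + 1e-9) {
    stop_venc("acquisition time %.3f s lies beyond the stimulus series end (%.3f s)",
              max(times), (tt - 1) / rate_hz)
  }
  lo <- pmin(floor(pos), tt)
  w <- pos - lo
  hi <- pmin(lo + 1, tt)
  m[, lo, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, hi, drop = FALSE] * rep(w, each = nrow(m))
}

#' Discrete-cosine high-pass basis
#'
#' All DCT components with period longer than the cutoff, plus the constant.
#' Component k of an N-volume run has period `2 * N * TR / k` seconds, so
#' `K = floor(2 * N * TR / cutoff)` components enter the basis.
#'
#' @param n_volumes Number of volumes.
#' @param tr_seconds Repetition time.
#' @param cutoff_seconds Cutoff period (default 128).
#' @return `N x (K + 1)` matrix; first column constant.
#' @export
dct_basis <- function(n_volumes, tr_seconds = 0.987, cutoff_seconds = 128) {
  if (cutoff_seconds <= 2 * tr_seconds) {
    stop_venc("cutoff shorter than 2 * TR leaves no signal")
  }
  k_max <- floor(2 * n_volumes * tr_seconds / cutoff_seconds)
  n <- seq_len(n_volumes)
  b <- matrix(1, n_volumes, k_max + 1L)
  for (k in seq_len(k_max)) b[, k + 1L] <- cos(pi * k * (2 * n - 1) / (2 * n_volumes))
  b
}

#' High-pass filter by DCT-basis regression
#'
#' Each row is replaced by its residual from an ordinary regression on the
#' discrete-cosine basis of [dct_basis()]; output rows are orthogonal to
#' every basis component (drift and mean removed).
#'
#' @param m `U x N` matrix on the acquisition grid.
#' @param acq A `venc_acquisition` supplying TR and cutoff.
#' @return Filtered matrix of the same shape.
#' @export
highpass_dct <- function(m, acq = acquisition_spec()) {
  m <- as.matrix(m)
  nn <- ncol(m)
  if (nn < 4) stop_venc("need at least 4 volumes to high-pass filter")
  b <- dct_basis(nn, acq$tr_seconds, acq$highpass_cutoff_seconds)
  q <- qr.Q(qr(b))
  m - (m %*% q) %*% t(q)
}

#' Drop units that were never active
#'
#' Removes units whose activation series is identically zero over the whole
#' session set; only such units are excluded, so predictor identity is shared
#' by all sessions and folds.
#'
#' @param f A `venc_features`, or a list of them (one per session).
#' @param also_constant Additionally drop units whose series is constant
#'   (zero variance) within any session; such units cannot be z-scored.
#' @return Same shape as `f`, with surviving units only; the number of
#'   dropped units is reported via attribute `"n_dropped"`.
#' @export
drop_inactive_units <- function(f, also_constant = FALSE) {
  single <- inherits(f, "venc_features")
  fl <- if (single) list(f) else f
  stopifnot(all(vapply(fl, inherits, TRUE, "venc_features")))
  active <- Reduce(`|`, lapply(fl, function(s) rowSums(s$values != 0) > 0))
  keep <- active
  if (also_constant) {
    nonconst <- Reduce(`&`, lapply(fl, function(s) {
      v <- s$values - rowMeans(s$values)
      rowSums(v^2) / (ncol(s$values) - 1) > VAR_EPS
    }))
    keep <- keep & nonconst
  }
  if (!any(keep)) stop_venc("all units inactive: degenerate feature set")
  out <- lapply(fl, function(s) {
    r <- feature_series(s$values[keep, , drop = FALSE], s$unit_layer[keep],
                        s$unit_index[keep], s$rate_hz)
    attr(r, "n_dropped") <- sum(!keep)
    r
  })
  if (single) out[[1]] else out
}

#' Z-score along the temporal and feature dimensions
#'
#' Standardizes each unit's series over time (sample sd, n - 1 divisor), then
#' standardizes across units at each time point. Temporal-first is the
#' default ordering; see `order`. A single-unit matrix skips the feature
#' pass, which is undefined for one unit.
#'
#' @param m `U x T` matrix (units in rows).
#' @param order `"temporal_first"` (default) or `"feature_first"`.
#' @return Matrix of the same shape.
#' @export
zscore_dual <- function(m, order = c("temporal_first", "feature_first")) {
  order <- match.arg(order)
  m <- as.matrix(m)
  zt <- function(x) zscore_rows(x, what = "unit")
  zf <- function(x) {
    if (nrow(x) == 1L) return(x)
    t(zscore_rows(t(x), what = "time point"))
  }
  if (order == "temporal_first") zf(zt(m)) else zt(zf(m))
}

#' Assemble a GLM-ready design matrix from feature series
#'
#' Applies, in order: layer selection, inactive/constant-unit filtering
#' (across the whole session set), dual z-scoring, causal convolution with
#' the hemodynamic kernel at the stimulus rate, linear resampling to the
#' acquisition grid, DCT high-pass filtering, and a final temporal z-score.
#'
#' @param f A `venc_features` or list of them (one per session).
#' @param layer_selection `"all"` or a subset of the layer labels present.
#' @param acq A `venc_acquisition`.
#' @param hrf A `venc_hrf`.
#' @param zscore_order Passed to [zscore_dual()].
#' @return A `venc_design` (or list, matching `f`): `values` is the `P x N`
#'   standardized predictor matrix with `predictor_layer`/`unit_index`
#'   labels.
#' @export
assemble_design <- function(f, layer_selection = "all", acq = acquisition_spec(),
                            hrf = hrf_spec(), zscore_order = "temporal_first") {
  single <- inherits(f, "venc_features")
  fl <- if (single) list(f) else f
  if (length(layer_selection) == 0) stop_venc("empty layer selection")
  if (!identical(layer_selection, "all")) {
    unknown <- setdiff(layer_selection, unique(fl[[1]]$unit_layer))
    if (length(unknown)) stop_venc("unknown layer(s): %s", paste(unknown, collapse = ", "))
    fl <- lapply(fl, function(s) {
      sel <- s$unit_layer %in% layer_selection
      feature_series(s$values[sel, , drop = FALSE], s$unit_layer[sel],
                     s$unit_index[sel], s$rate_hz)
    })
  }
  fl <- drop_inactive_units(fl, also_constant = TRUE)
  kern <- hrf_kernel(hrf, fl[[1]]$rate_hz)
  out <- lapply(fl, function(s) {
    z <- zscore_dual(s$values, order = zscore_order)
    conv <- convolve_rows(z, kern)
    ds <- resample_to_tr(conv, acq, s$rate_hz)
    hp <- highpass_dct(ds, acq)
    final <- zscore_rows(hp, what = "predictor")
    structure(
      list(values = final, predictor_layer = s$unit_layer,
           unit_index = s$unit_index, acq = acq, standardized = TRUE,
           layer_selection = paste(layer_selection, collapse = "+")),
      class = "venc_design"
    )
  })
  if (single) out[[1]] else out
}

#' @export
print.venc_design <- function(x, ...) {
  cat(sprintf("<venc_design> %d predictors x %d volumes (%s)\n",
              nrow(x$values), ncol(x$values), x$layer_selection))
  invisible(x)
}

#' Residualize voxel series against motion and drift regressors
#'
#' Per voxel, the ordinary-least-squares residual from a regression on the
#' six motion parameters, the DCT high-pass basis, and a constant. This
#' implements nuisance correction as part of the GLM specification: residuals
#' are exactly orthogonal to every regressor.
#'
#' @param v `V x N` voxel matrix, or a `venc_voxels`.
#' @param motion `6 x N` (or `N x 6`) motion-parameter matrix.
#' @param acq A `venc_acquisition`.
#' @return Residualized object of the same class/shape.
#' @export
motion_residualize <- function(v, motion, acq = acquisition_spec()) {
  vox <- inherits(v, "venc_voxels")
  m <- if (vox) v$values else as.matrix(v)
  motion <- as.matrix(motion)
  if (ncol(motion) == ncol(m) && nrow(motion) != ncol(m)) motion <- t(motion)
  if (nrow(motion) != ncol(m)) stop_venc("motion parameters not aligned with voxel series")
  x <- cbind(dct_basis(ncol(m), acq$tr_seconds, acq$highpass_cutoff_seconds), motion)
  dec <- qr(x)
  if (dec$rank < ncol(x)) stop_venc("rank-deficient nuisance regressor matrix")
  q <- qr.Q(dec)
  res <- m - (m %*% q) %*% t(q)
  if (vox) { v$values <- res; v } else res
}

#' Raw-pixel control design
#'
#' A control feature space in which every pixel of the preprocessed state
#' (optionally block-averaged by `block_factor`) is one predictor, run
#' through the same temporal pipeline as network features. Tests whether a
#' linear transformation of the raw screens explains the same activity.
#'
#' @param seq A `venc_frames` or list of them (sessions).
#' @param acq,hrf As in [assemble_design()].
#' @param block_factor Side length of the pixel blocks averaged into one
#'   predictor (must divide the state size); 1 keeps single pixels.
#' @return A `venc_design` or list thereof; predictor layer label `"pixel"`.
#' @export
pixel_control_design <- function(seq, acq = acquisition_spec(), hrf = hrf_spec(),
                                 block_factor = 1L) {
  single <- inherits(seq, "venc_frames")
  sl <- if (single) list(seq) else seq
  d <- dim(sl[[1]]$frames)
  if (d[1] %% block_factor != 0) stop_venc("block_factor must divide the state size")
  nb <- d[1] %/% block_factor
  w <- resize_weights(d[1], nb)
  feats <- lapply(sl, function(s) {
    tt <- dim(s$frames)[3]
    px <- vapply(seq_len(tt), function(t) as.vector(w %*% s$frames[, , t] %*% t(w)),
                 numeric(nb * nb))
    feature_series(px, rep("pixel", nb * nb), rate_hz = s$rate_hz)
  })
  out <- assemble_design(feats, "all", acq, hrf)
  if (single) out[[1]] else out
}

#' Motor-response control design
#'
#' One indicator predictor per action code observed in the logs (button or
#' button combination), convolved, resampled, filtered, and standardized as
#' in [assemble_design()]. Tests how much activity the overt motor output
#' alone explains.
#'
#' @param actions Length-`T` action-code vector, or a list of them
#'   (sessions), or `venc_frames` object(s).
#' @param acq,hrf As in [assemble_design()].
#' @param valid_codes Allowed action codes; an action outside this set is an
#'   error. `0` is treated as "no press" and gets no predictor.
#' @param rate_hz Sampling rate of the action log.
#' @return A `venc_design` or list thereof; layer label `"motor"`.
#' @export
motor_control_design <- function(actions, acq = acquisition_spec(), hrf = hrf_spec(),
                                 valid_codes = 0:3, rate_hz = 45) {
  as_codes <- function(a) if (inherits(a, "venc_frames")) a$actions else as.integer(a)
  single <- !is.list(actions) || inherits(actions, "venc_frames")
  al <- if (single) list(as_codes(actions)) else lapply(actions, as_codes)
  codes <- sort(unique(unlist(al)))
  if (length(setdiff(codes, valid_codes))) {
    stop_venc("unknown action code(s): %s",
              paste(setdiff(codes, valid_codes), collapse = ", "))
  }
  press <- setdiff(codes, 0L)
  if (length(press) == 0L) stop_venc("all units inactive: no presses in the action log")
  feats <- lapply(al, function(a) {
    ind <- vapply(press, function(cd) as.numeric(a == cd), numeric(length(a)))
    feature_series(t(ind), rep("motor", length(press)), rate_hz = rate_hz)
  })
  out <- assemble_design(feats, "all", acq, hrf)
  if (single) out[[1]] else out
}
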