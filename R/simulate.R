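#' Configuration of the toy visuomotor game
#'
#' A deterministic, seeded stand-in for real arcade gameplay: a ball bounces
#' inside an 84 x 84 screen with a static brick band, and a scripted paddle
#' policy tracks it imperfectly at the bottom. An episode ends (terminal
#' flag) when the paddle misses, or after `max_episode_seconds` of play.
#' Defaults reproduce the study conditions: five sessions of 7 minutes at
#' 45 Hz, i.e. 18,900 frames per session.
#'
#' @param grid_size Screen side length in pixels (default 84).
#' @param ball_speed Ball speed in pixels/frame.
#' @param paddle_speed Maximum paddle speed in pixels/frame.
#' @param paddle_width Paddle width in pixels.
#' @param policy_noise_sd Sd of the tracking error of the scripted policy.
#' @param freeze_prob Per-frame probability that the paddle does not move.
#' @param max_episode_seconds Forced episode end ("game over" timer).
#' @param session_minutes Session duration in minutes (default 7).
#' @param rate_hz Frame rate (default 45).
#' @param n_sessions Number of sessions (default 5).
#' @param session_frames Frames per session; defaults to
#'   `round(session_minutes * 60 * rate_hz)`.
#' @param seed Master seed.
#' @return A `venc_game_config` list.
#' @export
toy_game_config <- function(grid_size = 84, ball_speed = 1.2, paddle_speed = 1.1,
                            paddle_width = 12, policy_noise_sd = 3,
                            freeze_prob = 0.08, max_episode_seconds = 30,
                            session_minutes = 7, rate_hz = 45, n_sessions = 5,
                            session_frames = NULL, seed = 1L) {
  if (grid_size < 16) stop_venc("degenerate grid: need at least 16 pixels")
  session_frames <- session_frames %||% round(session_minutes * 60 * rate_hz)
  structure(list(grid_size = grid_size, ball_speed = ball_speed,
                 paddle_speed = paddle_speed, paddle_width = paddle_width,
                 policy_noise_sd = policy_noise_sd, freeze_prob = freeze_prob,
                 max_episode_seconds = max_episode_seconds,
                 session_minutes = session_minutes, rate_hz = rate_hz,
                 n_sessions = as.integer(n_sessions),
                 session_frames = as.integer(session_frames),
                 seed = as.integer(seed)),
            class = "venc_game_config")
}

#' Generate one session of toy gameplay
#'
#' Deterministic given `(cfg$seed, session)`. Actions follow the scripted
#' policy (0 = no-op, 1 = fire at episode start, 2 = left, 3 = right);
#' rewards mark paddle hits; terminal flags mark episode ends.
#'
#' @param cfg A `venc_game_config`.
#' @param session Session index (its own random stream).
#' @return A `venc_frames` with raw (un-preprocessed) frames.
#' @export
generate_toy_game <- function(cfg = toy_game_config(), session = 1L) {
  g <- cfg$grid_size
  tt <- cfg$session_frames
  max_ep <- round(cfg$max_episode_seconds * cfg$rate_hz)
  with_seed(child_seed(cfg$seed, paste0("game-", session)), {
    bx <- by <- vx <- vy <- px <- numeric(tt)
    actions <- integer(tt)
    rewards <- numeric(tt)
    terminal <- logical(tt)
    half <- cfg$paddle_width / 2
    reset <- function() {
      c(bx = g / 2 + runif(1, -10, 10), by = g / 4,
        vx = sample(c(-1, 1), 1) * cfg$ball_speed * runif(1, 0.6, 1),
        vy = cfg$ball_speed)
    }
    st <- reset(); p <- g / 2
    ep_frame <- 0L
    for (t in seq_len(tt)) {
      ep_frame <- ep_frame + 1L
      new_ep <- ep_frame == 1L
      # scripted policy: track the ball with noise and occasional freezes
      target <- st["bx"] + rnorm(1, sd = cfg$policy_noise_sd)
      move <- max(-cfg$paddle_speed, min(cfg$paddle_speed, target - p))
      if (runif(1) < cfg$freeze_prob) move <- 0
      p <- max(half + 1, min(g - half, p + move))
      actions[t] <- if (new_ep) 1L else if (move < -0.05) 2L else if (move > 0.05) 3L else 0L
      # ball dynamics with wall bounces
      st["bx"] <- st["bx"] + st["vx"]
      st["by"] <- st["by"] + st["vy"]
      if (st["bx"] < 3) { st["bx"] <- 3; st["vx"] <- abs(st["vx"]) }
      if (st["bx"] > g - 2) { st["bx"] <- g - 2; st["vx"] <- -abs(st["vx"]) }
      if (st["by"] < 8) { st["by"] <- 8; st["vy"] <- abs(st["vy"]) }
      miss <- FALSE
      if (st["by"] >= g - 3) {
        if (abs(st["bx"] - p) <= half + 2) {
          st["by"] <- g - 3; st["vy"] <- -abs(st["vy"]); rewards[t] <- 1
        } else miss <- TRUE
      }
      bx[t] <- st["bx"]; by[t] <- st["by"]; px[t] <- p
      if (miss || ep_frame >= max_ep) {
        terminal[t] <- TRUE
        st <- reset(); p <- g / 2; ep_frame <- 0L
      }
    }
    # draw: static brick band plus moving ball and paddle
    template <- matrix(0L, g, g)
    template[, 4:6] <- 80L
    frames <- array(template, c(g, g, tt))
    bi <- pmax(2L, pmin(g - 1L, round(bx)))
    bj <- pmax(2L, pmin(g - 1L, round(by)))
    pi_ <- round(px)
    for (t in seq_len(tt)) {
      frames[(bi[t] - 1L):(bi[t] + 1L), (bj[t] - 1L):(bj[t] + 1L), t] <- 255L
      lo <- max(1L, pi_[t] - as.integer(half)); hi <- min(g, pi_[t] + as.integer(half))
      frames[lo:hi, (g - 2L):(g - 1L), t] <- 160L
    }
    frame_sequence(frames, terminal, actions, rewards, cfg$rate_hz)
  })
}

#' Simulate head-motion parameter time courses
#'
#' Six slowly varying stationary series (three translations, three
#' rotations), modelled as standardized AR(1) processes with coefficient
#' `phi`, scaled by `amplitude`.
#'
#' @param n_volumes Number of volumes.
#' @param amplitude Amplitude multiplier.
#' @param phi AR(1) coefficient of the motion series.
#' @param seed Integer seed.
#' @return `6 x n_volumes` matrix.
#' @export
simulate_motion <- function(n_volumes, amplitude = 1, phi = 0.3, seed = 1L) {
  with_seed(child_seed(seed, "motion"), {
    m <- t(vapply(1:6, function(i) {
      as.numeric(scale(ar1_noise(n_volumes, 1, phi)))
    }, numeric(n_volumes)))
    m * amplitude
  })
}

ar1_noise <- function(n, sd_marginal, phi) {
  if (sd_marginal == 0) return(numeric(n))
  if (phi == 0) return(rnorm(n, sd = sd_marginal))
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
}

#' Simulate BOLD voxel series with known linear structure
#'
#' Each voxel is a sparse linear mixture of predictors drawn from a single
#' designated layer's assembled design, plus a motion confound and AR(1)
#' Gaussian noise — the generative inverse of the linear encoding model. The
#' noise variance is set from the realized signal variance so that
#' `ceiling_r = sqrt(snr / (1 + snr))` is the attainable prediction accuracy.
#'
#' @param designs_by_layer Named list (by layer) of per-session design lists,
#'   e.g. from [assemble_design()] with layer-wise selections.
#' @param voxel_layer Length-`V` layer label per voxel (the generating layer).
#' @param n_active Active predictors per voxel.
#' @param snr Signal-to-noise variance ratio (> 0; `Inf` for noise-free).
#' @param phi AR(1) coefficient of the noise (marginal variance normalized).
#' @param motion_sd Sd of the per-voxel motion-confound loadings (0 disables).
#' @param seed Integer seed.
#' @return List with `voxels` (per-session `V x N` matrices), `motion`
#'   (per-session `6 x N`), and `truth`, a tibble recording each voxel's
#'   layer, active set, weights, noise sd, `phi`, and `ceiling_r`.
#' @export
simulate_bold <- function(designs_by_layer, voxel_layer, n_active = 3, snr = 1,
                          phi = 0.3, motion_sd = 0.3, seed = 1L) {
  if (snr <= 0) stop_venc("`snr` must be positive")
  layers <- unique(voxel_layer)
  if (length(setdiff(layers, names(designs_by_layer)))) {
    stop_venc("no design supplied for layer(s): %s",
              paste(setdiff(layers, names(designs_by_layer)), collapse = ", "))
  }
  n_sessions <- length(designs_by_layer[[1]])
  nv <- length(voxel_layer)
  nn <- ncol(designs_by_layer[[1]][[1]]$values)
  with_seed(child_seed(seed, "bold"), {
    active <- vector("list", nv)
    weights <- vector("list", nv)
    signal <- lapply(seq_len(n_sessions), function(s) matrix(0, nv, nn))
    for (l in layers) {
      idx <- which(voxel_layer == l)
      p_l <- nrow(designs_by_layer[[l]][[1]]$values)
      if (p_l < n_active) stop_venc("layer %s has fewer than %d predictors", l, n_active)
      w_mat <- matrix(0, length(idx), p_l)
      for (k in seq_along(idx)) {
        a <- sort(sample.int(p_l, n_active))
        w <- rnorm(n_active) / sqrt(n_active)
        active[[idx[k]]] <- a
        weights[[idx[k]]] <- w
        w_mat[k, a] <- w
      }
      for (s in seq_len(n_sessions)) {
        signal[[s]][idx, ] <- w_mat %*% designs_by_layer[[l]][[s]]$values
      }
    }
    allsig <- do.call(cbind, signal)
    var_sig <- apply(allsig, 1, var)
    noise_sd <- if (is.finite(snr)) sqrt(var_sig / snr) else rep(0, nv)
    ceiling_r <- sqrt(var_sig / (var_sig + noise_sd^2))
    motion <- lapply(seq_len(n_sessions), function(s) {
      simulate_motion(nn, seed = child_seed(seed, paste0("motion-", s)))
    })
    gamma <- matrix(rnorm(nv * 6, sd = motion_sd), nv, 6)
    voxels <- lapply(seq_len(n_sessions), function(s) {
      noise <- t(vapply(seq_len(nv), function(v) ar1_noise(nn, noise_sd[v], phi),
                        numeric(nn)))
      signal[[s]] + gamma %*% motion[[s]] + noise
    })
    truth <- tibble::tibble(
      voxel = seq_len(nv), layer = voxel_layer,
      active = active, weights = weights,
      noise_sd = noise_sd, phi = phi, ceiling_r = ceiling_r
    )
    list(voxels = voxels, motion = motion, truth = truth)
  })
}

#' Build disjoint toy regions of interest
#'
#' Rectangular, mutually disjoint ROIs stacked along the third axis of a
#' reference volume, each labelled with the network layer its voxels are
#' sourced from in [simulate_bold()] — a toy cortical hierarchy.
#'
#' @param vol_dim Volume dimensions (length 3).
#' @param n_rois Number of ROIs.
#' @param voxels_per_roi Voxels per ROI.
#' @param roi_names Optional ROI labels (default `roi1..roiN`).
#' @param layers Layer assigned to each ROI (recycled from [WINNER_LAYERS]).
#' @return A `venc_rois` list: `masks` (logical arrays), `table` (tibble with
#'   `voxel`, `roi`, `layer`, grid coordinates), `vol_dim`.
#' @export
make_toy_rois <- function(vol_dim = c(20, 20, 20), n_rois = 5,
                          voxels_per_roi = 200, roi_names = NULL,
                          layers = WINNER_LAYERS) {
  slab <- vol_dim[3] %/% n_rois
  if (slab < 1 || prod(vol_dim[1:2]) * slab < voxels_per_roi) {
    stop_venc("volume %s cannot hold %d disjoint ROIs of %d voxels",
              paste(vol_dim, collapse = "x"), n_rois, voxels_per_roi)
  }
  roi_names <- roi_names %||% paste0("roi", seq_len(n_rois))
  layers <- rep_len(layers, n_rois)
  masks <- list()
  rows <- list()
  vid <- 0L
  for (r in seq_len(n_rois)) {
    m <- array(FALSE, vol_dim)
    z0 <- (r - 1L) * slab
    within <- seq_len(voxels_per_roi) - 1L
    x <- within %% vol_dim[1] + 1L
    y <- (within %/% vol_dim[1]) %% vol_dim[2] + 1L
    z <- z0 + within %/% prod(vol_dim[1:2]) + 1L
    m[cbind(x, y, z)] <- TRUE
    masks[[roi_names[r]]] <- m
    rows[[r]] <- tibble::tibble(voxel = vid + seq_len(voxels_per_roi),
                                roi = roi_names[r], layer = layers[r],
                                x = x, y = y, z = z)
    vid <- vid + voxels_per_roi
  }
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1)) stop_venc("ROIs overlap")
  structure(list(masks = masks, table = dplyr::bind_rows(rows), vol_dim = vol_dim),
            class = "venc_rois")
}

#' Simulate a full synthetic cohort
#'
#' End-to-end generator: toy gameplay (5 sessions), fixture network weights,
#' forward passes with a deterministic per-layer unit subsample, layer-wise
#' and all-layer design matrices, toy ROIs, and per-subject BOLD with motion
#' confounds and AR(1) noise. Every stage is a pure function of `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois,voxels_per_roi ROI geometry (each ROI sources one layer).
#' @param n_volumes Volumes per session.
#' @param units_per_layer Units retained per layer for the design stage.
#' @param snr,n_active,phi,motion_sd Passed to [simulate_bold()].
#' @param variant Network variant (default recurrent dueling: all 5 hidden
#'   layers present).
#' @param acq,hrf Acquisition and HRF parameters.
#' @param max_episode_seconds Forced episode length of the toy game.
#' @param seed Master seed.
#' @return A `venc_cohort` list: `designs` (named by selection, each a list
#'   of sessions), `subjects` (per-subject [simulate_bold()] outputs),
#'   `rois`, `truth`, and the generating objects/parameters.
#' @export
simulate_cohort <- function(n_subjects = 10, n_rois = 5, voxels_per_roi = 200,
                            n_volumes = 200, units_per_layer = 20, snr = 1,
                            n_active = 3, phi = 0.3, motion_sd = 0.3,
                            variant = "recurrent_dueling",
                            acq = NULL, hrf = hrf_spec(),
                            max_episode_seconds = 20, seed = 1L) {
  acq <- acq %||% acquisition_spec(n_volumes = n_volumes)
  spec <- network_spec(variant)
  frames_needed <- as.integer(ceiling(n_volumes * acq$tr_seconds * 45))
  game_cfg <- toy_game_config(session_frames = frames_needed,
                              max_episode_seconds = max_episode_seconds,
                              seed = child_seed(seed, "game"))
  weights <- make_fixture_weights(spec, seed = child_seed(seed, "weights"))
  hidden <- feature_layers(spec, include_output = FALSE)
  keep <- stats::setNames(as.list(rep(units_per_layer, length(hidden))), hidden)
  feats <- lapply(seq_len(game_cfg$n_sessions), function(s) {
    seq_s <- preprocess_frames(generate_toy_game(game_cfg, s))
    f <- forward_features(spec, weights, seq_s, keep_units = keep,
                          seed = child_seed(seed, "units"))
    sel <- f$unit_layer != "output"
    feature_series(f$values[sel, , drop = FALSE], f$unit_layer[sel],
                   f$unit_index[sel], f$rate_hz)
  })
  selections <- c(list(all = "all"), stats::setNames(as.list(hidden), hidden))
  designs <- lapply(selections, function(sel) assemble_design(feats, sel, acq, hrf))
  rois <- make_toy_rois(n_rois = n_rois, voxels_per_roi = voxels_per_roi,
                        layers = hidden)
  voxel_layer <- rois$table$layer
  subjects <- lapply(seq_len(n_subjects), function(sj) {
    simulate_bold(designs[hidden], voxel_layer, n_active = n_active, snr = snr,
                  phi = phi, motion_sd = motion_sd,
                  seed = child_seed(seed, paste0("subject-", sj)))
  })
  structure(
    list(designs = designs, subjects = subjects, rois = rois,
         truth = subjects[[1]]$truth[c("voxel", "layer")],
         features = feats, game_cfg = game_cfg, spec = spec, acq = acq,
         hrf = hrf, snr = snr, seed = seed),
    class = "venc_cohort"
  )
}

#' Fit and analyse a synthetic cohort end to end
#'
#' Runs the full analysis path on a [simulate_cohort()] output: motion
#' residualization, all-layer and layer-wise encoding for every subject,
#' group-level Fisher-Z one-sample inference with family-wise-error control
#' (the eligibility gate), winner-layer assignment, ROI layer compositions,
#' per-subject early/late log-ratios, and pairwise ROI comparisons.
#'
#' @param cohort A `venc_cohort`.
#' @param cfg A `venc_encoding_config`.
#' @param alpha Corrected significance level for the eligibility gate.
#' @return A list with per-subject encodings, the group map, assignments,
#'   per-subject compositions and log-ratios, ROI-pair tests, and the
#'   assignment accuracy against the generating layers.
#' @export
fit_cohort <- function(cohort, cfg = encoding_config(), alpha = 0.05) {
  stopifnot(inherits(cohort, "venc_cohort"))
  hidden <- feature_layers(cohort$spec, include_output = FALSE)
  n_sub <- length(cohort$subjects)
  nvx <- nrow(cohort$truth)
  # the designs are shared, so all subjects' voxels are fit in one
  # multi-response pass per selection and split afterwards
  vox_all <- lapply(seq_along(cohort$subjects[[1]]$voxels), function(s) {
    do.call(rbind, lapply(cohort$subjects, function(sub) {
      motion_residualize(sub$voxels[[s]], sub$motion[[s]], cohort$acq)
    }))
  })
  enc_all <- encode_all_voxels(cohort$designs$all, vox_all, cfg)
  layerwise_all <- sapply(hidden, function(l) {
    encode_all_voxels(cohort$designs[[l]], vox_all, cfg)$mean_r
  })
  res <- lapply(seq_len(n_sub), function(sj) {
    rows <- (sj - 1L) * nvx + seq_len(nvx)
    sub_enc <- enc_all[rows, ]
    sub_enc$voxel <- seq_len(nvx)
    attr(sub_enc, "layer_selection") <- attr(enc_all, "layer_selection")
    list(all = sub_enc, layerwise = layerwise_all[rows, , drop = FALSE])
  })
  z_maps <- do.call(rbind, lapply(res, function(r) fisher_z(r$all$mean_r)))
  group <- one_sample_fwe(z_maps, alpha = alpha)
  truth_layer <- cohort$truth$layer
  assignments <- lapply(res, function(r) {
    assign_winner_layer(r$layerwise, eligibility = group$significant,
                        layers = hidden)
  })
  acc <- vapply(assignments, function(a) {
    ok <- a$eligible
    mean(as.character(a$winner[ok]) == truth_layer[ok])
  }, numeric(1))
  roi_map <- cohort$rois$table
  compositions <- lapply(assignments, roi_layer_proportions, roi = roi_map,
                         layers = hidden)
  logratios <- dplyr::bind_rows(lapply(seq_along(compositions), function(sj) {
    lr <- early_late_logratio(compositions[[sj]])
    lr$subject <- sj
    lr
  }))
  roi_tests <- if (length(unique(logratios$roi)) >= 2) {
    compare_roi_ratios(logratios)
  } # with fewer than two ROIs surviving the gate there is nothing to compare
  list(encodings = res, group = group, assignments = assignments,
       accuracy = acc, compositions = compositions, logratios = logratios,
       roi_tests = roi_tests)
}
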