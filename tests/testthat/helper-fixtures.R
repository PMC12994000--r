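# Shared fixtures, memoised so expensive objects are built once per run.

.venc_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.venc_cache[[key]])) .venc_cache[[key]] <- build()
  .venc_cache[[key]]
}

# A short preprocessed toy session plus recurrent-variant features.
tiny_session <- function() {
  cache_get("tiny_session", function() {
    cfg <- toy_game_config(session_frames = 240, max_episode_seconds = 2, seed = 42)
    seq1 <- preprocess_frames(generate_toy_game(cfg, 1))
    spec <- network_spec("recurrent_dueling")
    w <- make_fixture_weights(spec, seed = 7)
    list(cfg = cfg, seq = seq1, spec = spec, weights = w,
         features = forward_features(spec, w, seq1))
  })
}

# Five-session feature set and assembled designs at a small scale: 60 volumes
# per session, 8 retained units per layer.
small_designs <- function() {
  cache_get("small_designs", function() {
    co <- simulate_cohort(n_subjects = 1, voxels_per_roi = 5, n_volumes = 60,
                          units_per_layer = 8, snr = 1, seed = 101)
    co
  })
}

# The full recovery cohort of the acceptance suite: 10 subjects, 5 ROIs x
# 200 voxels, SNR 1, 200-volume sessions, 20 units per layer.
recovery_cohort <- function() {
  cache_get("recovery_cohort", function() {
    simulate_cohort(n_subjects = 10, n_rois = 5, voxels_per_roi = 200,
                    n_volumes = 200, units_per_layer = 20, snr = 1, seed = 2024)
  })
}

recovery_fit <- function() {
  cache_get("recovery_fit", function() fit_cohort(recovery_cohort()))
}

# Simple standardized random regression problem.
std_problem <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    x <- scale(matrix(rnorm(n * p), n, p))
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    x
  })
}
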