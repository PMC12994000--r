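#' Construct a frame sequence
#'
#' Bundles a grayscale stimulus stream with its aligned episode-terminal,
#' action, and reward logs. Frames are stored as an `H x W x T` array in
#' `[0, 255]`; time runs along the third dimension.
#'
#' @param frames `H x W x T` numeric array of grayscale intensities in
#'   `[0, 255]`.
#' @param terminal_flags Length-`T` logical vector; `TRUE` marks the last
#'   state of an episode.
#' @param actions Length-`T` integer action codes (optional).
#' @param rewards Length-`T` numeric rewards (optional).
#' @param rate_hz Sampling rate of the stream in Hz. Defaults to 45, the rate
#'   at which game states are logged.
#' @return An object of class `venc_frames`.
#' @export
frame_sequence <- function(frames, terminal_flags = NULL, actions = NULL,
                           rewards = NULL, rate_hz = 45) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_venc("`frames` must be an H x W x T array")
  }
  tt <- dim(frames)[3]
  if (tt < 1L) stop_venc("empty frame sequence")
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) stop_venc("frame intensities must lie in [0, 255]")
  terminal_flags <- terminal_flags %||% rep(FALSE, tt)
  actions <- actions %||% rep(0L, tt)
  rewards <- rewards %||% rep(0, tt)
  if (length(terminal_flags) != tt || length(actions) != tt || length(rewards) != tt) {
    stop_venc("terminal/action/reward logs must all have length T = %d", tt)
  }
  structure(
    list(frames = frames, terminal_flags = as.logical(terminal_flags),
         actions = as.integer(actions), rewards = as.numeric(rewards),
         rate_hz = rate_hz),
    class = "venc_frames"
  )
}

#' @export
print.venc_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<venc_frames> %d states of %d x %d at %g Hz, %d episode terminal(s)\n",
              d[3], d[1], d[2], x$rate_hz, sum(x$terminal_flags)))
  invisible(x)
}

# Area-style resampling matrix mapping `from` samples onto `to` samples:
# each output cell averages the input cells it overlaps, weighted by overlap.
resize_weights <- function(from, to) {
  w <- matrix(0, to, from)
  scale <- from / to
  for (i in seq_len(to)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), from)
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) w[i, j] <- overlap
    }
  }
  w / scale
}

#' Preprocess raw frames into network-ready states
#'
#' Each state is the element-wise maximum of the current and previous raw
#' frame (the first state is the first frame unchanged), which removes the
#' flicker of sprites drawn on alternating frames. States are then resized to
#' `target_size x target_size` by area-weighted downsampling.
#'
#' @param raw `H x W x T` array of grayscale intensities in `[0, 255]`, or a
#'   `venc_frames` object whose frames have not yet been max-pooled.
#' @param target_size Output height/width in pixels (default 84).
#' @param terminal_flags,actions,rewards,rate_hz Passed through to
#'   [frame_sequence()]; taken from `raw` when it is a `venc_frames`.
#' @return A `venc_frames` whose frames are the preprocessed states.
#' @export
preprocess_frames <- function(raw, target_size = 84, terminal_flags = NULL,
                              actions = NULL, rewards = NULL, rate_hz = 45) {
  if (inherits(raw, "venc_frames")) {
    terminal_flags <- terminal_flags %||% raw$terminal_flags
    actions <- actions %||% raw$actions
    rewards <- rewards %||% raw$rewards
    rate_hz <- raw$rate_hz
    raw <- raw$frames
  }
  if (!is.array(raw) || length(dim(raw)) != 3L) {
    stop_venc("`raw` must be an H x W x T array of 2-D frames")
  }
  d <- dim(raw)
  if (d[3] < 1L) stop_venc("empty frame sequence")
  states <- raw
  if (d[3] > 1L) {
    prev <- raw[, , -d[3], drop = FALSE]
    cur <- raw[, , -1L, drop = FALSE]
    states[, , -1L] <- pmax(cur, prev)
  }
  if (d[1] != target_size || d[2] != target_size) {
    wh <- resize_weights(d[1], target_size)
    ww <- resize_weights(d[2], target_size)
    out <- array(0, c(target_size, target_size, d[3]))
    for (t in seq_len(d[3])) out[, , t] <- wh %*% states[, , t] %*% t(ww)
    states <- out
  }
  frame_sequence(states, terminal_flags, actions, rewards, rate_hz)
}

#' Stack consecutive states into network input volumes
#'
#' The network input at time `t` is the stack of states `t - depth + 1, ..., t`.
#' The first `depth - 1` stacks are left-padded by repeating the first state,
#' so that one stack exists per state and the feature series keeps the length
#' of the state series.
#'
#' @param seq A `venc_frames` of preprocessed states.
#' @param depth Number of consecutive states per stack (default 4).
#' @param pad If `FALSE`, error when `depth` exceeds the series length instead
#'   of padding (padding within the series is always applied at the start).
#' @return `H x W x depth x T` array; `[, , d, t]` is state `t - depth + d`.
#' @export
stack_states <- function(seq, depth = 4, pad = TRUE) {
  stopifnot(inherits(seq, "venc_frames"))
  if (depth < 1L) stop_venc("`depth` must be >= 1")
  d <- dim(seq$frames)
  tt <- d[3]
  if (!pad && depth > tt) {
    stop_venc("depth %d exceeds series length %d and padding is disabled", depth, tt)
  }
  out <- array(0, c(d[1], d[2], depth, tt))
  for (t in seq_len(tt)) {
    idx <- pmax((t - depth + 1L):t, 1L)
    out[, , , t] <- seq$frames[, , idx]
  }
  out
}
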