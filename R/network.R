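#' Spatial output size of a valid convolution
#'
#' @param input_size Input height/width in pixels.
#' @param kernel Kernel size.
#' @param stride Stride (>= 1).
#' @return `floor((input_size - kernel) / stride) + 1`.
#' @examples
#' conv_output_size(84, 8, 4) # 20
#' conv_output_size(20, 4, 2) # 9
#' conv_output_size(9, 3, 1)  # 7
#' @export
conv_output_size <- function(input_size, kernel, stride) {
  if (kernel > input_size) stop_venc("kernel %d larger than input %d", kernel, input_size)
  if (stride < 1) stop_venc("stride must be >= 1")
  as.integer(floor((input_size - kernel) / stride) + 1)
}

#' Describe a layered action-value network
#'
#' Three architectures are supported, sharing the convolutional trunk
#' (32 8x8/4, 64 4x4/2, 64 3x3/1 on an 84 x 84 four-frame stack, giving the
#' spatial size chain 84 -> 20 -> 9 -> 7):
#' \describe{
#'   \item{feedforward}{trunk, a fully connected layer of 512 ReLU units
#'     (layer 4), and a linear output of Q-values, one per action.}
#'   \item{dueling}{trunk, then two separate 512-unit ReLU streams (layer 4)
#'     feeding a state-value head and an action-advantage head, combined as
#'     `Q = V + A - mean(A)`.}
#'   \item{recurrent_dueling}{trunk, a fully connected 512-unit layer feeding
#'     a single 512-unit LSTM cell whose state resets at episode terminals,
#'     then the dueling streams and output as above.}
#' }
#'
#' @param variant One of `"feedforward"`, `"dueling"`, `"recurrent_dueling"`.
#' @param n_actions Number of actions (output units).
#' @param input_size Input height/width (default 84).
#' @param stack_depth Frames per input stack (default 4).
#' @return A `venc_network_spec` with per-layer unit counts.
#' @export
network_spec <- function(variant = c("feedforward", "dueling", "recurrent_dueling"),
                         n_actions = 4L, input_size = 84L, stack_depth = 4L) {
  variant <- match.arg(variant)
  if (n_actions < 1L) stop_venc("`n_actions` must be positive")
  conv <- list(
    list(out = 32L, kernel = 8L, stride = 4L),
    list(out = 64L, kernel = 4L, stride = 2L),
    list(out = 64L, kernel = 3L, stride = 1L)
  )
  sz <- input_size
  for (i in seq_along(conv)) {
    sz <- conv_output_size(sz, conv[[i]]$kernel, conv[[i]]$stride)
    conv[[i]]$spatial <- sz
  }
  flat <- sz^2 * conv[[3]]$out
  units <- c(
    conv1 = conv[[1]]$spatial^2 * conv[[1]]$out,
    conv2 = conv[[2]]$spatial^2 * conv[[2]]$out,
    conv3 = flat,
    lstm = if (variant == "recurrent_dueling") 512L else 0L,
    layer4 = if (variant == "feedforward") 512L else 1024L,
    output = as.integer(n_actions)
  )
  structure(
    list(variant = variant, conv = conv, fc_units = 512L, lstm_units = 512L,
         n_actions = as.integer(n_actions), input_size = as.integer(input_size),
         stack_depth = as.integer(stack_depth), flat = as.integer(flat),
         units = units),
    class = "venc_network_spec"
  )
}

#' @export
print.venc_network_spec <- function(x, ...) {
  cat(sprintf("<venc_network_spec> %s, %d actions\n", x$variant, x$n_actions))
  cat("  units:", paste(sprintf("%s=%d", names(x$units), x$units), collapse = ", "), "\n")
  invisible(x)
}

#' Layer labels carried by a network variant's feature series
#' @param spec A `venc_network_spec`.
#' @param include_output Include the Q-value output layer?
#' @return Character vector of layer labels in network order.
#' @export
feature_layers <- function(spec, include_output = TRUE) {
  l <- names(spec$units)[spec$units > 0]
  if (!include_output) l <- setdiff(l, "output")
  l
}

#' Generate seeded fixture weights
#'
#' Variance-scaled Gaussian initialization (He-style for ReLU layers,
#' 1/fan-in for the LSTM, with the forget-gate bias set to 1), deterministic
#' given the seed. These stand in for trained weights, which are out of scope
#' here; the resulting activations are non-degenerate on varied input.
#'
#' @param spec A `venc_network_spec`.
#' @param seed Integer seed.
#' @param zero_init If `TRUE`, return all-zero weights (degenerate fixture).
#' @return A named list of weight arrays conforming to `spec`.
#' @export
make_fixture_weights <- function(spec, seed = 1L, zero_init = FALSE) {
  stopifnot(inherits(spec, "venc_network_spec"))
  gen <- function(dims, fan_in, gain = 2) {
    if (zero_init) return(array(0, dims))
    array(rnorm(prod(dims), sd = sqrt(gain / fan_in)), dims)
  }
  with_seed(child_seed(seed, paste0("weights-", spec$variant)), {
    w <- list()
    in_ch <- spec$stack_depth
    for (i in 1:3) {
      cv <- spec$conv[[i]]
      w[[paste0("conv", i)]] <- list(
        w = gen(c(cv$kernel, cv$kernel, in_ch, cv$out), cv$kernel^2 * in_ch),
        b = numeric(cv$out)
      )
      in_ch <- cv$out
    }
    nA <- spec$n_actions
    if (spec$variant == "feedforward") {
      w$fc <- list(w = gen(c(spec$flat, 512L), spec$flat), b = numeric(512))
      w$out <- list(w = gen(c(512L, nA), 512, gain = 1), b = numeric(nA))
    } else {
      stream_in <- if (spec$variant == "recurrent_dueling") 512L else spec$flat
      if (spec$variant == "recurrent_dueling") {
        w$fc <- list(w = gen(c(spec$flat, 512L), spec$flat), b = numeric(512))
        b_lstm <- numeric(2048)
        b_lstm[513:1024] <- 1 # forget gate bias
        w$lstm <- list(
          w_in = gen(c(512L, 2048L), 512, gain = 1),
          w_rec = gen(c(512L, 2048L), 512, gain = 1),
          b = b_lstm
        )
      }
      w$value_stream <- list(w = gen(c(stream_in, 512L), stream_in), b = numeric(512))
      w$adv_stream <- list(w = gen(c(stream_in, 512L), stream_in), b = numeric(512))
      w$value_head <- list(w = gen(c(512L, 1L), 512, gain = 1), b = numeric(1))
      w$adv_head <- list(w = gen(c(512L, nA), 512, gain = 1), b = numeric(nA))
    }
    w
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Flat gather indices for im2col. Input volume h x w x ch flattened
# column-major; returns (k*k*ch) x (oh*ow) index matrix whose column p holds
# the input positions of output patch p (kernel row fastest, then kernel
# column, then channel — matching column-major flattening of the kernel).
conv_gather_index <- function(h, w, ch, k, stride) {
  oh <- conv_output_size(h, k, stride)
  ow <- conv_output_size(w, k, stride)
  dr <- rep(seq_len(k), times = k * ch)
  dc <- rep(rep(seq_len(k), each = k), times = ch)
  dch <- rep(seq_len(ch), each = k * k)
  elem <- dr + h * (dc - 1L) + h * w * (dch - 1L) # offset of patch element
  ox <- rep(seq_len(oh), times = ow)
  oy <- rep(seq_len(ow), each = oh)
  origin <- (ox - 1L) * stride + h * ((oy - 1L) * stride) # top-left, 0-based row/col
  outer(elem, origin, `+`)
}

check_weight_shapes <- function(spec, weights) {
  in_ch <- spec$stack_depth
  for (i in 1:3) {
    cv <- spec$conv[[i]]
    want <- c(cv$kernel, cv$kernel, in_ch, cv$out)
    got <- dim(weights[[paste0("conv", i)]]$w)
    if (!identical(as.integer(got), as.integer(want))) {
      stop_venc("conv%d weight shape (%s) does not match spec (%s)",
                i, paste(got, collapse = "x"), paste(want, collapse = "x"))
    }
    in_ch <- cv$out
  }
  if (spec$variant == "feedforward") {
    if (!identical(as.integer(dim(weights$fc$w)), c(spec$flat, 512L))) {
      stop_venc("fc weight shape does not match spec")
    }
  } else if (spec$variant == "dueling") {
    if (!identical(as.integer(dim(weights$value_stream$w)), c(spec$flat, 512L))) {
      stop_venc("dueling stream weight shape does not match spec")
    }
  } else {
    if (is.null(weights$lstm) ||
        !identical(as.integer(dim(weights$lstm$w_in)), c(512L, 2048L))) {
      stop_venc("recurrent variant requires LSTM weights of shape 512 x 2048")
    }
  }
  invisible(TRUE)
}

# Resolve a per-layer unit subsample request into index vectors.
resolve_keep <- function(spec, keep_units, seed) {
  layers <- feature_layers(spec)
  keep <- stats::setNames(vector("list", length(layers)), layers)
  for (l in layers) {
    n <- spec$units[[l]]
    req <- keep_units[[l]]
    if (is.null(req)) {
      keep[[l]] <- seq_len(n)
    } else if (length(req) == 1L && req < n) {
      keep[[l]] <- with_seed(child_seed(seed, paste0("keep-", l)),
                             sort(sample.int(n, req)))
    } else if (length(req) == 1L) {
      keep[[l]] <- seq_len(n)
    } else {
      if (any(req < 1L | req > n)) stop_venc("unit indices out of range for %s", l)
      keep[[l]] <- sort(as.integer(req))
    }
  }
  keep
}

#' Run stimulus states through a network, recording unit activations
#'
#' Performs a deterministic forward pass over the whole state series and
#' returns the activation time series of every (retained) unit, labelled by
#' layer. Convolutional and layer-4 activations are recorded post-ReLU; the
#' LSTM layer records the hidden output (bounded by tanh); the output layer
#' records raw Q-values. For the recurrent variant, hidden and cell state are
#' reset to zero immediately after any time step whose terminal flag is set,
#' so activations following a terminal equal those of a fresh run.
#'
#' @param spec A `venc_network_spec`.
#' @param weights Conforming weights (see [make_fixture_weights()]).
#' @param x A `venc_frames` of preprocessed states (stacks are formed
#'   internally with repeat-first padding), or an `H x W x depth x T` stack
#'   array from [stack_states()] (small inputs; materializes every stack).
#' @param terminal_flags Length-`T` logical; defaults to the flags in `x`
#'   when it is a `venc_frames`.
#' @param keep_units Optional named list (by layer label) giving either a
#'   single count — that many units are sampled deterministically from
#'   `seed` — or explicit unit indices. Unlisted layers keep all units.
#' @param seed Seed for unit subsampling only; the pass itself is exact.
#' @param chunk Frames per processing chunk (memory/speed trade-off).
#' @return A `venc_features`: list with `values` (U x T matrix), `unit_layer`,
#'   `unit_index` (index within the layer), and `rate_hz`.
#' @export
forward_features <- function(spec, weights, x, terminal_flags = NULL,
                             keep_units = NULL, seed = 1L, chunk = 96L) {
  stopifnot(inherits(spec, "venc_network_spec"))
  check_weight_shapes(spec, weights)
  if (inherits(x, "venc_frames")) {
    terminal_flags <- terminal_flags %||% x$terminal_flags
    rate_hz <- x$rate_hz
    d <- dim(x$frames)
    if (d[1] != spec$input_size || d[2] != spec$input_size) {
      stop_venc("state size %dx%d does not match spec input %d", d[1], d[2], spec$input_size)
    }
    states <- matrix(x$frames, nrow = d[1] * d[2])
  } else if (is.array(x) && length(dim(x)) == 4L) {
    rate_hz <- 45
    d <- dim(x)
    if (d[3] != spec$stack_depth) stop_venc("stack depth %d does not match spec", d[3])
    states <- NULL
  } else {
    stop_venc("`x` must be a venc_frames or a 4-D stack array")
  }
  tt <- if (is.null(states)) dim(x)[4] else ncol(states)
  terminal_flags <- terminal_flags %||% rep(FALSE, tt)
  if (length(terminal_flags) != tt) stop_venc("terminal flags misaligned with states")

  keep <- resolve_keep(spec, keep_units, seed)
  layers <- feature_layers(spec)
  out <- lapply(layers, function(l) matrix(0, length(keep[[l]]), tt))
  names(out) <- layers

  cv <- spec$conv
  k1 <- matrix(weights$conv1$w, ncol = cv[[1]]$out)
  k2 <- matrix(weights$conv2$w, ncol = cv[[2]]$out)
  k3 <- matrix(weights$conv3$w, ncol = cv[[3]]$out)
  n1 <- cv[[1]]$spatial^2; n2 <- cv[[2]]$spatial^2; n3 <- cv[[3]]$spatial^2
  idx2 <- conv_gather_index(cv[[1]]$spatial, cv[[1]]$spatial, cv[[1]]$out,
                            cv[[2]]$kernel, cv[[2]]$stride)
  idx3 <- conv_gather_index(cv[[2]]$spatial, cv[[2]]$spatial, cv[[2]]$out,
                            cv[[3]]$kernel, cv[[3]]$stride)
  depth <- spec$stack_depth

  if (is.null(states)) {
    # Explicit-stack path: one im2col over all stack channels per time step.
    idx1s <- conv_gather_index(spec$input_size, spec$input_size, depth,
                               cv[[1]]$kernel, cv[[1]]$stride)
  } else {
    # Per-state path: the convolution is linear over stack channels, so each
    # state's single-channel patches are computed once and combined with the
    # per-channel kernel slices at the four time lags.
    idx1 <- conv_gather_index(spec$input_size, spec$input_size, 1L,
                              cv[[1]]$kernel, cv[[1]]$stride)
    k1_slices <- lapply(seq_len(depth), function(dd) {
      matrix(weights$conv1$w[, , dd, ], ncol = cv[[1]]$out)
    })
  }

  fc_in_all <- if (spec$variant == "recurrent_dueling") matrix(0, 512, tt)
  starts <- seq(1L, tt, by = chunk)

  # gather-index vectors are reused across chunks of the same size
  idx_cache <- new.env(parent = emptyenv())
  gather_idx <- function(key, idx, n_slices, slice_len) {
    id <- paste0(key, "-", n_slices)
    got <- idx_cache[[id]]
    if (is.null(got)) {
      got <- rep.int(as.integer(idx), n_slices) +
        rep(slice_len * (seq_len(n_slices) - 1L), each = length(idx))
      idx_cache[[id]] <- got
    }
    got
  }
  k1_all <- if (!is.null(states)) do.call(cbind, k1_slices)

  for (s0 in starts) {
    s1 <- min(s0 + chunk - 1L, tt)
    nc <- s1 - s0 + 1L
    if (is.null(states)) {
      a1 <- matrix(0, spec$units[["conv1"]], nc)
      for (j in seq_len(nc)) {
        p <- matrix(as.vector(x[, , , s0 + j - 1L])[idx1s], nrow = nrow(idx1s))
        a1[, j] <- pmax(as.vector(crossprod(p, k1)) +
                          rep(weights$conv1$b, each = n1), 0)
      }
    } else {
      # extended chunk: depth-1 preceding states (clamped to the first state)
      ext <- pmax((s0 - depth + 1L):s1, 1L)
      ne <- length(ext)
      sc <- states[, ext, drop = FALSE]
      p1 <- sc[gather_idx("c1", idx1, ne, nrow(states))]
      dim(p1) <- c(nrow(idx1), n1 * ne)
      zz <- crossprod(p1, k1_all) # (n1*ne) x (32*depth)
      dim(zz) <- c(n1, ne, cv[[1]]$out, depth)
      pre <- zz[, depth:(depth + nc - 1L), , depth, drop = FALSE]
      dim(pre) <- c(n1, nc, cv[[1]]$out)
      for (dd in seq_len(depth - 1L)) {
        lag <- zz[, dd:(dd + nc - 1L), , dd, drop = FALSE]
        dim(lag) <- dim(pre)
        pre <- pre + lag
      }
      if (any(weights$conv1$b != 0)) {
        pre <- pre + rep(weights$conv1$b, each = n1 * nc)
      }
      a1 <- aperm(pmax(pre, 0), c(1, 3, 2))
      dim(a1) <- c(spec$units[["conv1"]], nc)
    }
    out$conv1[, s0:s1] <- a1[keep$conv1, , drop = FALSE]

    p2 <- a1[gather_idx("c2", idx2, nc, nrow(a1))]
    dim(p2) <- c(nrow(idx2), n2 * nc)
    z2 <- pmax(crossprod(p2, k2) + rep(weights$conv2$b, each = n2 * nc), 0)
    dim(z2) <- c(n2, nc, cv[[2]]$out)
    a2 <- aperm(z2, c(1, 3, 2))
    dim(a2) <- c(spec$units[["conv2"]], nc)
    out$conv2[, s0:s1] <- a2[keep$conv2, , drop = FALSE]

    p3 <- a2[gather_idx("c3", idx3, nc, nrow(a2))]
    dim(p3) <- c(nrow(idx3), n3 * nc)
    z3 <- pmax(crossprod(p3, k3) + rep(weights$conv3$b, each = n3 * nc), 0)
    dim(z3) <- c(n3, nc, cv[[3]]$out)
    a3 <- aperm(z3, c(1, 3, 2))
    dim(a3) <- c(spec$flat, nc)
    out$conv3[, s0:s1] <- a3[keep$conv3, , drop = FALSE]

    if (spec$variant == "feedforward") {
      fc <- pmax(crossprod(weights$fc$w, a3) + weights$fc$b, 0)
      out$layer4[, s0:s1] <- fc[keep$layer4, , drop = FALSE]
      q <- crossprod(weights$out$w, fc) + weights$out$b
      out$output[, s0:s1] <- q[keep$output, , drop = FALSE]
    } else if (spec$variant == "dueling") {
      vs <- pmax(crossprod(weights$value_stream$w, a3) + weights$value_stream$b, 0)
      as_ <- pmax(crossprod(weights$adv_stream$w, a3) + weights$adv_stream$b, 0)
      l4 <- rbind(vs, as_)
      out$layer4[, s0:s1] <- l4[keep$layer4, , drop = FALSE]
      v <- crossprod(weights$value_head$w, vs) + weights$value_head$b
      a <- crossprod(weights$adv_head$w, as_) + weights$adv_head$b
      q <- sweep(a, 2, colMeans(a)) + matrix(v, spec$n_actions, nc, byrow = TRUE)
      out$output[, s0:s1] <- q[keep$output, , drop = FALSE]
    } else {
      fc_in_all[, s0:s1] <- pmax(crossprod(weights$fc$w, a3) + weights$fc$b, 0)
    }
  }

  if (spec$variant == "recurrent_dueling") {
    # Sequential LSTM over the whole session; gates ordered i, f, g, o.
    pre <- crossprod(weights$lstm$w_in, fc_in_all) + weights$lstm$b
    u <- t(weights$lstm$w_rec)
    h <- numeric(512); cc <- numeric(512)
    hs <- matrix(0, 512, tt)
    for (t in seq_len(tt)) {
      z <- pre[, t] + u %*% h
      i <- sigmoid(z[1:512]); f <- sigmoid(z[513:1024])
      g <- tanh(z[1025:1536]); o <- sigmoid(z[1537:2048])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      hs[, t] <- h
      if (terminal_flags[t]) { h <- numeric(512); cc <- numeric(512) }
    }
    out$lstm <- hs[keep$lstm, , drop = FALSE]
    vs <- pmax(crossprod(weights$value_stream$w, hs) + weights$value_stream$b, 0)
    as_ <- pmax(crossprod(weights$adv_stream$w, hs) + weights$adv_stream$b, 0)
    l4 <- rbind(vs, as_)
    out$layer4 <- l4[keep$layer4, , drop = FALSE]
    v <- crossprod(weights$value_head$w, vs) + weights$value_head$b
    a <- crossprod(weights$adv_head$w, as_) + weights$adv_head$b
    q <- sweep(a, 2, colMeans(a)) + matrix(v, spec$n_actions, tt, byrow = TRUE)
    out$output <- q[keep$output, , drop = FALSE]
  }

  feature_series(
    values = do.call(rbind, out[layers]),
    unit_layer = rep(layers, vapply(keep[layers], length, 1L)),
    unit_index = unlist(keep[layers], use.names = FALSE),
    rate_hz = rate_hz
  )
}

#' Construct a feature time series
#'
#' @param values `U x T` activation matrix.
#' @param unit_layer Length-`U` layer labels.
#' @param unit_index Length-`U` unit indices within each layer.
#' @param rate_hz Sampling rate in Hz.
#' @return A `venc_features` object.
#' @export
feature_series <- function(values, unit_layer, unit_index = NULL, rate_hz = 45) {
  values <- as.matrix(values)
  if (length(unit_layer) != nrow(values)) stop_venc("one layer label per unit required")
  structure(
    list(values = values, unit_layer = as.character(unit_layer),
         unit_index = unit_index %||% seq_len(nrow(values)), rate_hz = rate_hz),
    class = "venc_features"
  )
}

#' @export
print.venc_features <- function(x, ...) {
  cat(sprintf("<venc_features> %d units x %d steps at %g Hz\n",
              nrow(x$values), ncol(x$values), x$rate_hz))
  tab <- table(factor(x$unit_layer, levels = unique(x$unit_layer)))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
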