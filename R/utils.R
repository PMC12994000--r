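# Internal helpers shared across modules.

# Variance threshold below which a series counts as constant.
VAR_EPS <- 1e-12

stop_venc <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "voxelenc_error")

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop_venc("non-finite values in `%s`", name)
  invisible(x)
}

# Row-wise z-score of a U x T matrix using the sample sd (n - 1 divisor).
# Errors on (near-)constant rows, naming the first offender.
zscore_rows <- function(m, what = "unit") {
  mu <- rowMeans(m)
  centred <- m - mu
  v <- rowSums(centred^2) / (ncol(m) - 1)
  if (any(v <= VAR_EPS)) {
    bad <- which(v <= VAR_EPS)[1L]
    stop_venc("constant series: %s %d has variance <= %g", what, bad, VAR_EPS)
  }
  centred / sqrt(v)
}

# Deterministic child seed derived from a master seed and a label.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483587L) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
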