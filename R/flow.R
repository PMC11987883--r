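#' Dense optical-flow field
#'
#' A per-pixel 2-D displacement grid between two video frames: `u` holds the
#' horizontal and `v` the vertical displacement component, both in
#' pixels/frame, each a `height x width` matrix.
#'
#' @param u,v Numeric matrices of identical dimension with finite entries.
#' @return An object of class `flow_field`.
#' @export
#' @examples
#' f <- flow_field(matrix(3, 4, 5), matrix(4, 4, 5))
#' mean_displacement(f)
flow_field <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !identical(dim(u), dim(v))) {
    fc_abort("`u` and `v` must be matrices of identical dimension.")
  }
  if (length(u) == 0L) {
    fc_abort("flow field must contain at least one pixel.")
  }
  if (!all(is.finite(u)) || !all(is.finite(v))) {
    fc_abort("flow components must be finite.")
  }
  structure(list(u = u, v = v), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d px, mean |displacement| %.3f px/frame\n",
              nrow(x$u), ncol(x$u), mean_displacement(x)))
  invisible(x)
}

#' @export
dim.flow_field <- function(x) dim(x$u)

#' Per-frame activity: mean displacement magnitude
#'
#' The activity level of one frame pair is the mean over all pixels of the
#' Euclidean norm of the flow vector,
#' \eqn{A = \frac{1}{N}\sum_i \sqrt{u_i^2 + v_i^2}}, in pixels/frame.
#'
#' @param field A [flow_field()].
#' @return A non-negative scalar.
#' @export
mean_displacement <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  mean(sqrt(field$u^2 + field$v^2))
}

#' Segment activity: sum of frame-wise activity levels
#'
#' Aggregates per-frame activity values over one video segment (for the
#' reference acquisition protocol, a 5-min segment at 2 fps holds 600
#' frames). Units: cumulative pixels of displacement.
#'
#' @param frame_activities Non-negative numeric vector of per-frame values.
#' @return Their sum.
#' @export
segment_activity <- function(frame_activities) {
  if (length(frame_activities) == 0L) {
    fc_abort("`frame_activities` must be non-empty.")
  }
  if (!is.numeric(frame_activities) || !all(is.finite(frame_activities))) {
    fc_abort("`frame_activities` must be finite numbers.")
  }
  if (any(frame_activities < 0)) {
    fc_abort("frame activities are displacement magnitudes and cannot be negative.")
  }
  sum(frame_activities)
}

#' Min-max normalization of an activity series to [0, 100]
#'
#' Maps `x` to `(x - ref_min) / (ref_max - ref_min) * 100`. Values outside
#' the reference range (as happens when the reference was frozen on training
#' data and new data exceed it) are clipped to `[0, 100]`.
#'
#' @param raw Numeric vector.
#' @param ref_min,ref_max Reference range; defaults to the range of `raw`.
#' @param allow_constant If `TRUE` a degenerate reference range
#'   (`ref_max == ref_min`) maps everything to 0 instead of erroring.
#' @return Numeric vector in `[0, 100]`.
#' @export
#' @examples
#' normalize_series(c(0, 5, 10))
normalize_series <- function(raw, ref_min = min(raw), ref_max = max(raw),
                             allow_constant = FALSE) {
  if (!is.numeric(raw) || length(raw) == 0L) {
    fc_abort("`raw` must be a non-empty numeric vector.")
  }
  check_scalar_number(ref_min, "ref_min")
  check_scalar_number(ref_max, "ref_max")
  if (ref_max < ref_min) {
    fc_abort("`ref_max` must be >= `ref_min`.")
  }
  if (ref_max == ref_min) {
    if (allow_constant) return(rep(0, length(raw)))
    fc_abort("degenerate reference range: `ref_max` equals `ref_min`.",
             class = "farrowcast_degenerate_range")
  }
  pmin(100, pmax(0, (raw - ref_min) / (ref_max - ref_min) * 100))
}

#' Centered moving-average smoothing with edge shrinkage
#'
#' Smooths a series with an odd centered window; at the boundaries the
#' window is truncated to the available points (no padding), so the output
#' has the same length as the input and `window = 1` is the identity.
#'
#' @param values Numeric vector.
#' @param window Odd window width in points, `1 <= window <= length(values)`.
#' @return Smoothed numeric vector.
#' @export
#' @examples
#' smooth_series(c(0, 3, 0), window = 3)
smooth_series <- function(values, window = 5L) {
  if (!is.numeric(values) || length(values) == 0L) {
    fc_abort("`values` must be a non-empty numeric vector.")
  }
  check_count(window, "window", min = 1L)
  if (window %% 2L == 0L) {
    fc_abort("`window` must be odd so the window is centered.")
  }
  n <- length(values)
  if (window > n) {
    fc_abort("`window` must not exceed the series length.")
  }
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

check_same_shape <- function(pred, truth) {
  stopifnot(inherits(pred, "flow_field"), inherits(truth, "flow_field"))
  if (!identical(dim(pred$u), dim(truth$u))) {
    fc_abort("flow fields must have identical dimensions.")
  }
}

#' Mean end-point error between two flow fields
#'
#' Average over pixels of the Euclidean distance between predicted and
#' ground-truth flow vectors, in pixels.
#'
#' @param pred,truth [flow_field()] objects of identical dimension.
#' @return Non-negative scalar; 0 iff the fields are identical.
#' @export
epe <- function(pred, truth) {
  check_same_shape(pred, truth)
  mean(sqrt((pred$u - truth$u)^2 + (pred$v - truth$v)^2))
}

#' Percentage of pixels with large flow error (Fl-all)
#'
#' Share of pixels whose per-pixel end-point error exceeds the threshold
#' `delta`, as a percentage in `[0, 100]`.
#'
#' @inheritParams epe
#' @param delta Positive error threshold in pixels (3 px is customary).
#' @return Percentage of outlier pixels.
#' @export
fl_all <- function(pred, truth, delta = 3) {
  check_same_shape(pred, truth)
  check_scalar_number(delta, "delta", min = 0, allow_zero = FALSE)
  err <- sqrt((pred$u - truth$u)^2 + (pred$v - truth$v)^2)
  100 * mean(err > delta)
}

# --- Middlebury .flo I/O ----------------------------------------------------
# Layout: float32 magic 202021.25 ("PIEH"), int32 width, int32 height, then
# width*height interleaved (u, v) float32 pairs in row-major order, all
# little-endian.

FLO_MAGIC <- 202021.25

#' Read / write Middlebury `.flo` optical-flow files
#'
#' Bit-exact reader and writer for the standard little-endian `.flo`
#' container (float32 magic 202021.25, int32 width and height, interleaved
#' row-major `u`,`v` float32 pairs).
#'
#' @param field A [flow_field()].
#' @param path File path ending in `.flo`.
#' @return `write_flo()` returns `path` invisibly; `read_flo()` a
#'   [flow_field()].
#' @export
write_flo <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  h <- nrow(field$u); w <- ncol(field$u)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4L, endian = "little")
  writeBin(c(as.integer(w), as.integer(h)), con, size = 4L, endian = "little")
  inter <- numeric(2L * w * h)
  ut <- t(field$u)  # row-major traversal
  vt <- t(field$v)
  inter[seq(1L, by = 2L, length.out = w * h)] <- as.numeric(ut)
  inter[seq(2L, by = 2L, length.out = w * h)] <- as.numeric(vt)
  writeBin(inter, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_flo
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  if (!isTRUE(abs(magic - FLO_MAGIC) < 1e-3)) {
    fc_abort(sprintf("'%s' is not a Middlebury .flo file (bad magic).", path))
  }
  wh <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  w <- wh[1]; h <- wh[2]
  if (w < 1L || h < 1L) fc_abort("corrupt .flo header: non-positive dimensions.")
  inter <- readBin(con, "numeric", n = 2L * w * h, size = 4L, endian = "little")
  if (length(inter) != 2L * w * h) fc_abort("truncated .flo payload.")
  u <- matrix(inter[seq(1L, by = 2L, length.out = w * h)], nrow = h, ncol = w, byrow = TRUE)
  v <- matrix(inter[seq(2L, by = 2L, length.out = w * h)], nrow = h, ncol = w, byrow = TRUE)
  flow_field(u, v)
}

# --- pluggable flow estimation backends ------------------------------------

flow_backends <- new.env(parent = emptyenv())

#' Estimate optical flow between two frames via a registered backend
#'
#' Deep estimators (e.g. RAFT) are external to this package and plug in as
#' named backends; the built-in `"block_matching"` backend is an exhaustive
#' integer-displacement block matcher intended as a slow but dependable
#' reference for testing the activity pipeline on synthetic frames.
#'
#' @param frame_a,frame_b Numeric matrices of identical dimension (grayscale
#'   frames).
#' @param backend Backend name; see [register_flow_backend()].
#' @param ... Passed to the backend (for `"block_matching"`: `block_size`,
#'   default 8, and `search_radius`, default 4).
#' @return A [flow_field()].
#' @export
estimate_flow <- function(frame_a, frame_b, backend = "block_matching", ...) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b) ||
      !identical(dim(frame_a), dim(frame_b))) {
    fc_abort("frames must be matrices of identical dimension.")
  }
  fn <- flow_backends[[backend]]
  if (is.null(fn)) {
    fc_abort(sprintf("unknown flow backend '%s'; registered: %s.",
                     backend, paste(ls(flow_backends), collapse = ", ")),
             class = "farrowcast_backend_error")
  }
  fn(frame_a, frame_b, ...)
}

#' Register an optical-flow backend
#'
#' @param name Backend identifier.
#' @param fn Function `(frame_a, frame_b, ...) -> flow_field`.
#' @return `name`, invisibly.
#' @export
register_flow_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = flow_backends)
  invisible(name)
}

# exhaustive SSD block matching over integer displacements
block_matching_flow <- function(frame_a, frame_b, block_size = 8L,
                                search_radius = 4L) {
  block_size <- check_count(block_size, "block_size", min = 1L)
  search_radius <- check_count(search_radius, "search_radius", min = 0L)
  h <- nrow(frame_a); w <- ncol(frame_a)
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  shifts <- expand.grid(dx = -search_radius:search_radius,
                        dy = -search_radius:search_radius)
  for (by in seq(1L, h, by = block_size)) {
    for (bx in seq(1L, w, by = block_size)) {
      ys <- by:min(h, by + block_size - 1L)
      xs <- bx:min(w, bx + block_size - 1L)
      ref <- frame_a[ys, xs, drop = FALSE]
      best <- c(0, 0); best_ssd <- Inf
      for (k in seq_len(nrow(shifts))) {
        dy <- shifts$dy[k]; dx <- shifts$dx[k]
        ys2 <- ys + dy; xs2 <- xs + dx
        if (min(ys2) < 1L || max(ys2) > h || min(xs2) < 1L || max(xs2) > w) next
        cand <- frame_b[ys2, xs2, drop = FALSE]
        ssd <- sum((ref - cand)^2)
        if (ssd < best_ssd) {
          best_ssd <- ssd
          best <- c(dx, dy)
        }
      }
      u[ys, xs] <- best[1]
      v[ys, xs] <- best[2]
    }
  }
  flow_field(u, v)
}

#' Activity series from a sequence of flow fields
#'
#' Convenience wrapper: applies [mean_displacement()] to each field and
#' [segment_activity()] to the result.
#'
#' @param fields List of [flow_field()] objects from one video segment.
#' @return Scalar segment activity (pixels).
#' @export
segment_activity_from_fields <- function(fields) {
  if (length(fields) == 0L) fc_abort("`fields` must be non-empty.")
  segment_activity(vapply(fields, mean_displacement, numeric(1)))
}
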