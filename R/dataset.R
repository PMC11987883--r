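#' Region-of-interest specification
#'
#' Pixel rectangle in 0-based, half-open coordinates `[x1, x2) x [y1, y2)`,
#' so a ROI with corners `(167, 146)` and `(2499, 1232)` has width
#' `2499 - 167 = 2332` and height `1232 - 146 = 1086` exactly.
#'
#' @param top_left,bottom_right Integer `c(x, y)` pixel coordinates;
#'   `bottom_right` must strictly exceed `top_left` in both axes.
#' @return A `roi_spec` list with `top_left`, `bottom_right`, `width`,
#'   `height`.
#' @export
#' @examples
#' roi_spec(c(167, 146), c(2499, 1232))
roi_spec <- function(top_left, bottom_right) {
  if (length(top_left) != 2L || length(bottom_right) != 2L ||
      any(c(top_left, bottom_right) != round(c(top_left, bottom_right))) ||
      any(c(top_left, bottom_right) < 0)) {
    fc_abort("ROI corners must be non-negative integer c(x, y) pairs.")
  }
  if (bottom_right[1] <= top_left[1] || bottom_right[2] <= top_left[2]) {
    fc_abort("`bottom_right` must strictly exceed `top_left` in both axes.")
  }
  structure(
    list(top_left = as.integer(top_left),
         bottom_right = as.integer(bottom_right),
         width = as.integer(bottom_right[1] - top_left[1]),
         height = as.integer(bottom_right[2] - top_left[2])),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> (%d,%d)-(%d,%d): %d x %d px\n",
              x$top_left[1], x$top_left[2],
              x$bottom_right[1], x$bottom_right[2], x$width, x$height))
  invisible(x)
}

#' Crop a frame to a region of interest
#'
#' @param frame Numeric matrix (`height x width`) or `height x width x c`
#'   array.
#' @param roi A [roi_spec()]; must lie within the frame bounds.
#' @return The cropped frame with dimensions `roi$height x roi$width`.
#' @export
crop_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  d <- dim(frame)
  if (is.null(d) || length(d) < 2L) {
    fc_abort("`frame` must be a matrix or array with at least 2 dimensions.")
  }
  fh <- d[1]; fw <- d[2]
  if (roi$bottom_right[1] > fw || roi$bottom_right[2] > fh) {
    fc_abort(sprintf("ROI (%d x %d ending at (%d,%d)) exceeds the %d x %d frame.",
                     roi$width, roi$height,
                     roi$bottom_right[1], roi$bottom_right[2], fw, fh))
  }
  rows <- (roi$top_left[2] + 1L):roi$bottom_right[2]
  cols <- (roi$top_left[1] + 1L):roi$bottom_right[1]
  if (length(d) == 2L) {
    frame[rows, cols, drop = FALSE]
  } else {
    frame[rows, cols, , drop = FALSE]
  }
}

#' Frame-selection schedule for temporal downsampling
#'
#' Implements the acquisition convention of keeping a fixed set of frame
#' positions within each second of video (e.g. the 1st and 13th frame of
#' every second of 25-fps footage, giving an effective 2 fps).
#'
#' @param fps_in Input frame rate (frames per second).
#' @param indices_per_second Sorted set of 1-based positions within each
#'   second to retain; all must lie in `[1, fps_in]`.
#' @param n_seconds Clip duration in whole seconds.
#' @return Integer vector of retained 1-based frame indices into the
#'   original clip.
#' @export
#' @examples
#' length(select_frames(25, c(1, 13), n_seconds = 300))  # 600
select_frames <- function(fps_in, indices_per_second, n_seconds) {
  check_count(fps_in, "fps_in", min = 1L)
  check_count(n_seconds, "n_seconds", min = 1L)
  if (length(indices_per_second) == 0L ||
      any(indices_per_second != round(indices_per_second))) {
    fc_abort("`indices_per_second` must be integers.")
  }
  if (any(indices_per_second < 1L) || any(indices_per_second > fps_in)) {
    fc_abort(sprintf("`indices_per_second` must lie in [1, %d].", fps_in))
  }
  idx <- sort(unique(as.integer(indices_per_second)))
  as.integer(outer(idx, (seq_len(n_seconds) - 1L) * fps_in, `+`))
}

#' Build sliding-window remaining-time samples from activity series
#'
#' Slides a fixed-length window along each sow's activity series and labels
#' every window with the remaining time (in minutes) from the window's final
#' point to farrowing onset. With the end-anchored timestamp convention the
#' final window of a full pre-onset series has label 0.
#'
#' @param series Tibble with columns `sow_id`, `minutes_to_onset`
#'   (decreasing by 5 within each sow) and `activity`; one or several sows.
#' @param w Window length in points (default 72 = 6 h at 5-min steps).
#' @param step Step size in points between consecutive windows.
#' @return A tibble with one row per window: `sow_id`, `start_index`,
#'   `end_index`, `label` (minutes to onset, non-negative multiple of 5) and
#'   `window` (list-column of length-`w` numeric vectors). Per sow the
#'   window count is `floor((n - w)/step) + 1`.
#' @export
#' @examples
#' cfg <- sim_config(n_sows = 1, horizon_points = 96, diurnal_period = 12,
#'                   ramp_start = 24)
#' nrow(make_windows(simulate_cohort(cfg), w = 24, step = 1))  # 73
make_windows <- function(series, w = 72L, step = 1L) {
  need <- c("sow_id", "minutes_to_onset", "activity")
  if (!all(need %in% names(series))) {
    fc_abort(sprintf("`series` must have columns %s.", paste(need, collapse = ", ")))
  }
  w <- check_count(w, "w", min = 1L)
  step <- check_count(step, "step", min = 1L)
  one_sow <- function(df) {
    n <- nrow(df)
    if (w > n) {
      fc_abort(sprintf("window length %d exceeds series length %d.", w, n))
    }
    offs <- df$minutes_to_onset
    if (n > 1L && !all(diff(offs) == -5)) {
      fc_abort("`minutes_to_onset` must decrease by 5 along each series.")
    }
    starts <- seq(1L, n - w + 1L, by = step)
    ends <- starts + w - 1L
    tibble::tibble(
      sow_id = df$sow_id[1],
      start_index = starts,
      end_index = ends,
      label = offs[ends],
      window = lapply(seq_along(starts),
                      function(i) df$activity[starts[i]:ends[i]])
    )
  }
  series |>
    dplyr::group_by(.data$sow_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(one_sow)
}

# internal: windows tibble -> design matrix + labels
windows_matrix <- function(windows) {
  x <- do.call(rbind, windows$window)
  list(x = x, y = windows$label, sow_id = windows$sow_id)
}

#' Subject-level train/validation/test split with cross-validation folds
#'
#' Randomly partitions sow identifiers into disjoint train, validation and
#' test sets and assigns the non-test sows to equally sized
#' cross-validation folds. Splitting at the subject level guarantees that
#' no window of a held-out sow can leak into training.
#'
#' @param sow_ids Character vector of subject identifiers.
#' @param n_train,n_val,n_test Set sizes; must sum to `length(sow_ids)`.
#' @param n_folds Number of folds partitioning the `n_train + n_val`
#'   non-test sows evenly.
#' @param seed RNG seed.
#' @return A `split_plan` list with `train`, `val`, `test` (character
#'   vectors) and `folds` (named integer vector over train and val sows).
#' @export
#' @examples
#' make_split(sprintf("sow_%02d", 1:20), 12, 4, 4, n_folds = 4, seed = 1)
make_split <- function(sow_ids, n_train = 12L, n_val = 4L, n_test = 4L,
                       n_folds = 4L, seed = 1L) {
  sow_ids <- as.character(sow_ids)
  if (anyDuplicated(sow_ids)) fc_abort("`sow_ids` must be unique.")
  n_train <- check_count(n_train, "n_train", min = 1L)
  n_val <- check_count(n_val, "n_val", min = 0L)
  n_test <- check_count(n_test, "n_test", min = 0L)
  n_folds <- check_count(n_folds, "n_folds", min = 1L)
  if (n_train + n_val + n_test != length(sow_ids)) {
    fc_abort(sprintf("split sizes %d+%d+%d do not sum to the %d subjects.",
                     n_train, n_val, n_test, length(sow_ids)))
  }
  n_dev <- n_train + n_val
  if (n_dev %% n_folds != 0L) {
    fc_abort(sprintf("%d folds cannot evenly partition the %d non-test subjects.",
                     n_folds, n_dev))
  }
  with_seed(seed, {
    perm <- sample(sow_ids)
    train <- perm[seq_len(n_train)]
    val <- perm[n_train + seq_len(n_val)]
    test <- perm[n_train + n_val + seq_len(n_test)]
    dev <- c(train, val)
    folds <- rep(seq_len(n_folds), each = n_dev %/% n_folds)
    names(folds) <- sample(dev)
    structure(list(train = sort(train), val = sort(val), test = sort(test),
                   folds = folds[order(names(folds))]),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / val %d / test %d, %d CV folds\n",
              length(x$train), length(x$val), length(x$test),
              length(unique(x$folds))))
  invisible(x)
}

#' Persist or restore a split plan as JSON
#'
#' @param plan A `split_plan` from [make_split()].
#' @param path File path.
#' @return `write_split_json()` returns `path` invisibly;
#'   `read_split_json()` the restored plan.
#' @export
write_split_json <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(
    list(train = plan$train, val = plan$val, test = plan$test,
         folds = as.list(plan$folds)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = x$train, val = x$val, test = x$test,
                 folds = unlist(x$folds)),
            class = "split_plan")
}

#' Write a windowed dataset as CSV
#'
#' One row per window: `sow_id`, `start_index`, `label`, then `w` activity
#' columns `a1..aw`.
#'
#' @param windows Tibble from [make_windows()].
#' @param path File path.
#' @return `path`, invisibly (writer); the windows tibble (reader).
#' @export
write_windows_csv <- function(windows, path) {
  m <- do.call(rbind, windows$window)
  colnames(m) <- paste0("a", seq_len(ncol(m)))
  out <- cbind(windows[c("sow_id", "start_index", "end_index", "label")],
               as.data.frame(m))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  acols <- grep("^a[0-9]+$", names(df), value = TRUE)
  acols <- acols[order(as.integer(sub("^a", "", acols)))]
  m <- as.matrix(df[acols])
  tibble::tibble(
    sow_id = df$sow_id,
    start_index = df$start_index,
    end_index = df$end_index,
    label = df$label,
    window = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  )
}
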