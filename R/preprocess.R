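#' Calibrated HS-AFM topography movie
#'
#' Container for a stack of height-map frames (nm) with the calibration
#' needed downstream: pixel size (nm/px) and frame interval (s).
#'
#' @param frames list of numeric matrices (heights in nm), all the same
#'   shape.
#' @param pixel_size nm per pixel; > 0.
#' @param frame_interval frame interval delta-t in s; > 0.
#' @param timestamps optional frame times in s, strictly increasing;
#'   defaults to `(0:(n-1)) * frame_interval`.
#'
#' @return An object of class `topography_movie`.
#' @export
topography_movie <- function(frames, pixel_size, frame_interval,
                             timestamps = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, is.matrix, logical(1))))
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), logical(1))))
    stop("all frames must have the same shape")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (is.null(timestamps))
    timestamps <- (seq_along(frames) - 1) * frame_interval
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, timestamps = timestamps),
            class = "topography_movie")
}

#' @export
print.topography_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("topography_movie: %d frames of %d x %d px (%.3g nm/px, dt = %.3g s)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Isodata (intermeans) threshold
#'
#' The classic iterative intermeans threshold: starting from the image
#' mean, iterate `t <- (mean(px <= t) + mean(px > t)) / 2` until the
#' change is below `tol` (or `max_iter` is reached). The result is a fixed
#' point of the intermeans map and separates a bimodal height distribution
#' (e.g. membrane vs. protein cluster).
#'
#' @param frame numeric matrix or vector of heights.
#' @param tol convergence tolerance in the intensity unit (default 1e-6).
#' @param max_iter maximum iterations (default 100).
#'
#' @return The threshold (same unit as the input).
#' @export
isodata_threshold <- function(frame, tol = 1e-6, max_iter = 100L) {
  v <- as.numeric(frame)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2) stop("degenerate input: frame has < 2 distinct values")
  t0 <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (length(hi) == 0) { # threshold above max: step down
      t1 <- (mean(lo) + max(v)) / 2
    } else {
      t1 <- (mean(lo) + mean(hi)) / 2
    }
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Line-by-line background flattening of a topography frame
#'
#' Removes per-scan-line polynomial background (degree 0 or 1), the
#' standard AFM flattening step. The background fit per line uses only
#' pixels below the frame's isodata threshold (membrane/support pixels),
#' so protein features do not bias it; the median background level is
#' then set to zero. If a scan line is entirely foreground, the whole
#' line is used with a warning.
#'
#' @param frame numeric matrix of heights (rows = scan lines).
#' @param degree polynomial degree per line: 0 (offset) or 1 (offset +
#'   slope).
#'
#' @return The flattened frame (same shape).
#' @export
flatten_frame <- function(frame, degree = 1L) {
  stopifnot(is.matrix(frame), nrow(frame) >= 1, degree %in% c(0L, 1L))
  if (length(unique(as.numeric(frame))) < 2) {
    return(frame - stats::median(frame))
  }
  thr <- isodata_threshold(frame)
  bg <- frame <= thr
  out <- frame
  xs <- seq_len(ncol(frame))
  warned <- FALSE
  for (r in seq_len(nrow(frame))) {
    sel <- bg[r, ]
    if (sum(sel) < degree + 1) {
      sel <- rep(TRUE, ncol(frame))
      warned <- TRUE
    }
    if (degree == 0L) {
      out[r, ] <- frame[r, ] - mean(frame[r, sel])
    } else {
      fit <- stats::lm.fit(cbind(1, xs[sel]), frame[r, sel])
      out[r, ] <- frame[r, ] - (fit$coefficients[1] + fit$coefficients[2] * xs)
    }
  }
  if (warned)
    warning("scan line(s) entirely foreground: fell back to whole-line fit")
  # re-reference: median of background pixels at 0
  bg2 <- out <= isodata_threshold(out)
  out - stats::median(out[bg2])
}

#' Drift alignment of a topography movie
#'
#' Translates every frame to maximize cross-correlation with a running
#' reference (the previously aligned frame), the usual strategy for slow
#' shape change. Shifts are estimated to sub-pixel precision by parabolic
#' interpolation of the correlation peak and applied as integer-pixel
#' translations; the cumulative drift trajectory is returned.
#'
#' @param movie a [topography_movie()].
#' @param fill value for pixels shifted in from outside the field
#'   (default: frame median).
#'
#' @return A list: `movie` (aligned [topography_movie()]) and `drift`
#'   (data frame with per-frame cumulative `dy`, `dx` in px).
#' @export
align_frames <- function(movie, fill = NULL) {
  stopifnot(inherits(movie, "topography_movie"))
  nfr <- length(movie$frames)
  drift <- data.frame(frame = seq_len(nfr), dy = 0, dx = 0)
  if (nfr < 2) return(list(movie = movie, drift = drift))
  aligned <- movie$frames
  for (f in 2:nfr) {
    # reference is the previous *aligned* frame, so the measured shift is
    # already the total correction for this frame
    sh <- xcorr_shift(aligned[[f - 1]], movie$frames[[f]])
    drift$dy[f] <- -sh[1]; drift$dx[f] <- -sh[2]
    fl <- if (is.null(fill)) stats::median(movie$frames[[f]]) else fill
    aligned[[f]] <- mat_shift(movie$frames[[f]], round(sh[1]), round(sh[2]),
                              fill = fl)
  }
  out <- movie
  out$frames <- aligned
  list(movie = out, drift = drift)
}

#' Cluster mask stack from a topography movie
#'
#' Thresholds every frame with [isodata_threshold()], keeps the resulting
#' binary masks together with the per-frame thresholds, and (optionally)
#' applies the three-frame walking average and hole filling so that the
#' final masks contain no gap pixels.
#'
#' @param movie a [topography_movie()].
#' @param condition if `TRUE` (default) apply [walking_average()] and fill
#'   holes.
#'
#' @return An object of class `mask_stack`: list with `masks` (list of
#'   logical matrices), `thresholds` (numeric per frame), `pixel_size`,
#'   `frame_interval`.
#' @export
mask_stack <- function(movie, condition = TRUE) {
  stopifnot(inherits(movie, "topography_movie"))
  thr <- vapply(movie$frames, isodata_threshold, numeric(1))
  masks <- mapply(function(f, t) f > t, movie$frames, thr, SIMPLIFY = FALSE)
  ms <- structure(list(masks = masks, thresholds = thr,
                       pixel_size = movie$pixel_size,
                       frame_interval = movie$frame_interval),
                  class = "mask_stack")
  if (condition) ms <- walking_average(ms)
  ms
}

#' Three-frame walking average of a mask stack
#'
#' Majority vote over a sliding window of `window` consecutive frames: a
#' pixel survives in frame t if it is present in more than half of the
#' frames in the window centered on t. This removes single-frame
#' salt-noise pixels from the rough masks. At the stack ends the window
#' is clamped to the nearest full window inside the stack (shrinking only
#' when the stack itself is shorter than the window). Interior holes
#' ("gap pixels") are filled afterwards.
#'
#' @param masks a `mask_stack` (or plain list of logical matrices).
#' @param window odd window length, default 3.
#' @param fill fill enclosed holes afterwards (default `TRUE`).
#'
#' @return Same type as the input, with conditioned masks.
#' @export
walking_average <- function(masks, window = 3L, fill = TRUE) {
  is_stack <- inherits(masks, "mask_stack")
  ml <- if (is_stack) masks$masks else masks
  stopifnot(window %% 2 == 1, window >= 1)
  nfr <- length(ml)
  half <- window %/% 2
  out <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    lo <- max(1, min(f - half, nfr - window + 1))
    hi <- min(nfr, lo + window - 1)
    acc <- Reduce(`+`, lapply(ml[lo:hi], function(m) m * 1))
    out[[f]] <- acc > (hi - lo + 1) / 2
    if (fill) out[[f]] <- fill_holes(out[[f]])
  }
  if (is_stack) { masks$masks <- out; masks } else out
}

#' Three-class surface coverage (protein / lipid / support)
#'
#' Splits a frame into three height classes with two stacked isodata
#' thresholds — first support (mica) vs. the rest, then lipid membrane
#' vs. protein — and reports the pixel fraction of each class. Fractions
#' sum to one. If fewer than three levels are distinguishable the missing
#' class gets fraction 0 with a warning.
#'
#' @param frame numeric matrix of heights.
#' @param min_separation minimal separation (nm) between the two
#'   thresholds for the 3-class split to be accepted (default 0.2).
#'
#' @return Named numeric vector `c(protein=, lipid=, mica=)` plus
#'   attribute `thresholds`.
#' @export
surface_coverage <- function(frame, min_separation = 0.2) {
  v <- as.numeric(frame)
  if (length(unique(v)) < 2) {
    warning("frame has a single level: counted as lipid membrane")
    out <- c(protein = 0, lipid = 1, mica = 0)
    attr(out, "thresholds") <- c(NA_real_, NA_real_)
    return(out)
  }
  t1 <- isodata_threshold(v)                  # support vs. rest
  upper <- v[v > t1]
  t2 <- if (length(unique(upper)) >= 2) isodata_threshold(upper) else NA_real_
  if (is.na(t2) || t2 - t1 < min_separation) {
    warning("fewer than 3 distinguishable levels: lipid and protein merged")
    mica <- mean(v <= t1)
    out <- c(protein = 0, lipid = 1 - mica, mica = mica)
    attr(out, "thresholds") <- c(t1, NA_real_)
    return(out)
  }
  mica <- mean(v <= t1)
  lipid <- mean(v > t1 & v <= t2)
  protein <- mean(v > t2)
  out <- c(protein = protein, lipid = lipid, mica = mica)
  attr(out, "thresholds") <- c(t1, t2)
  out
}

#' Select isolated, stable cluster traces
#'
#' Tracks connected components across a conditioned mask stack by frame-
#' to-frame overlap and keeps only clusters that are isolated for the whole
#' observation: any trace whose component merges with another
#' (under-segmentation) or splits into several (over-segmentation), or
#' that touches the field border in any frame, is rejected. Accepted
#' traces span all frames.
#'
#' @param masks a `mask_stack`.
#' @param min_pixels components smaller than this are ignored as noise
#'   (default 9).
#'
#' @return A list of traces; each trace is a list of logical matrices (one
#'   mask per frame). Empty (with a warning) if nothing survives.
#' @export
select_isolated_clusters <- function(masks, min_pixels = 9L) {
  stopifnot(inherits(masks, "mask_stack"))
  ml <- masks$masks
  nfr <- length(ml)
  labs <- lapply(ml, label_components)
  comp_ids <- lapply(labs, function(L) setdiff(unique(as.vector(L)), 0L))
  # drop tiny components
  comp_ids <- lapply(seq_len(nfr), function(f)
    Filter(function(id) sum(labs[[f]] == id) >= min_pixels, comp_ids[[f]]))

  touches_border <- function(L, id) {
    any(L[1, ] == id) || any(L[nrow(L), ] == id) ||
      any(L[, 1] == id) || any(L[, ncol(L)] == id)
  }

  # seed traces with frame-1 components, follow by overlap
  traces <- list()
  for (id in comp_ids[[1]]) {
    cur <- labs[[1]] == id
    ok <- !touches_border(labs[[1]], id)
    trace <- list(cur)
    for (f in 2:nfr) {
      if (!ok) break
      over <- unique(labs[[f]][cur])
      over <- setdiff(over, 0L)
      over <- intersect(over, comp_ids[[f]])
      if (length(over) != 1L) { ok <- FALSE; break }   # lost or split
      # merge check: does any other frame-(f-1) region also map to this id?
      nxt <- labs[[f]] == over
      back <- setdiff(unique(labs[[f - 1]][nxt]), 0L)
      back <- intersect(back, comp_ids[[f - 1]])
      if (length(back) != 1L) { ok <- FALSE; break }   # merge
      if (touches_border(labs[[f]], over)) { ok <- FALSE; break }
      trace[[f]] <- nxt
      cur <- nxt
    }
    if (ok && length(trace) == nfr) traces[[length(traces) + 1]] <- trace
  }
  if (length(traces) == 0L)
    warning("no isolated cluster trace survived merge/split/border filtering")
  traces
}
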