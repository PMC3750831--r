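# Retrospective respiratory gating: silhouette mask, AP/MP inter-frame
# statistics, cycle-curve construction and selection of the two stages
# (expand-to-maximum, contract-to-minimum) at every angle.

as_frame_array <- function(frames) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3) stop("frames must be a stack (N x M x F)")
  frames
}

#' Silhouette mask of a frame stack
#'
#' Binary mask of the pixels where inter-frame motion occurs, built as the
#' pixels whose temporal standard deviation across the stack exceeds the
#' given quantile of all per-pixel standard deviations. The AP/MP gating
#' statistics are computed over this mask.
#'
#' @param frames `N x M x F` array (or list of matrices), `F >= 2`.
#' @param threshold_quantile Quantile in `[0, 1)` of the per-pixel temporal
#'   standard deviations used as the threshold (default 0.8). `0` keeps
#'   every pixel with nonzero variance.
#' @return Logical matrix of class `silhouette_mask` with attribute
#'   `n_mask`.
#' @export
compute_silhouette_mask <- function(frames, threshold_quantile = 0.8) {
  frames <- as_frame_array(frames)
  if (dim(frames)[3] < 2) stop("need at least 2 frames")
  mu <- rowMeans(frames, dims = 2)
  mu2 <- rowMeans(frames^2, dims = 2)
  v <- pmax(mu2 - mu^2, 0)
  sds <- sqrt(v)
  tol <- 1e-10 * max(sds)
  if (max(sds) == 0 || all(sds <= tol))
    stop("empty silhouette mask: all frames are identical (no motion)")
  thr <- stats::quantile(sds, threshold_quantile, names = FALSE)
  mask <- sds > pmax(thr, tol)
  if (!any(mask))
    stop("empty silhouette mask: threshold quantile leaves no pixels")
  structure(mask, n_mask = sum(mask), class = c("silhouette_mask", "matrix"))
}

#' AP and MP gating statistics of a frame pair
#'
#' The two respiratory statistics of a pair of frames over a silhouette
#' mask: AP is the mean and MP the maximum of the absolute intensity
#' difference `|I1 - I2|` over the mask pixels. The absolute value makes
#' both non-negative and symmetric in the two frames (without it,
#' symmetric motion cancels in the mean and the cycle curve collapses).
#'
#' @param frame1,frame2 Intensity images of identical shape.
#' @param mask Logical matrix (e.g. from [compute_silhouette_mask()]) with
#'   at least one `TRUE` pixel.
#' @return Named numeric vector `c(ap = ..., mp = ...)`; always `mp >= ap`.
#' @export
compute_ap_mp <- function(frame1, frame2, mask) {
  if (!all(dim(frame1) == dim(frame2)))
    stop("frames have different shapes")
  if (!all(dim(frame1) == dim(mask)))
    stop("mask shape does not match the frames")
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  d <- abs(frame1[m] - frame2[m])
  c(ap = mean(d), mp = max(d))
}

# 3-point moving average on interior points; the two end values are kept
# raw so extrema adjacent to the curve ends are not smeared away
smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- (c(v[1], v[-n]) + v + c(v[-1], v[n])) / 3
  out[c(1, n)] <- v[c(1, n)]
  out
}

# earliest index of each interior local minimum; plateaus collapse to their
# first element, and a descending plateau that runs into the end of the
# curve counts (the turning point lies inside it)
local_minima <- function(v) {
  n <- length(v)
  mins <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] < v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j == n || v[j + 1L] > v[i]) mins <- c(mins, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  mins
}

# radial spread of the deviation-from-background image; larger when the
# thorax is expanded, used to tell the two stages apart
frame_spread <- function(frame) {
  w <- abs(frame - stats::median(frame))
  if (sum(w) == 0) return(0)
  N <- nrow(frame); M <- ncol(frame)
  cr <- (N - 1) / 2; ccol <- (M - 1) / 2
  r2 <- outer(((0:(N - 1)) - cr)^2, ((0:(M - 1)) - ccol)^2, `+`)
  sum(w * r2) / sum(w)
}

#' Extract respiratory phases from one angle's frame stack
#'
#' Builds the AP (and MP) respiratory cycle curve over the stack, finds its
#' turning points, and labels the frames at the turning points as the two
#' respiratory stages. Consecutive frames move fastest mid-cycle and pause
#' at the extremes, so stage frames sit at local minima of the smoothed AP
#' curve; the two stages are told apart by the radial spread of each
#' turning frame (expanded thorax = larger spread).
#'
#' @param frames `N x M x F` array (or list), `F >= 3`.
#' @param mask Silhouette mask; computed via [compute_silhouette_mask()]
#'   when `NULL`.
#' @param reference_frame_policy `"rolling"` (default) pairs consecutive
#'   frames `(f, f+1)`; `"first"` pairs every frame with frame 1.
#' @return An object of class `respiratory_signal`: list with `ap`, `mp`
#'   (per pair), `ap_smooth`, `labels` (per frame:
#'   `"max_expansion"`, `"min_contraction"` or `"transitional"`), `turning`
#'   (data frame of turning frames) and `n_frames`.
#' @export
extract_phases <- function(frames, mask = NULL,
                           reference_frame_policy = c("rolling", "first")) {
  reference_frame_policy <- match.arg(reference_frame_policy)
  frames <- as_frame_array(frames)
  Fn <- dim(frames)[3]
  if (Fn < 3) stop("need at least 3 frames")
  if (is.null(mask)) mask <- compute_silhouette_mask(frames)
  ref <- function(f) if (reference_frame_policy == "rolling") f else 1L
  apmp <- vapply(seq_len(Fn - 1L), function(f)
    compute_ap_mp(frames[, , ref(f)], frames[, , f + 1L], mask),
    numeric(2))
  ap <- apmp[1, ]; mp <- apmp[2, ]
  aps <- smooth3(ap)
  if (max(aps) - min(aps) <= 1e-12 * max(aps, 1e-300))
    stop("no respiratory cycle: the AP curve is flat")
  pairs <- local_minima(aps)
  if (!length(pairs))
    stop("no respiratory cycle: the AP curve has no interior turning point")
  # an AP minimum at pair j means the motion pauses between frames j and
  # j + 1; the side whose neighbouring pair moves less holds the extreme
  # frame (ties go to the earlier frame)
  aval <- function(k) if (k >= 1 && k <= length(aps)) aps[k] else Inf
  turn <- vapply(pairs, function(j) {
    if (aval(j - 1L) <= aval(j + 1L)) j else min(j + 1L, Fn)
  }, integer(1))
  turn <- sort(unique(turn))
  spread <- vapply(turn, function(f) frame_spread(frames[, , f]),
                   numeric(1))
  mid <- (max(spread) + min(spread)) / 2
  lab <- ifelse(spread > mid, "max_expansion", "min_contraction")
  labels <- rep("transitional", Fn)
  labels[turn] <- lab
  structure(list(ap = ap, mp = mp, ap_smooth = aps, labels = labels,
                 turning = data.frame(frame = turn, label = lab,
                                      spread = spread),
                 n_frames = Fn),
            class = "respiratory_signal")
}

#' @export
print.respiratory_signal <- function(x, ...) {
  cat(sprintf("respiratory signal over %d frames: %d turning frame(s)\n",
              x$n_frames, nrow(x$turning)))
  print(x$turning)
  invisible(x)
}

#' Select one frame per angle for a respiratory stage
#'
#' Given the per-angle respiratory signals, returns exactly one frame index
#' per angle for the requested stage. When a stage occurs in several cycles
#' the (lower) median-index representative is taken.
#'
#' @param signals List of [extract_phases()] results, one per angle.
#' @param stage `"max_expansion"` or `"min_contraction"`.
#' @return Integer vector of frame indices, one per angle.
#' @export
select_stage_frames <- function(signals,
                                stage = c("max_expansion",
                                          "min_contraction")) {
  stage <- match.arg(stage)
  vapply(seq_along(signals), function(a) {
    idx <- which(signals[[a]]$labels == stage)
    if (!length(idx))
      stop(sprintf("gating coverage error: no %s frame at angle %d",
                   stage, a))
    lower_median(idx)
  }, integer(1))
}
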