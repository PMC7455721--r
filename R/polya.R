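#' Calibrate gel migration position against a size marker
#'
#' Log-linear interpolation of fragment length against migration position:
#' within the anchor range, log(length) is interpolated linearly in position
#' (so the midpoint of two anchors maps to the geometric mean of their
#' lengths); outside it, the flanking segment is extended and the result is
#' flagged as extrapolated.
#'
#' @param marker data frame with columns \code{length_nt} and \code{position};
#'   at least two anchors, strictly monotone (longer fragments migrate less
#'   far, i.e. smaller positions).
#' @return object of class \code{gel_calibration}.
#' @export
calibrate <- function(marker) {
  need <- c("length_nt", "position")
  if (!all(need %in% names(marker))) {
    stop("marker must have columns length_nt and position")
  }
  if (nrow(marker) < 2) stop("need at least two marker anchors")
  m <- marker[order(marker$position), ]
  if (any(diff(m$position) <= 0) || any(diff(m$length_nt) >= 0)) {
    stop("marker must be strictly monotone: length decreasing with position")
  }
  structure(list(position = m$position, log_length = log(m$length_nt)),
            class = "gel_calibration")
}

# linear interpolation with linear extension beyond the anchor range
interp_extend <- function(x, y, xout) {
  n <- length(x)
  yout <- stats::approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  sl1 <- (y[2] - y[1]) / (x[2] - x[1])
  sln <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  yout[lo] <- y[1] + sl1 * (xout[lo] - x[1])
  yout[hi] <- y[n] + sln * (xout[hi] - x[n])
  list(y = yout, extrapolated = lo | hi)
}

#' Fragment length at a migration position
#'
#' @param cal a \code{gel_calibration}.
#' @param position migration positions.
#' @return lengths in nucleotides, with attribute \code{extrapolated}
#'   (logical) flagging queries outside the anchor range.
#' @export
predict_length <- function(cal, position) {
  stopifnot(inherits(cal, "gel_calibration"))
  r <- interp_extend(cal$position, cal$log_length, position)
  structure(exp(r$y), extrapolated = r$extrapolated)
}

#' Migration position of a fragment length
#'
#' Inverse of \code{\link{predict_length}}.
#'
#' @param cal a \code{gel_calibration}.
#' @param length_nt fragment lengths in nucleotides.
#' @return migration positions, with attribute \code{extrapolated}.
#' @export
predict_position <- function(cal, length_nt) {
  stopifnot(inherits(cal, "gel_calibration"))
  # log(length) decreases with position; invert on reversed axes
  r <- interp_extend(rev(cal$log_length), rev(cal$position), log(length_nt))
  structure(r$y, extrapolated = r$extrapolated)
}

#' Optional rolling-minimum background subtraction
#'
#' @param profile a \code{densitogram}.
#' @param window rolling window in grid points (default 51).
#' @return the background-subtracted \code{densitogram}.
#' @export
subtract_background <- function(profile, window = 51) {
  y <- profile$intensity
  n <- length(y)
  h <- floor(window / 2)
  base <- vapply(seq_len(n),
                 function(i) min(y[max(1, i - h):min(n, i + h)]), 0)
  profile$intensity <- pmax(y - base, 0)
  profile
}

#' Fraction of poly(A) signal above a tail-length threshold
#'
#' Trapezoidal mass of the lane profile at tail lengths above the threshold,
#' divided by the total mass. Longer tails migrate to smaller positions, so
#' this integrates the profile up to the threshold's migration position (with
#' linear interpolation at the boundary).
#'
#' @param profile a \code{densitogram} (fields \code{position},
#'   \code{intensity}, \code{marker}).
#' @param threshold_nt tail-length threshold in nucleotides (default 50).
#' @param background \code{"none"} (default) or \code{"rolling_min"}.
#' @return fraction in \[0, 1\].
#' @export
fraction_above <- function(profile, threshold_nt = 50,
                           background = c("none", "rolling_min")) {
  background <- match.arg(background)
  if (background == "rolling_min") profile <- subtract_background(profile)
  x <- profile$position
  y <- profile$intensity
  if (any(y < 0)) stop("intensities must be non-negative")
  total <- trapezoid(x, y)
  if (total <= 0) stop("profile has zero total intensity")
  cal <- calibrate(profile$marker)
  p_thr <- as.numeric(predict_position(cal, threshold_nt))
  if (p_thr <= x[1]) return(0)
  if (p_thr >= x[length(x)]) return(1)
  below <- x <= p_thr
  xi <- c(x[below], p_thr)
  yi <- c(y[below], stats::approx(x, y, p_thr)$y)
  trapezoid(xi, yi) / total
}
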