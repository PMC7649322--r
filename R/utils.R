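# Low-level array helpers shared by every stage of the pipeline.
# All 2-D fields are matrices indexed [row = y (down), col = x (right)].

#' Same-size 2-D correlation with zero padding
#'
#' Computes the filter response `r[y, x] = sum_{i,j} k[i, j] * m[y + i - c,
#' x + j - c]` (cross-correlation, kernel centred at `c`), treating pixels
#' outside the image as zero. Implemented by FFT for speed; exact up to
#' floating-point rounding.
#'
#' @param m numeric matrix (image or activity field).
#' @param k numeric matrix with odd dimensions (the kernel).
#' @return matrix of the same dimensions as `m`.
#' @keywords internal
filter2_same <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  h <- nrow(m); w <- ncol(m)
  # correlation = convolution with the kernel rotated 180 degrees
  kr <- k[kh:1, kw:1, drop = FALSE]
  ph <- h + kh - 1L; pw <- w + kw - 1L
  mp <- matrix(0, ph, pw); mp[1:h, 1:w] <- m
  kp <- matrix(0, ph, pw); kp[1:kh, 1:kw] <- kr
  full <- Re(stats::fft(stats::fft(mp) * stats::fft(kp), inverse = TRUE)) / (ph * pw)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  full[(rh + 1L):(rh + h), (rw + 1L):(rw + w), drop = FALSE]
}

#' Zero-padded box sum over a (2r+1) x (2r+1) window
#'
#' Running-sum (integral image) implementation; exact, O(H*W).
#'
#' @param m numeric matrix.
#' @param r integer window radius.
#' @return matrix of window sums, same dimensions as `m`.
#' @keywords internal
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  # pad with r zeros on each side, then 2-D cumulative sums
  p <- matrix(0, h + 2L * r, w + 2L * r)
  p[(r + 1L):(r + h), (r + 1L):(r + w)] <- m
  cs <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed after second apply
  cs <- t(cs)
  # prepend a zero row/col so that S[i, j] = sum of p[1:i, 1:j]
  S <- matrix(0, nrow(cs) + 1L, ncol(cs) + 1L)
  S[-1L, -1L] <- cs
  d <- 2L * r + 1L
  i0 <- 1L:h; j0 <- 1L:w   # top-left of each window in padded coords
  S[i0 + d, j0 + d, drop = FALSE] - S[i0, j0 + d, drop = FALSE] -
    S[i0 + d, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
}

#' Apply `box_sum` to every direction channel of an H x W x N array
#' @keywords internal
box_sum_channels <- function(a, r) {
  out <- a
  for (n in seq_len(dim(a)[3L])) out[, , n] <- box_sum(a[, , n], r)
  out
}

# Direction conventions ------------------------------------------------------

#' Direction channel angles in degrees (counter-clockwise, 0 = rightward)
#' @param N number of channels.
#' @keywords internal
dir_angles <- function(N = 8L) (seq_len(N) - 1L) * (360 / N)

#' Unit displacement (dx right, dy down) for a direction angle in degrees
#'
#' Image rows grow downward, so upward motion (90 degrees) has dy < 0.
#' @keywords internal
dir_vector <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(dx = cos(a), dy = -sin(a))
}

#' Clip values into a range
#' @keywords internal
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
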