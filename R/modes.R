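#' Detect expression modes in a count distribution
#'
#' Counts the modes (strict local maxima) of a smoothed probability mass
#' function and partitions the mass between them. The PMF is smoothed with
#' a centred moving average; a local maximum only counts as a mode when
#' its prominence (peak height minus the highest valley separating it
#' from a taller peak) exceeds `prominence` times the height of the
#' tallest smoothed bin -- a relative criterion, so broad modes of wide
#' count distributions are not penalised for spreading their mass over
#' many bins. Mode weights
#' are the mass on each side of the minimum-density valley between
#' adjacent modes and always sum to 1. On a flat (plateau) maximum the
#' leftmost bin is reported as the mode location.
#'
#' @param dist a [stationary_distribution()] or non-negative numeric
#'   vector over counts `0:(n-1)`.
#' @param smoothing_window odd width of the moving-average smoother in
#'   bins (default 5; 1 disables smoothing).
#' @param prominence minimum peak prominence as a fraction of the
#'   tallest smoothed bin (default 0.05).
#' @return List with `n_modes`, `locations` (counts), `weights`
#'   (summing to 1), and `smoothed` (the smoothed PMF).
#' @examples
#' detect_modes(dpois(0:120, 50))$n_modes                      # 1
#' m <- detect_modes(0.5 * dpois(0:160, 5) + 0.5 * dpois(0:160, 80))
#' m$n_modes                                                   # 2
#' @export
detect_modes <- function(dist, smoothing_window = 5, prominence = 0.05) {
  p <- as.numeric(dist)
  if (length(p) == 0 || sum(p) <= 0)
    stop("empty distribution", call. = FALSE)
  p <- p / sum(p)
  w <- as.integer(smoothing_window)
  if (w < 1 || w %% 2 == 0)
    stop("smoothing_window must be a positive odd integer", call. = FALSE)
  if (w > 1 && length(p) > w) {
    k <- rep(1 / w, w)
    sm <- as.numeric(stats::filter(p, k, sides = 2))
    # shrink the window near the edges instead of dropping them
    half <- (w - 1L) %/% 2L
    n <- length(p)
    for (i in which(is.na(sm))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      sm[i] <- mean(p[lo:hi])
    }
  } else sm <- p
  n <- length(sm)

  # strict local maxima with leftmost-of-plateau tie-break
  is_peak <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sm[j + 1L] == sm[i]) j <- j + 1L  # plateau [i, j]
    left_ok <- i == 1L || sm[i - 1L] < sm[i]
    right_ok <- j == n || sm[j + 1L] < sm[i]
    if (left_ok && right_ok && sm[i] > 0) is_peak[i] <- TRUE
    i <- j + 1L
  }
  peaks <- which(is_peak)
  if (length(peaks) == 0) peaks <- which.max(sm)

  # prominence: drop to the highest separating valley toward a taller peak
  prom <- vapply(peaks, function(pk) {
    taller <- peaks[sm[peaks] > sm[pk]]
    if (length(taller) == 0) return(sm[pk])  # global max: full height
    valleys <- vapply(taller, function(tp) {
      rng <- if (tp < pk) tp:pk else pk:tp
      min(sm[rng])
    }, numeric(1))
    sm[pk] - max(valleys)
  }, numeric(1))
  keep <- peaks[prom >= prominence * max(sm)]
  if (length(keep) == 0) keep <- peaks[which.max(prom)]
  keep <- sort(keep)

  # split mass at the minimum-density valley between adjacent kept modes
  cuts <- integer(0)
  if (length(keep) > 1) {
    for (m in seq_len(length(keep) - 1L)) {
      rng <- keep[m]:keep[m + 1L]
      cuts <- c(cuts, rng[which.min(sm[rng])])
    }
  }
  bounds <- c(0L, cuts, n)
  weights <- vapply(seq_len(length(keep)), function(m)
    sum(p[(bounds[m] + 1L):bounds[m + 1L]]), numeric(1))
  weights <- weights / sum(weights)

  list(n_modes = length(keep), locations = keep - 1L, weights = weights,
       smoothed = sm)
}
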