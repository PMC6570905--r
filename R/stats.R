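#' Fano factor of a sample
#'
#' Variance over mean, using the population (1/n) variance so that a
#' distribution-level definition applies to samples. Equals 1 for Poisson
#' counts; substantially larger values flag super-Poissonian noise such as
#' a mixture of a low- and a high-expression population ("two Poisson
#' processes added together will not lead to a Poisson distribution").
#' Note the Fano factor is not scale-invariant: `fano_factor(a * x) =
#' a * fano_factor(x)`, so fluorescence units proportional to molecule
#' number need not give 1 even for Poisson counts; the coefficient of
#' variation is the scale-free alternative.
#'
#' @param values numeric vector, at least 2 values, positive mean.
#' @return Fano factor `var(x) / mean(x)` (population variance).
#' @examples
#' fano_factor(rpois(1e4, 100))  # about 1
#' @export
fano_factor <- function(values) {
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need >= 2 finite values", call. = FALSE)
  m <- mean(values)
  if (m <= 0)
    stop("Fano factor undefined for mean <= 0", call. = FALSE)
  pop_var(values) / m
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Inhibition probability and inhibition curve
#'
#' The inhibition probability at a threshold is the fraction of cells
#' whose fluorescence lies strictly below it — the fraction of the
#' population scored as repressed. Evaluated on a grid of thresholds it
#' is the empirical CDF of the population (the "inhibition curve").
#'
#' @param values per-cell fluorescence values (non-empty).
#' @param threshold finite threshold(s).
#' @return Fraction(s) in `[0, 1]`, one per threshold.
#' @examples
#' inhibition_probability(c(1, 2, 3, 4), 2.5)  # 0.5
#' @export
inhibition_probability <- function(values, threshold) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(threshold)))
    stop("threshold must be finite", call. = FALSE)
  vapply(threshold, function(th) mean(values < th), numeric(1))
}

#' Population snapshot of per-cell fluorescence
#'
#' One steady-state sample of per-cell mean fluorescence values (linear
#' scale) at a single inducer concentration. A warning is emitted below
#' `min_cells` (microscopy practice in this assay collects at least ~10^3
#' cells per condition).
#'
#' @param values per-cell mean fluorescence, all > 0.
#' @param atc_ng_per_ml inducer concentration tag (ng/mL).
#' @param min_cells sample-size warning threshold (default 1000).
#' @return Object of class `population_snapshot`.
#' @export
population_snapshot <- function(values, atc_ng_per_ml = NA_real_,
                                min_cells = 1000) {
  if (length(values) < 1 || any(!is.finite(values)) || any(values <= 0))
    stop("snapshot values must be positive and finite", call. = FALSE)
  if (length(values) < min_cells)
    warning(sprintf("snapshot has %d cells (< %d)", length(values),
                    min_cells), call. = FALSE)
  structure(list(values = as.numeric(values), atc = atc_ng_per_ml,
                 n = length(values)),
            class = "population_snapshot")
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf("population_snapshot: %d cells at aTc = %s ng/mL, mean %.1f\n",
              x$n, format(x$atc), mean(x$values)))
  invisible(x)
}

#' Summary statistics of one expression snapshot
#'
#' Assembles the noise statistics used to characterise an expression
#' distribution: mean, population variance, Fano factor, CV, inhibition
#' probability at a threshold, and mode count/weights. Mode statistics are
#' computed with [detect_modes()] on a histogram of log10 fluorescence
#' (Freedman-Diaconis bin width, at least `min_bins` bins).
#'
#' @param snap a [population_snapshot()] (or bare numeric vector).
#' @param threshold inhibition threshold on the linear fluorescence scale;
#'   `NULL` skips the inhibition statistic (reported as `NA`).
#' @param min_bins minimum number of histogram bins for mode detection.
#' @param smoothing_window,prominence passed to [detect_modes()]; the
#'   defaults are stricter than for exact distributions because sampled
#'   histograms carry bin noise.
#' @return List of class `summary_stats` with fields `mean`, `var`,
#'   `fano`, `cv`, `inhibition_p`, `threshold`, `n_modes`, `mode_weights`,
#'   `mode_locations` (log10 fluorescence at histogram bin centres), `n`.
#' @export
snapshot_summary <- function(snap, threshold = NULL, min_bins = 30,
                             smoothing_window = 7, prominence = 0.15) {
  if (!inherits(snap, "population_snapshot"))
    snap <- population_snapshot(snap, min_cells = 1)
  x <- snap$values
  m <- mean(x)
  v <- pop_var(x)
  lx <- log10(x)
  if (length(x) >= 2 && v > 0) {
    # Freedman-Diaconis on the log10 scale, floored at min_bins
    iqr <- diff(quantile(lx, c(0.25, 0.75), names = FALSE))
    h <- 2 * iqr / length(lx)^(1 / 3)
    nb <- if (h > 0) ceiling(diff(range(lx)) / h) else min_bins
    nb <- max(nb, min_bins)
    br <- seq(min(lx), max(lx), length.out = nb + 1L)
    cnt <- tabulate(findInterval(lx, br, rightmost.closed = TRUE), nb)
    modes <- detect_modes(cnt, smoothing_window = smoothing_window,
                          prominence = prominence)
    centers <- (br[-1] + br[-length(br)]) / 2
    mode_loc <- centers[modes$locations + 1L]
  } else {
    modes <- list(n_modes = 1L, weights = 1)
    mode_loc <- lx[1]
  }
  structure(list(
    mean = m, var = v, fano = if (m > 0) v / m else NA_real_,
    cv = if (m > 0) sqrt(v) / m else NA_real_,
    inhibition_p = if (is.null(threshold)) NA_real_
                   else inhibition_probability(x, threshold),
    threshold = if (is.null(threshold)) NA_real_ else threshold,
    n_modes = modes$n_modes, mode_weights = modes$weights,
    mode_locations = mode_loc, n = snap$n, atc = snap$atc
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "summary_stats: n = %d, mean = %.3g, Fano = %.3g, CV = %.3g, %d mode(s)\n",
    x$n, x$mean, x$fano, x$cv, x$n_modes))
  invisible(x)
}

#' Default inhibition threshold from the bimodal condition
#'
#' The inhibition threshold is not a universal constant; by default it is
#' placed at the minimum-density valley between the two modes of the
#' log10-fluorescence histogram at the highest inducer concentration in a
#' run (where the population is bimodal), and reported alongside every
#' statistic so it can be overridden.
#'
#' @param values per-cell fluorescence at the reference (highest-inducer)
#'   condition.
#' @param min_bins,smoothing_window,prominence as in [snapshot_summary()].
#' @return Threshold on the linear fluorescence scale; falls back to the
#'   population median when the reference distribution is unimodal.
#' @export
valley_threshold <- function(values, min_bins = 30, smoothing_window = 7,
                             prominence = 0.15) {
  lx <- log10(values)
  iqr <- diff(quantile(lx, c(0.25, 0.75), names = FALSE))
  h <- 2 * iqr / length(lx)^(1 / 3)
  nb <- max(if (h > 0) ceiling(diff(range(lx)) / h) else min_bins, min_bins)
  br <- seq(min(lx), max(lx), length.out = nb + 1L)
  cnt <- tabulate(findInterval(lx, br, rightmost.closed = TRUE), nb)
  modes <- detect_modes(cnt, smoothing_window = smoothing_window,
                        prominence = prominence)
  if (modes$n_modes < 2) return(10^median(lx))
  sm <- modes$smoothed
  pk <- modes$locations + 1L
  rng <- pk[1]:pk[2]
  centers <- (br[-1] + br[-length(br)]) / 2
  10^centers[rng[which.min(sm[rng])]]
}

#' Read / write snapshot tables
#'
#' Snapshot TSV dialect: columns `cell_id`, `fluorescence`,
#' `aTc_ng_per_ml`. `read_snapshots()` returns one
#' [population_snapshot()] per concentration.
#'
#' @param path TSV file path.
#' @param min_cells forwarded to [population_snapshot()].
#' @return Named list of snapshots (names = aTc levels).
#' @export
read_snapshots <- function(path, min_cells = 1000) {
  d <- read.delim(path, sep = "\t")
  need <- c("cell_id", "fluorescence", "aTc_ng_per_ml")
  if (!all(need %in% names(d)))
    stop("snapshot table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  by_level <- split(d, d$aTc_ng_per_ml)
  lapply(by_level, function(g)
    population_snapshot(g$fluorescence, unique(g$aTc_ng_per_ml),
                        min_cells = min_cells))
}

#' @rdname read_snapshots
#' @param snapshots named list of [population_snapshot()]s.
#' @export
write_snapshots <- function(snapshots, path) {
  rows <- lapply(snapshots, function(s)
    data.frame(cell_id = sprintf("c%06d", seq_along(s$values)),
               fluorescence = s$values, aTc_ng_per_ml = s$atc))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Per-concentration statistics table
#'
#' Applies [snapshot_summary()] to each snapshot of a run and returns the
#' `stats.tsv` table: one row per inducer concentration with the Fano
#' factor, CV, inhibition probability and mode statistics. When
#' `threshold` is `NULL` it is derived with [valley_threshold()] from the
#' highest-concentration snapshot.
#'
#' @param snapshots named list of [population_snapshot()]s.
#' @param threshold inhibition threshold (linear scale) or `NULL`.
#' @return data.frame with columns `aTc_ng_per_ml`, `n_cells`, `mean`,
#'   `var`, `fano`, `cv`, `inhibition_p`, `threshold_used`, `n_modes`,
#'   `w_low`, `w_high`.
#' @export
snapshot_stats_table <- function(snapshots, threshold = NULL) {
  stopifnot(length(snapshots) > 0)
  atc <- vapply(snapshots, function(s) as.numeric(s$atc), numeric(1))
  if (is.null(threshold)) {
    ref <- snapshots[[which.max(atc)]]
    threshold <- valley_threshold(ref$values)
  }
  rows <- lapply(snapshots, function(s) {
    st <- snapshot_summary(s, threshold = threshold)
    data.frame(aTc_ng_per_ml = as.numeric(s$atc), n_cells = st$n,
               mean = st$mean, var = st$var, fano = st$fano, cv = st$cv,
               inhibition_p = st$inhibition_p, threshold_used = threshold,
               n_modes = st$n_modes,
               w_low = st$mode_weights[1],
               w_high = if (st$n_modes > 1)
                 st$mode_weights[st$n_modes] else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$aTc_ng_per_ml), , drop = FALSE]
}
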