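# Binned AT%-versus-recruitment relationship, its slope, and peak counts
# by recruitment range.

#' Binned AT content versus recruitment curve
#'
#' Recruitment (fold enrichment) is divided into `n_bins` ranges (equal
#' width by default, quantile bins optionally); per bin the mean
#' recruitment, mean summit-window AT% and peak count are reported, and an
#' ordinary least-squares fit of bin-mean AT fraction on bin-mean
#' recruitment over the non-empty bins gives the headline slope. Because
#' the field sometimes quotes this relationship per bin index rather than
#' per fold-enrichment unit, both slope variants are emitted; the
#' peak-level Pearson correlation is reported separately.
#'
#' @param peakset A [peak_set()] with at least 2 distinct recruitment
#'   values.
#' @param genome A [genome_sequence()].
#' @param n_bins Number of recruitment ranges (default 20).
#' @param halfwidth Summit-window halfwidth (default 49).
#' @param binning `"width"` (equal-width ranges, default) or `"quantile"`.
#' @return List of class `at_recruitment_curve`: `bins` (data.frame `bin`,
#'   `lo`, `hi`, `n`, `mean_recruitment`, `mean_at_pct`), `fit` (list
#'   `slope_at_frac_per_fc`, `slope_at_pct_per_fc`, `slope_at_pct_per_bin`,
#'   `intercept_at_pct`, `pearson_r_bins`, `pearson_r_peaks`,
#'   `n_bins_used`), and `peaks` (per-peak `name`, `recruitment`,
#'   `at_frac`). Empty bins are flagged (`n = 0`) and excluded from the
#'   fit; bin counts sum to the total number of peaks.
#' @export
bin_at_vs_recruitment <- function(peakset, genome, n_bins = 20L,
                                  halfwidth = 49L,
                                  binning = c("width", "quantile")) {
  binning <- match.arg(binning)
  if (!is_count(n_bins) || n_bins < 2) stop_fmt("n_bins must be >= 2")
  p <- peakset$peaks
  if (nrow(p) < 2L) stop_fmt("need at least 2 peaks")
  r <- p$recruitment
  if (diff(range(r)) == 0)
    stop_fmt("all recruitment values identical; cannot bin")
  win <- extract_summit_windows(peakset, genome, halfwidth)
  at <- rep(NA_real_, nrow(p))
  at[!win$truncated] <- at_fraction(win$sequence[!win$truncated])
  edges <- if (binning == "width") {
    seq(min(r), max(r), length.out = n_bins + 1L)
  } else {
    unique(stats::quantile(r, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE))
  }
  idx <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1L
  bins <- data.frame(
    bin = seq_len(nb), lo = edges[-length(edges)], hi = edges[-1L],
    n = tabulate(idx, nb),
    mean_recruitment = vapply(seq_len(nb), function(b)
      if (any(idx == b)) mean(r[idx == b]) else NA_real_, numeric(1)),
    mean_at_pct = vapply(seq_len(nb), function(b)
      if (any(idx == b & !is.na(at)))
        100 * mean(at[idx == b], na.rm = TRUE) else NA_real_, numeric(1)))
  use <- bins$n > 0 & !is.na(bins$mean_at_pct)
  if (sum(use) < 2L) stop_fmt("fewer than 2 usable bins for the fit")
  fit_fc <- stats::lm(mean_at_pct ~ mean_recruitment, data = bins[use, ])
  fit_bin <- stats::lm(mean_at_pct ~ bin, data = bins[use, ])
  co <- stats::coef(fit_fc)
  pk_ok <- !is.na(at)
  fit <- list(
    slope_at_frac_per_fc = unname(co[2]) / 100,
    slope_at_pct_per_fc = unname(co[2]),
    slope_at_pct_per_bin = unname(stats::coef(fit_bin)[2]),
    intercept_at_pct = unname(co[1]),
    pearson_r_bins = if (stats::sd(bins$mean_at_pct[use]) > 0)
      stats::cor(bins$mean_recruitment[use], bins$mean_at_pct[use])
    else NA_real_,
    pearson_r_peaks = if (sum(pk_ok) >= 3 && stats::sd(at[pk_ok]) > 0)
      stats::cor(r[pk_ok], at[pk_ok]) else NA_real_,
    n_bins_used = sum(use))
  structure(list(bins = bins, fit = fit,
                 peaks = data.frame(name = p$name, recruitment = r,
                                    at_frac = at, stringsAsFactors = FALSE),
                 edges = edges, binning = binning),
            class = "at_recruitment_curve")
}

#' @export
print.at_recruitment_curve <- function(x, ...) {
  cat(sprintf(
    "AT-recruitment curve: %d peaks in %d bins (%d used)\n  slope %.4g AT%% per fold-enrichment unit (r_bins = %.3f)\n",
    sum(x$bins$n), nrow(x$bins), x$fit$n_bins_used,
    x$fit$slope_at_pct_per_fc, x$fit$pearson_r_bins))
  invisible(x)
}

#' Peak counts by recruitment range
#'
#' Tabulates the curve's recruitment ranges and adds a low-recruitment
#' aggregate over a configurable fold-enrichment span (default Fc 1-6).
#'
#' @param curve An [bin_at_vs_recruitment()] result.
#' @param low_range Length-2 numeric, the inclusive fold-enrichment span
#'   counted as "low recruitment".
#' @return data.frame (`range`, `lo`, `hi`, `count`, `fraction`) with
#'   attributes `low_count`, `low_fraction`, `low_range`; fractions sum
#'   to 1.
#' @export
count_by_range <- function(curve, low_range = c(1, 6)) {
  stopifnot(inherits(curve, "at_recruitment_curve"))
  b <- curve$bins
  total <- sum(b$n)
  out <- data.frame(range = sprintf("[%.3g,%.3g%s", b$lo, b$hi,
                                    ifelse(b$bin == nrow(b), "]", ")")),
                    lo = b$lo, hi = b$hi, count = b$n,
                    fraction = b$n / total, stringsAsFactors = FALSE)
  r <- curve$peaks$recruitment
  low <- sum(r >= low_range[1] & r <= low_range[2])
  attr(out, "low_count") <- low
  attr(out, "low_fraction") <- low / total
  attr(out, "low_range") <- low_range
  out
}
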