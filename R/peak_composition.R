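# Summit-window extraction, AT content, genome AT maps, peak-set summaries
# and differential peak-set comparison.

#' AT fraction of DNA sequences
#'
#' `(#A + #T) / (#A + #C + #G + #T)`; `N` bases are excluded from both
#' numerator and denominator. A sequence with no unambiguous base yields
#' `NA`. Strand-invariant by construction (A pairs with T, C with G).
#'
#' @param sequence Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Numeric vector of fractions in `[0, 1]` (or `NA`).
#' @export
at_fraction <- function(sequence) {
  if (length(sequence) == 0L) return(numeric(0))
  if (any(!nzchar(sequence))) stop_fmt("empty sequence")
  n_at <- nchar(gsub("[^AT]", "", sequence))
  n_acgt <- nchar(gsub("[^ACGT]", "", sequence))
  ifelse(n_acgt == 0L, NA_real_, n_at / n_acgt)
}

#' Extract summit-centered windows for a peak set
#'
#' The window of a peak with absolute summit `s` is
#' `[s - halfwidth, s + halfwidth + 1)` — `halfwidth` bases either side of
#' the summit, 99 bp at the default — clipped to contig bounds. Clipped
#' windows carry `truncated = TRUE` and are excluded from set-level
#' statistics by the downstream summaries.
#'
#' @param peakset A [peak_set()].
#' @param genome A [genome_sequence()].
#' @param halfwidth Window halfwidth in bp (default 49).
#' @return data.frame with columns `name`, `contig`, `win_start`,
#'   `win_end`, `sequence`, `truncated`.
#' @export
extract_summit_windows <- function(peakset, genome, halfwidth = 49L) {
  p <- peakset$peaks
  miss <- setdiff(unique(p$contig), names(genome))
  if (length(miss)) stop_fmt("contig %s not present in genome", miss[1L])
  if (halfwidth < 0) stop_fmt("halfwidth must be >= 0")
  summit <- p$start + p$summit_offset
  len <- nchar(genome)[match(p$contig, names(genome))]
  lo <- pmax(summit - halfwidth, 0L)
  hi <- pmin(summit + halfwidth + 1L, len)
  seqs <- substring(genome[match(p$contig, names(genome))], lo + 1L, hi)
  data.frame(name = p$name, contig = p$contig, win_start = lo, win_end = hi,
             sequence = unname(seqs),
             truncated = (hi - lo) != (2L * halfwidth + 1L),
             stringsAsFactors = FALSE)
}

#' @rdname extract_summit_windows
#' @param peak A single-row peak data.frame (as in `peak_set()$peaks`).
#' @export
extract_summit_window <- function(peak, genome, halfwidth = 49L) {
  extract_summit_windows(peak_set("single", peak), genome, halfwidth)
}

#' Genome-wide AT map over fixed windows
#'
#' Tiles every contig with consecutive non-overlapping windows of exactly
#' `window` bp (trailing partial windows are dropped) and reports AT
#' content in percent as a bedGraph-writable track.
#'
#' @param genome A [genome_sequence()].
#' @param window Window size in bp (default 100).
#' @return A [coverage_track()] with `depth` = AT% of each window;
#'   all-`N` windows are omitted.
#' @export
genome_at_map <- function(genome, window = 100L) {
  if (!is_count(window)) stop_fmt("window must be a positive count")
  segs <- lapply(names(genome), function(id) {
    L <- nchar(genome[[id]])
    n_win <- L %/% window
    if (n_win == 0L) return(NULL)
    starts <- (seq_len(n_win) - 1L) * window
    at <- at_fraction(substring(genome[[id]], starts + 1L, starts + window))
    keep <- !is.na(at)
    data.frame(contig = id, start = starts[keep], end = starts[keep] + window,
               depth = 100 * at[keep], stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L)
    stop_fmt("no contig holds a complete %d bp window", window)
  coverage_track(segs)
}

#' AT summary of a peak set against genome and island references
#'
#' @param peakset A [peak_set()].
#' @param genome A [genome_sequence()].
#' @param gi_intervals Optional data.frame (`contig`, `start`, `end`,
#'   0-based half-open) of genomic-island intervals for the island
#'   reference; `NULL` or empty reports the reference as `NA`.
#' @param halfwidth Summit-window halfwidth (default 49).
#' @param pooling `"per_peak"` (mean of per-peak AT fractions; default) or
#'   `"pooled_bases"` (base counts pooled across all windows before the
#'   ratio).
#' @return List of class `at_summary`: `per_peak` (data.frame `name`,
#'   `at_frac`), `mean_at_pct`, `genome_at_pct`, `gi_at_pct`,
#'   `n_peaks_used`, `n_truncated`.
#' @export
peakset_at_summary <- function(peakset, genome, gi_intervals = NULL,
                               halfwidth = 49L,
                               pooling = c("per_peak", "pooled_bases")) {
  pooling <- match.arg(pooling)
  win <- extract_summit_windows(peakset, genome, halfwidth)
  keep <- !win$truncated
  if (any(!keep))
    message(sprintf("peakset_at_summary: %d truncated window(s) excluded",
                    sum(!keep)))
  at <- at_fraction(win$sequence[keep])
  per_peak <- data.frame(name = win$name[keep], at_frac = at,
                         stringsAsFactors = FALSE)
  mean_at <- if (pooling == "per_peak") {
    100 * mean(at, na.rm = TRUE)
  } else {
    100 * at_pooled(win$sequence[keep])
  }
  gi_at <- NA_real_
  if (!is.null(gi_intervals) && nrow(gi_intervals) > 0) {
    gi_seqs <- mapply(genome_slice, contig = gi_intervals$contig,
                      start = gi_intervals$start, end = gi_intervals$end,
                      MoreArgs = list(genome = genome))
    gi_at <- 100 * at_pooled(gi_seqs)
  }
  structure(list(per_peak = per_peak,
                 mean_at_pct = mean_at,
                 genome_at_pct = 100 * at_pooled(unclass(genome)),
                 gi_at_pct = gi_at,
                 n_peaks_used = sum(keep), n_truncated = sum(!keep),
                 pooling = pooling),
            class = "at_summary")
}

# pooled-base AT ratio across a set of sequences
at_pooled <- function(seqs) {
  n_at <- sum(nchar(gsub("[^AT]", "", seqs)))
  n_acgt <- sum(nchar(gsub("[^ACGT]", "", seqs)))
  if (n_acgt == 0L) NA_real_ else n_at / n_acgt
}

#' @export
print.at_summary <- function(x, ...) {
  cat(sprintf("AT summary (%s): peaks %.2f%% (n=%d) | genome %.2f%% | islands %s\n",
              x$pooling, x$mean_at_pct, x$n_peaks_used, x$genome_at_pct,
              if (is.na(x$gi_at_pct)) "NA" else sprintf("%.2f%%", x$gi_at_pct)))
  invisible(x)
}

#' Differential comparison of two peak sets
#'
#' A peak is shared when it overlaps a peak of the other set by at least
#' 1 bp and by at least `min_overlap_frac` of the shorter of the two peaks.
#' Unique peaks keep their recruitment so callers can summarise, e.g., the
#' mean fold enrichment of condition-specific peaks.
#'
#' @param setA,setB Two [peak_set()] objects.
#' @param min_overlap_frac Minimum overlap as a fraction of the shorter
#'   peak (default 0: any 1-bp overlap).
#' @return List with `unique_a`, `unique_b` (peak data.frames) and
#'   `shared` (data.frame `name_a`, `name_b`, `overlap_bp`). Swapping the
#'   inputs swaps the unique lists.
#' @export
compare_peaksets <- function(setA, setB, min_overlap_frac = 0) {
  pa <- setA$peaks; pb <- setB$peaks
  gra <- GenomicRanges::GRanges(pa$contig,
                                IRanges::IRanges(pa$start + 1L, pa$end))
  grb <- GenomicRanges::GRanges(pb$contig,
                                IRanges::IRanges(pb$start + 1L, pb$end))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gra)[qi],
                                           IRanges::ranges(grb)[si]))
  need <- pmax(1, min_overlap_frac * pmin(pa$end[qi] - pa$start[qi],
                                          pb$end[si] - pb$start[si]))
  keep <- ov >= need
  qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
  list(unique_a = pa[!seq_len(nrow(pa)) %in% qi, , drop = FALSE],
       unique_b = pb[!seq_len(nrow(pb)) %in% si, , drop = FALSE],
       shared = data.frame(name_a = pa$name[qi], name_b = pb$name[si],
                           overlap_bp = ov, stringsAsFactors = FALSE))
}
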