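# Coverage signal matrix and mean metaprofile around transcription start
# sites (the computeMatrix / plotHeatmap analogue for bedGraph input).

# per-contig depth vectors; contig length = furthest segment end
expand_track <- function(track) {
  out <- lapply(split(track, track$contig), function(seg) {
    L <- max(seg$end)
    d <- numeric(L)
    for (i in seq_len(nrow(seg)))
      d[(seg$start[i] + 1L):seg$end[i]] <- seg$depth[i]
    d
  })
  out
}

#' Coverage matrix around transcription start sites
#'
#' For each TSS, the window spans `upstream` bp before to `downstream` bp
#' after the start, strand-corrected: minus-strand rows are reversed so
#' that column 1 is always biologically upstream. Each bin value is the
#' mean per-base depth over the bin's in-range bases (bedGraph gaps count
#' as depth 0); bases beyond the contig are missing and bins entirely
#' off-contig are `NA`, excluded from column means downstream.
#'
#' @param track A [coverage_track()].
#' @param tss data.frame as from [read_bed_tss()] / [simulate_tss()].
#' @param upstream,downstream Window extents in bp (defaults 500/500,
#'   sized for compact bacterial genomes).
#' @param bin_size Bin width in bp; must divide `upstream` and
#'   `downstream` (default 10).
#' @return Numeric matrix of class `tss_matrix` (rows = TSS, named by
#'   gene id; columns = bins) with attribute `bin_centers`: the bin-center
#'   coordinates relative to the TSS (negative = upstream).
#' @export
build_tss_matrix <- function(track, tss, upstream = 500L, downstream = 500L,
                             bin_size = 10L) {
  if (upstream %% bin_size != 0 || downstream %% bin_size != 0)
    stop_fmt("bin_size must divide upstream and downstream")
  keep <- tss$contig %in% unique(track$contig)
  if (!any(keep)) stop_fmt("no TSS lies on a covered contig")
  tss <- tss[keep, , drop = FALSE]
  depths <- expand_track(track)
  n_bins <- (upstream + downstream) %/% bin_size
  span <- upstream + downstream
  m <- matrix(NA_real_, nrow(tss), n_bins)
  for (i in seq_len(nrow(tss))) {
    d <- depths[[tss$contig[i]]]
    pos <- tss$position[i]
    coords <- if (tss$strand[i] == "+") {
      (pos - upstream):(pos + downstream - 1L)
    } else {
      (pos + upstream):(pos - downstream + 1L)
    }
    vals <- rep(NA_real_, span)
    ok <- coords >= 0L & coords < length(d)
    vals[ok] <- d[coords[ok] + 1L]
    vm <- matrix(vals, nrow = bin_size)
    m[i, ] <- colMeans(vm, na.rm = TRUE)
  }
  m[is.nan(m)] <- NA_real_
  rownames(m) <- tss$gene
  attr(m, "bin_centers") <- -upstream + bin_size * (seq_len(n_bins) - 1L) +
    bin_size / 2
  attr(m, "bin_size") <- bin_size
  class(m) <- c("tss_matrix", "matrix", "array")
  m
}

#' Mean metaprofile of a TSS matrix
#'
#' Column-wise mean depth ignoring missing entries, plus per-bin support
#' (`n`, rows contributing) and occupancy (fraction of contributing rows
#' with depth above the profile-wide minimum, a peak-count-style measure).
#'
#' @param matrix A [build_tss_matrix()] result.
#' @return data.frame with columns `bin_center`, `mean_depth`, `n`,
#'   `occupancy`.
#' @export
mean_profile <- function(matrix) {
  stopifnot(inherits(matrix, "tss_matrix"))
  m <- unclass(matrix)
  floor_depth <- min(m, na.rm = TRUE)
  data.frame(bin_center = attr(matrix, "bin_centers"),
             mean_depth = colMeans(m, na.rm = TRUE),
             n = colSums(!is.na(m)),
             occupancy = colMeans(m > floor_depth + 1e-9, na.rm = TRUE))
}
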