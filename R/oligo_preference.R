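# Oligonucleotide (k-mer) usage, usage deviation against the uniform
# expectation, and per-k-mer Spearman correlation with recruitment.

#' All k-mers over {A,C,G,T} in lexicographic order
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- b
  for (i in seq_len(k - 1L)) out <- as.vector(t(outer(out, b, paste0)))
  out
}

#' k-mer frequency distribution of a sequence
#'
#' Successive overlapping windows of width `k`, step 1 (`L - k + 1`
#' windows); windows containing `N` are skipped. Frequencies are counts
#' divided by the number of counted windows and always cover all `4^k`
#' categories (16 dinucleotides, 64 trinucleotides), absent k-mers as 0.
#'
#' @param sequence A DNA string over `{A,C,G,T,N}`.
#' @param k Word length, 2 or 3.
#' @return Named numeric vector of length `4^k` summing to 1, or `NULL`
#'   (with a message) when no window could be counted.
#' @export
kmer_frequencies <- function(sequence, k) {
  if (!k %in% c(2L, 3L)) stop_fmt("k must be 2 or 3")
  L <- nchar(sequence)
  if (L < k) {
    message(sprintf("kmer_frequencies: sequence shorter than k = %d, usage missing", k))
    return(NULL)
  }
  words <- substring(sequence, 1:(L - k + 1L), k:L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0L) {
    message("kmer_frequencies: no N-free window, usage missing")
    return(NULL)
  }
  counts <- table(factor(words, levels = all_kmers(k)))
  stats::setNames(as.vector(counts) / length(words), all_kmers(k))
}

#' Usage deviation from the uniform expectation
#'
#' Observed frequency divided by the uniform expectation `1 / 4^k`
#' (0.0625 for dinucleotides, 0.015625 for trinucleotides), i.e.
#' `frequency * 4^k`.
#'
#' @param frequencies Output of [kmer_frequencies()].
#' @param k Word length matching `frequencies`.
#' @return Named numeric vector of deviations.
#' @export
usage_deviation <- function(frequencies, k) {
  if (length(frequencies) != 4^k)
    stop_fmt("expected %d categories for k = %d, got %d", 4^k, k,
             length(frequencies))
  frequencies * 4^k
}

#' Spearman rank correlation
#'
#' Ranks use average ties; rho is the Pearson correlation of the rank
#' vectors. The two-sided p-value uses the t approximation with `n - 2`
#' degrees of freedom for `n > 10` and otherwise a seeded 10,000-draw
#' permutation sample (both modes can be forced via `p_method`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, no missing values.
#' @param p_method `"auto"` (default), `"t"` or `"permutation"`.
#' @param n_perm Permutation draws for the permutation p-value.
#' @return List with `rho`, `p` and `n`; `rho` is `NA` (with `p` `NA`)
#'   when either rank vector has zero variance.
#' @export
spearman_rho <- function(x, y, p_method = c("auto", "t", "permutation"),
                         n_perm = 10000L) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) stop_fmt("x and y must have equal length")
  if (n < 3L) stop_fmt("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_fmt("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  use_t <- p_method == "t" || (p_method == "auto" && n > 10L)
  if (use_t) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    p <- with_seed_restored(10007L, {
      perm <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
      (1 + sum(perm >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate k-mer usage with recruitment across peaks
#'
#' For each of the `4^k` k-mers, the Spearman correlation between the
#' per-peak usage deviation and the per-peak recruitment level (fold
#' enrichment). Peaks with truncated summit windows or undefined usage are
#' dropped. Raw p-values are reported alongside Benjamini-Hochberg
#' adjusted values computed across the `4^k` tests of the same `k`.
#'
#' @param peakset A [peak_set()].
#' @param genome A [genome_sequence()].
#' @param k Word length, 2 or 3.
#' @param halfwidth Summit-window halfwidth (default 49).
#' @param p_method Passed to [spearman_rho()].
#' @return data.frame with one row per k-mer: `kmer`, `rho`, `p`, `q`,
#'   `n`.
#' @export
correlate_usage_recruitment <- function(peakset, genome, k, halfwidth = 49L,
                                        p_method = "auto") {
  win <- extract_summit_windows(peakset, genome, halfwidth)
  keep <- !win$truncated
  freqs <- lapply(win$sequence[keep],
                  function(s) suppressMessages(kmer_frequencies(s, k)))
  ok <- !vapply(freqs, is.null, logical(1))
  if (sum(ok) < 3L) stop_fmt("fewer than 3 peaks with defined k-mer usage")
  dev <- do.call(rbind, freqs[ok]) * 4^k
  recruit <- peakset$peaks$recruitment[keep][ok]
  res <- lapply(all_kmers(k), function(km) {
    s <- spearman_rho(dev[, km], recruit, p_method = p_method)
    data.frame(kmer = km, rho = s$rho, p = s$p, n = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("kmer", "rho", "p", "q", "n")]
}
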