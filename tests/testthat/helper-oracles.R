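# Independent brute-force oracles and small fixture builders.

# character-by-character k-mer enumeration, deliberately naive
bf_kmer_counts <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- integer(0)
  n_counted <- 0L
  for (i in seq_len(length(chars) - k + 1L)) {
    w <- paste(chars[i:(i + k - 1L)], collapse = "")
    if (grepl("N", w)) next
    n_counted <- n_counted + 1L
    counts[w] <- (if (is.na(counts[w])) 0L else counts[w]) + 1L
  }
  list(counts = counts, n_counted = n_counted)
}

# average ranks computed by explicit tie-group search, Pearson by sums
bf_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

bf_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

bf_spearman <- function(x, y) bf_pearson(bf_rank(x), bf_rank(y))

# quadratic-time overlap scan between two peak data.frames
bf_shared <- function(pa, pb) {
  shared_a <- logical(nrow(pa))
  shared_b <- logical(nrow(pb))
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    if (pa$contig[i] != pb$contig[j]) next
    ov <- min(pa$end[i], pb$end[j]) - max(pa$start[i], pb$start[j])
    if (ov >= 1) { shared_a[i] <- TRUE; shared_b[j] <- TRUE }
  }
  list(unique_a = pa$name[!shared_a], unique_b = pb$name[!shared_b])
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_peakset <- function(contig, starts, width, recruitment,
                         label = "test") {
  peak_set(label, data.frame(
    contig = contig, start = starts, end = starts + width,
    name = sprintf("pk%03d", seq_along(starts)),
    summit_offset = width %/% 2L, recruitment = recruitment,
    stringsAsFactors = FALSE))
}

# small, fast simulator configuration for unit tests
small_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, genome_length = 100000L, n_islands = 8L,
                   island_length = 2500L, n_sites = 150L, tss_count = 80L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
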