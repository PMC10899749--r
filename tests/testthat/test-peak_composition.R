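test_that("summit windows are 2*halfwidth+1 bp, clipped windows flagged", {
  g <- genome_sequence(c(c1 = random_dna(1000)))
  mk <- function(start, width = 200L, so = width %/% 2L)
    peak_set("t", data.frame(contig = "c1", start = start,
                             end = start + width, name = "p1",
                             summit_offset = so, recruitment = 2))
  # summit at 100: window [51, 150), 49 either side of the summit
  w <- extract_summit_windows(mk(0L, 200L, 100L), g, halfwidth = 49)
  expect_equal(c(w$win_start, w$win_end), c(51L, 150L))
  expect_equal(nchar(w$sequence), 99L)
  expect_false(w$truncated)
  expect_identical(w$sequence, genome_slice(g, "c1", 51, 150))

  # summit at 10: clipped at the contig start
  w2 <- extract_summit_windows(mk(0L, 200L, 10L), g, halfwidth = 49)
  expect_equal(c(w2$win_start, w2$win_end), c(0L, 60L))
  expect_true(w2$truncated)

  # halfwidth 0: the summit base alone
  w3 <- extract_summit_windows(mk(0L, 200L, 100L), g, halfwidth = 0)
  expect_identical(w3$sequence, substr(g[["c1"]], 101, 101))

  expect_error(extract_summit_windows(
    peak_set("t", data.frame(contig = "nope", start = 0L, end = 10L,
                             name = "p", summit_offset = 5L,
                             recruitment = 1)), g), "not present")
})

test_that("AT fraction follows the declared N policy and strand symmetry", {
  expect_equal(at_fraction("ATAT"), 1)
  expect_equal(at_fraction("GCGC"), 0)
  expect_equal(at_fraction("ATGCN"), 0.5)
  expect_true(is.na(at_fraction("NNN")))
  expect_error(at_fraction(""), "empty")
  # reverse complement leaves the value unchanged
  withr::local_seed(1)
  for (i in 1:20) {
    s <- random_dna(60, c("A", "C", "G", "T", "N"))
    rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                         collapse = ""))
    expect_identical(at_fraction(s), at_fraction(rc))
  }
})

test_that("genome AT map tiles with fixed windows and matches a recount", {
  g <- genome_sequence(c(c1 = random_dna(250), c2 = strrep("A", 150)))
  tr <- genome_at_map(g, window = 100)
  expect_equal(sum(tr$contig == "c1"), 2L)   # 50 bp tail dropped
  expect_equal(sum(tr$contig == "c2"), 1L)
  expect_equal(tr$depth[tr$contig == "c2"], 100)
  # windows tile without overlap and values equal a brute-force count
  for (i in which(tr$contig == "c1")) {
    s <- genome_slice(g, "c1", tr$start[i], tr$end[i])
    chars <- strsplit(s, "")[[1]]
    expect_equal(tr$depth[i], 100 * sum(chars %in% c("A", "T")) / 100)
  }
  c1 <- tr[tr$contig == "c1", ]
  expect_equal(c1$start[-1], c1$end[-nrow(c1)])
  # concatenated window AT counts equal whole-genome counts minus the tail
  head200 <- genome_slice(g, "c1", 0, 200)
  expect_equal(sum(c1$depth), 100 * at_fraction(head200) * 2)
})

test_that("peak-set AT summary averages untruncated windows against references", {
  g <- genome_sequence(c(c1 = paste0(strrep("A", 300), strrep("G", 700))))
  ps <- make_peakset("c1", c(50L, 100L), 100L, c(2, 3))  # summits at 100, 150
  s <- peakset_at_summary(ps, g)
  expect_equal(s$mean_at_pct, 100)
  expect_equal(s$genome_at_pct, 30)
  expect_true(is.na(s$gi_at_pct))
  s2 <- peakset_at_summary(ps, g, gi_intervals = data.frame(
    contig = "c1", start = 250L, end = 350L))
  expect_equal(s2$gi_at_pct, 50)
  # truncated windows are dropped from the mean
  ps3 <- make_peakset("c1", c(50L, 920L), 80L, c(2, 3))  # summits at 90, 960
  expect_message(s3 <- peakset_at_summary(ps3, g), "1 truncated")
  expect_equal(s3$n_peaks_used, 1L)
  expect_equal(s3$mean_at_pct, 100)
  # pooled_bases mode equals the per_peak mode on equal-length windows with equal AT
  expect_equal(peakset_at_summary(ps, g, pooling = "pooled_bases")$mean_at_pct,
               100)
})

test_that("set mean AT lies between per-peak extremes on simulated data", {
  cfg <- small_config(seed = 3)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  s <- peakset_at_summary(sim$peaks, g)
  expect_gte(s$mean_at_pct / 100, min(s$per_peak$at_frac))
  expect_lte(s$mean_at_pct / 100, max(s$per_peak$at_frac))
  expect_true(all(s$per_peak$at_frac >= 0 & s$per_peak$at_frac <= 1))
})

test_that("peak-set comparison matches a quadratic brute-force scan and is symmetric", {
  a <- make_peakset("c1", c(0L, 500L, 900L), 100L, c(1, 2, 3), "A")
  id <- compare_peaksets(a, a)
  expect_equal(nrow(id$unique_a), 0L)
  expect_equal(nrow(id$unique_b), 0L)

  b <- make_peakset("c1", c(2000L, 3000L), 100L, c(1, 2), "B")
  dj <- compare_peaksets(a, b)
  expect_equal(dj$unique_a$name, a$peaks$name)
  expect_equal(dj$unique_b$name, b$peaks$name)

  withr::local_seed(11)
  for (i in 1:15) {
    pa <- make_peakset(sample(c("c1", "c2"), 12, replace = TRUE),
                       sample.int(2000, 12), sample(20:200, 1),
                       runif(12, 1, 5), "A")$peaks
    pb <- make_peakset(sample(c("c1", "c2"), 9, replace = TRUE),
                       sample.int(2000, 9), sample(20:200, 1),
                       runif(9, 1, 5), "B")$peaks
    got <- compare_peaksets(peak_set("A", pa), peak_set("B", pb))
    want <- bf_shared(pa, pb)
    expect_setequal(got$unique_a$name, want$unique_a)
    expect_setequal(got$unique_b$name, want$unique_b)
    # symmetry: swapping the inputs swaps the unique lists
    swp <- compare_peaksets(peak_set("B", pb), peak_set("A", pa))
    expect_identical(swp$unique_a, got$unique_b)
    expect_identical(swp$unique_b, got$unique_a)
  }
})

test_that("minimum-overlap fraction tightens the sharing criterion", {
  a <- make_peakset("c1", 0L, 100L, 2, "A")
  b <- make_peakset("c1", 95L, 100L, 2, "B")  # 5 bp overlap
  expect_equal(nrow(compare_peaksets(a, b)$shared), 1L)
  expect_equal(nrow(compare_peaksets(a, b, min_overlap_frac = 0.5)$shared), 0L)
})
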