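test_that("simulator outputs are bit-identical under an identical config", {
  cfg <- small_config(seed = 7)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  tss1 <- simulate_tss(cfg, g1)
  s1 <- simulate_peaks(cfg, g1, tss1)
  s2 <- simulate_peaks(cfg, g2, simulate_tss(cfg, g2))
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(simulate_coverage(s1$peaks, cfg),
                   simulate_coverage(s2$peaks, cfg))
})

test_that("degenerate composition: background_at = 1 gives an A/T-only genome", {
  cfg <- small_config(seed = 2, background_at = 1, island_at = 1,
                      genome_length = 20000L, n_islands = 1L,
                      island_length = 500L)
  g <- simulate_genome(cfg)
  expect_false(grepl("[CG]", g[["chr"]]))
})

test_that("background AT fraction sits within 3 binomial SDs of its target", {
  cfg <- small_config(seed = 9, genome_length = 200000L)
  g <- simulate_genome(cfg)
  isl <- attr(g, "islands")
  bases <- strsplit(g[["chr"]], "")[[1]]
  in_island <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(isl)))
    in_island[(isl$start[i] + 1L):isl$end[i]] <- TRUE
  bg <- bases[!in_island]
  p_hat <- mean(bg %in% c("A", "T"))
  sd3 <- 3 * sqrt(cfg$background_at * (1 - cfg$background_at) / length(bg))
  expect_lt(abs(p_hat - cfg$background_at), sd3)
  # islands are elevated and non-overlapping
  expect_true(all(diff(isl$start) >= cfg$island_length))
  p_isl <- mean(bases[in_island] %in% c("A", "T"))
  expect_gt(p_isl, cfg$background_at + 0.05)
})

test_that("island placement fails loudly when islands cannot fit", {
  expect_error(simulate_genome(small_config(genome_length = 10000L,
                                            n_islands = 5L,
                                            island_length = 3000L)),
               "fit|overlap")
})

test_that("alpha = 1 removes the AT dependence of recruitment", {
  cfg <- small_config(seed = 4, alpha_acetyl = 1, noise_sd = 0,
                      call_threshold = 1)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  # specific term zero for every site: recruitment collapses to the
  # nonspecific baseline r0 * (1 + kappa)
  expect_equal(unique(sim$truth$sites$recruitment),
               cfg$r_nonspecific * (1 + cfg$kappa))
  expect_true(is.na(sim$truth$s_true))
})

test_that("noiseless sites at background AT recruit exactly the nonspecific level", {
  cfg <- small_config(seed = 5, noise_sd = 0, call_threshold = 1)
  g <- simulate_genome(cfg)
  sim <- simulate_peaks(cfg, g)
  st <- sim$truth$sites
  flat <- st$at_frac <= cfg$background_at
  expect_gt(sum(flat), 0)
  expect_equal(st$recruitment[flat], rep(cfg$r_nonspecific, sum(flat)))
  # and the linear law holds exactly above background
  expect_equal(st$recruitment[!flat],
               cfg$beta_spec * (st$at_frac[!flat] - cfg$background_at) +
                 cfg$r_nonspecific)
})

test_that("mean called-peak AT% drops between alpha 0 and 0.8 for every seed", {
  for (seed in 1:10) {
    at <- vapply(c(0, 0.8), function(a) {
      cfg <- small_config(seed = seed, alpha_acetyl = a)
      g <- simulate_genome(cfg)
      sim <- simulate_peaks(cfg, g)
      mean(sim$truth$sites$at_frac[sim$truth$sites$called])
    }, numeric(1))
    expect_lt(at[2], at[1])
  }
})

test_that("coverage is a floor plus additive triangular bumps peaking at summits", {
  cfg <- small_config(genome_length = 10000L, n_islands = 1L,
                      island_length = 500L)
  empty <- peak_set("none", data.frame(contig = character(0),
                                       start = integer(0), end = integer(0),
                                       name = character(0),
                                       summit_offset = integer(0),
                                       recruitment = numeric(0)))
  flat <- simulate_coverage(empty, cfg)
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$depth, cfg$cov_floor)
  expect_equal(flat$end, cfg$genome_length)

  one <- make_peakset("chr", 4000L, 201L, 5)
  cov1 <- simulate_coverage(one, cfg)
  summit <- 4000L + 100L
  at_summit <- cov1$depth[cov1$start <= summit & cov1$end > summit]
  expect_equal(at_summit, max(cov1$depth))
  expect_equal(at_summit, cfg$cov_floor + cfg$cov_gain * 5)

  # superposition: two overlapping peaks add depth
  two <- make_peakset("chr", c(4000L, 4000L), 201L, c(5, 3))
  cov2 <- simulate_coverage(two, cfg)
  expect_equal(max(cov2$depth), cfg$cov_floor + cfg$cov_gain * 8)
})

test_that("noiseless Ct tables encode the programmed folds cycle-exactly", {
  cfg <- small_config(ct_noise = 0)
  tab <- simulate_ct(data.frame(target = "tgt", condition = "cal", fold = 1),
                     cfg, mode = "expression")
  expect_equal(tab$ct[tab$target == "tgt"], rep(cfg$ct_ref, cfg$n_reps))
  tab2 <- simulate_ct(data.frame(target = "tgt", condition = "cal", fold = 2),
                      cfg, mode = "expression")
  expect_equal(unique(tab2$ct[tab2$target == "tgt"]), cfg$ct_ref - 1)
  expect_error(simulate_ct(data.frame(target = "dnaA", condition = "c",
                                      fold = 2), cfg),
               "reference")
})
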