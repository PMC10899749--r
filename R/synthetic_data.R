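# Synthetic genome / occupancy / qPCR simulator with recorded ground truth.
#
# The generator emulates the statistical structure of a ChIP-seq experiment
# on a xenogeneic silencer: a bacterial genome with background AT ~ 40% and
# AT-elevated islands (genomic-island analogues), binding sites whose
# recruitment (fold enrichment) rises linearly with local AT content above
# background, and an acetylation parameter alpha that attenuates that
# AT dependence while adding diffuse nonspecific binding.

#' Simulator configuration
#'
#' Recruitment of a candidate site with summit-window AT fraction `a` is
#' \deqn{r = \beta (1-\alpha) \max(0, a - a_0) + r_0 (1 + \kappa \alpha)
#'       + N(0, \sigma)}
#' where `a_0 = background_at`, `beta = beta_spec`, `alpha = alpha_acetyl`,
#' `r_0 = r_nonspecific` and `sigma = noise_sd`. Sites with `r >=
#' call_threshold` become called peaks. The slope of AT fraction against
#' recruitment among specifically bound sites is therefore
#' `s_true = 1 / (beta_spec * (1 - alpha_acetyl))`.
#'
#' @param seed Integer RNG seed; every simulator output is bit-identical
#'   under an identical configuration.
#' @param genome_length Genome size in bp (single contig `"chr"`).
#' @param background_at Genome background AT fraction (default 0.403, the
#'   genome-wide average of the modelled organism).
#' @param n_islands,island_length,island_at Number, length (bp) and AT
#'   fraction of non-overlapping AT-elevated islands.
#' @param n_sites Candidate binding sites per condition.
#' @param beta_spec AT-dependence strength, recruitment units per unit of
#'   AT fraction above background.
#' @param alpha_acetyl Acetylation attenuation in `[0, 1]`; 0 = fully
#'   specific binder, 1 = AT dependence abolished.
#' @param r_nonspecific Baseline (nonspecific) recruitment.
#' @param kappa Nonspecific gain per unit `alpha_acetyl`: acetylated
#'   protein binds more diffusely.
#' @param noise_sd SD of Gaussian recruitment noise.
#' @param call_threshold Minimum recruitment for a site to be emitted as a
#'   called peak.
#' @param tss_count Number of transcription start sites.
#' @param tss_island_frac Fraction of TSS placed inside islands (silencers
#'   target promoters of AT-rich acquired genes).
#' @param tss_bias_p0 Probability, at `alpha_acetyl = 0`, that a site is
#'   targeted to within 50 bp of a TSS; the effective probability is
#'   `tss_bias_p0 * (1 - alpha_acetyl)`.
#' @param window_halfwidth Summit-window halfwidth in bp used for the
#'   site AT fraction (window length `2 * halfwidth + 1`).
#' @param peak_halfwidth Halfwidth of the emitted peak interval and of the
#'   triangular coverage bump.
#' @param cov_floor,cov_gain Coverage floor depth and bump apex per unit
#'   recruitment for [simulate_coverage()].
#' @param ct_ref,ct_noise,n_reps Reference Ct (cycles), Ct noise SD and
#'   replicate count for [simulate_ct()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 500000L,
                       background_at = 0.403,
                       n_islands = 20L,
                       island_length = 5000L,
                       island_at = 0.55,
                       n_sites = 300L,
                       beta_spec = 200,
                       alpha_acetyl = 0,
                       r_nonspecific = 1.5,
                       kappa = 1,
                       noise_sd = 0.5,
                       call_threshold = 3,
                       tss_count = 200L,
                       tss_island_frac = 0.6,
                       tss_bias_p0 = 0.5,
                       window_halfwidth = 49L,
                       peak_halfwidth = 100L,
                       cov_floor = 1,
                       cov_gain = 10,
                       ct_ref = 20,
                       ct_noise = 0.15,
                       n_reps = 3L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              background_at = background_at, n_islands = as.integer(n_islands),
              island_length = as.integer(island_length), island_at = island_at,
              n_sites = as.integer(n_sites), beta_spec = beta_spec,
              alpha_acetyl = alpha_acetyl, r_nonspecific = r_nonspecific,
              kappa = kappa, noise_sd = noise_sd,
              call_threshold = call_threshold, tss_count = as.integer(tss_count),
              tss_island_frac = tss_island_frac, tss_bias_p0 = tss_bias_p0,
              window_halfwidth = as.integer(window_halfwidth),
              peak_halfwidth = as.integer(peak_halfwidth),
              cov_floor = cov_floor, cov_gain = cov_gain, ct_ref = ct_ref,
              ct_noise = ct_noise, n_reps = as.integer(n_reps))
  for (f in c("background_at", "island_at", "alpha_acetyl", "tss_bias_p0",
              "tss_island_frac"))
    if (!is_frac(cfg[[f]])) stop_fmt("%s must be a fraction in [0,1]", f)
  for (f in c("genome_length", "n_islands", "island_length", "n_sites",
              "tss_count", "n_reps"))
    if (!is_count(cfg[[f]])) stop_fmt("%s must be a positive count", f)
  if (cfg$beta_spec < 0) stop_fmt("beta_spec must be >= 0")
  if (cfg$noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  if (cfg$window_halfwidth < 0) stop_fmt("window_halfwidth must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

#' Simulate a genome with AT-elevated islands
#'
#' Background bases are i.i.d. with `P(A) = P(T) = background_at / 2`;
#' `n_islands` non-overlapping intervals are redrawn i.i.d. at `island_at`.
#'
#' @param config A [sim_config()].
#' @return A [genome_sequence()] (single contig `"chr"`) with attribute
#'   `"islands"`: a data.frame of 0-based half-open island intervals.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  il <- config$island_length
  if (config$n_islands * il > L)
    stop_fmt("islands do not fit in the genome")
  with_seed_restored(config$seed, {
    bases <- rand_dna(L, config$background_at)
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < config$n_islands) {
      cand <- sample.int(L - il + 1L, 1L) - 1L
      if (!any(abs(cand - starts) < il)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 1000L * config$n_islands)
        stop_fmt("could not place %d non-overlapping islands; reduce n_islands or island_length",
                 config$n_islands)
    }
    starts <- sort(starts)
    for (s in starts) bases[(s + 1L):(s + il)] <- rand_dna(il, config$island_at)
    g <- genome_sequence(c(chr = paste(bases, collapse = "")))
    attr(g, "islands") <- data.frame(contig = "chr", start = starts,
                                     end = starts + il)
    g
  })
}

#' Simulate transcription start sites
#'
#' A fraction `tss_island_frac` of TSS is placed uniformly inside islands,
#' the rest uniformly over the genome; strands are random.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()] (carries the island
#'   intervals as an attribute).
#' @return data.frame with columns `contig`, `position`, `strand`, `gene`.
#' @export
simulate_tss <- function(config, genome) {
  islands <- attr(genome, "islands")
  if (is.null(islands)) stop_fmt("genome lacks island annotation; use simulate_genome()")
  L <- nchar(genome[["chr"]])
  with_seed_restored(config$seed + 1L, {
    n_isl <- round(config$tss_count * config$tss_island_frac)
    pos_isl <- if (n_isl > 0) {
      which_isl <- sample.int(nrow(islands), n_isl, replace = TRUE)
      islands$start[which_isl] +
        sample.int(config$island_length, n_isl, replace = TRUE) - 1L
    } else integer(0)
    n_bg <- config$tss_count - n_isl
    pos_bg <- if (n_bg > 0) sample.int(L, n_bg) - 1L else integer(0)
    pos <- c(pos_isl, pos_bg)
    data.frame(contig = "chr", position = as.integer(pos),
               strand = sample(c("+", "-"), config$tss_count, replace = TRUE),
               gene = sprintf("g%04d", seq_len(config$tss_count)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate binding sites and called peaks, recording ground truth
#'
#' Each of `n_sites` summits is targeted to within +/- 50 bp of a random
#' TSS with probability `tss_bias_p0 * (1 - alpha_acetyl)`, otherwise
#' placed uniformly. Recruitment follows the linear-with-threshold model of
#' [sim_config()]; sites reaching `call_threshold` are emitted as peaks.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @param tss Optional TSS table; generated via [simulate_tss()] when `NULL`.
#' @return A list with elements `peaks` (a [peak_set()] labelled
#'   `alpha_<alpha_acetyl>`) and `truth` (class `sim_truth`: island
#'   intervals, the TSS table, per-site table with AT fraction `at_frac`,
#'   pre-threshold recruitment `recruitment`, `tss_targeted` flag and
#'   `called` flag, and the analytic slope `s_true =
#'   1/(beta_spec*(1-alpha_acetyl))`, `NA` when `alpha_acetyl = 1`).
#' @export
simulate_peaks <- function(config, genome, tss = NULL) {
  stopifnot(inherits(config, "sim_config"))
  islands <- attr(genome, "islands")
  if (is.null(tss)) tss <- simulate_tss(config, genome)
  L <- nchar(genome[["chr"]])
  hw <- config$window_halfwidth
  alpha <- config$alpha_acetyl
  with_seed_restored(config$seed + 2L, {
    p_tss <- config$tss_bias_p0 * (1 - alpha)
    targeted <- stats::runif(config$n_sites) < p_tss
    summit <- integer(config$n_sites)
    n_t <- sum(targeted)
    if (n_t > 0) {
      anchor <- tss$position[sample.int(nrow(tss), n_t, replace = TRUE)]
      summit[targeted] <- anchor + sample(-50:50, n_t, replace = TRUE)
    }
    summit[!targeted] <- sample.int(L, config$n_sites - n_t) - 1L
    summit <- pmin(pmax(summit, 0L), L - 1L)
    win_lo <- pmax(summit - hw, 0L)
    win_hi <- pmin(summit + hw + 1L, L)
    at <- at_fraction(substring(genome[["chr"]], win_lo + 1L, win_hi))
    r <- config$beta_spec * (1 - alpha) * pmax(0, at - config$background_at) +
      config$r_nonspecific * (1 + config$kappa * alpha) +
      stats::rnorm(config$n_sites, 0, config$noise_sd)
    called <- !is.na(r) & r >= config$call_threshold
    if (!any(called))
      stop_fmt("no site reached call_threshold = %g; lower it or raise beta_spec",
               config$call_threshold)
    sites <- data.frame(site = seq_len(config$n_sites), summit = summit,
                        at_frac = at, recruitment = r,
                        tss_targeted = targeted, called = called)
    pw <- config$peak_halfwidth
    cs <- summit[called]
    start <- pmax(cs - pw, 0L)
    end <- pmin(cs + pw + 1L, L)
    peaks <- peak_set(sprintf("alpha_%g", alpha), data.frame(
      contig = "chr", start = start, end = end,
      name = sprintf("p%04d", which(called)),
      summit_offset = cs - start, recruitment = r[called],
      stringsAsFactors = FALSE))
    s_true <- if (alpha < 1) 1 / (config$beta_spec * (1 - alpha)) else NA_real_
    truth <- structure(list(islands = islands, tss = tss, sites = sites,
                            s_true = s_true, alpha_acetyl = alpha,
                            config = config),
                       class = "sim_truth")
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate a coverage track from called peaks
#'
#' Constant floor depth plus, per peak, a symmetric triangular bump
#' centered at the summit with apex `cov_gain * recruitment`; overlapping
#' bumps add.
#'
#' @param peaks A [peak_set()].
#' @param config A [sim_config()] (supplies genome length, floor, gain and
#'   bump halfwidth).
#' @return A [coverage_track()] spanning the whole contig.
#' @export
simulate_coverage <- function(peaks, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  depth <- rep(config$cov_floor, L)
  p <- peaks$peaks
  w <- config$peak_halfwidth
  if (nrow(p)) {
    summit <- p$start + p$summit_offset
    for (i in seq_len(nrow(p))) {
      lo <- max(summit[i] - w, 0L); hi <- min(summit[i] + w, L - 1L)
      off <- abs((lo:hi) - summit[i])
      depth[(lo:hi) + 1L] <- depth[(lo:hi) + 1L] +
        config$cov_gain * p$recruitment[i] * (1 - off / (w + 1))
    }
  }
  r <- rle(depth)
  end <- cumsum(r$lengths)
  coverage_track(data.frame(contig = "chr", start = c(0L, end[-length(end)]),
                            end = end, depth = r$values))
}

#' Simulate a Ct table with programmed fold changes
#'
#' In `"expression"` mode each row of `fold_changes` (`target`,
#' `condition`, `fold`) yields `n_reps` replicate Ct values
#' `ct = ct_base - log2(fold) + N(0, ct_noise)`; the reference gene
#' (`dnaA` analogue) is added with fold 1 in every condition, so folds are
#' relative to the calibrator condition where the programmed fold is 1.
#' In `"chip"` mode input-fraction Cts sit at the target's base Ct and IP
#' Cts at `base - log2(fold)`, so the dnaA-normalized enrichment ratio
#' equals the programmed fold.
#'
#' @param fold_changes data.frame with columns `target`, `condition`,
#'   `fold` (> 0).
#' @param config A [sim_config()].
#' @param mode `"expression"` or `"chip"`.
#' @param reference Reference target id (default `"dnaA"`).
#' @return data.frame with columns `target`, `condition`, `fraction`,
#'   `replicate`, `ct`.
#' @export
simulate_ct <- function(fold_changes, config, mode = c("expression", "chip"),
                        reference = "dnaA") {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  fc <- as.data.frame(fold_changes)
  if (any(fc$fold <= 0)) stop_fmt("programmed folds must be > 0")
  if (reference %in% fc$target)
    stop_fmt("reference target %s must not carry a programmed fold", reference)
  conds <- unique(fc$condition)
  fc <- rbind(fc, data.frame(target = reference, condition = conds, fold = 1))
  targets <- unique(fc$target)
  base_ct <- config$ct_ref + 0.7 * (match(fc$target, targets) - 1L)
  with_seed_restored(config$seed + 3L, {
    reps <- seq_len(config$n_reps)
    expand <- fc[rep(seq_len(nrow(fc)), each = config$n_reps), ]
    base <- rep(base_ct, each = config$n_reps)
    noise <- function(n) stats::rnorm(n, 0, config$ct_noise)
    if (mode == "expression") {
      out <- data.frame(target = expand$target, condition = expand$condition,
                        fraction = "sample",
                        replicate = rep(reps, nrow(fc)),
                        ct = base - log2(expand$fold) + noise(nrow(expand)))
    } else {
      inp <- data.frame(target = expand$target, condition = expand$condition,
                        fraction = "input", replicate = rep(reps, nrow(fc)),
                        ct = base + noise(nrow(expand)))
      ip <- data.frame(target = expand$target, condition = expand$condition,
                       fraction = "IP", replicate = rep(reps, nrow(fc)),
                       ct = base - log2(expand$fold) + noise(nrow(expand)))
      out <- rbind(inp, ip)
    }
    rownames(out) <- NULL
    out
  })
}
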