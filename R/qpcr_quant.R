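# Delta-delta-Ct calculators: ChIP-qPCR enrichment normalized to a
# nonspecific reference locus, and qRT-PCR relative expression against a
# housekeeping reference gene and calibrator condition.

check_ct_table <- function(table, need_fraction) {
  need <- c("target", "condition", "replicate", "ct")
  if (need_fraction) need <- c(need, "fraction")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop_fmt("Ct table missing column(s): %s",
                             paste(miss, collapse = ", "))
  if (any(table$ct <= 0)) stop_fmt("Ct values must be > 0")
  invisible(table)
}

mean_ct <- function(table, target, condition, fraction = NULL) {
  sel <- table$target == target & table$condition == condition
  if (!is.null(fraction)) sel <- sel & table$fraction == fraction
  if (!any(sel)) return(NA_real_)
  mean(table$ct[sel])
}

#' ChIP-qPCR enrichment by the delta-delta-Ct method
#'
#' Per target and condition, `dCt = mean Ct(IP) - mean Ct(input)`
#' (replicate means before differencing) and the enrichment ratio is
#' `2^-(dCt(target) - dCt(reference))`, i.e. fold enrichment over the
#' nonspecific reference locus (a `dnaA` intragenic region by default).
#' Per-replicate ratios (pairing replicates by index against the
#' reference's mean dCt) are emitted for dispersion.
#'
#' @param table Ct table: columns `target`, `condition`, `fraction`
#'   (`"input"`/`"IP"`), `replicate`, `ct`.
#' @param reference Reference target (default `"dnaA"`).
#' @return data.frame with one row per (target, condition): `target`,
#'   `condition`, `dct`, `ddct`, `ratio`, plus `ratio_sd` over the
#'   per-replicate ratios. The reference target's own ratio is 1 by
#'   construction.
#' @export
chip_enrichment <- function(table, reference = "dnaA") {
  check_ct_table(table, need_fraction = TRUE)
  if (!reference %in% table$target)
    stop_fmt("reference target %s absent from the Ct table", reference)
  combos <- unique(table[, c("target", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tg <- combos$target[i]; cd <- combos$condition[i]
    ip <- mean_ct(table, tg, cd, "IP")
    inp <- mean_ct(table, tg, cd, "input")
    rip <- mean_ct(table, reference, cd, "IP")
    rinp <- mean_ct(table, reference, cd, "input")
    if (anyNA(c(ip, inp, rip, rinp)))
      stop_fmt("missing input/IP fraction for target %s or reference %s in condition %s",
               tg, reference, cd)
    dct <- ip - inp
    dct_ref <- rip - rinp
    sel_ip <- table$target == tg & table$condition == cd & table$fraction == "IP"
    sel_in <- table$target == tg & table$condition == cd & table$fraction == "input"
    rep_ids <- intersect(table$replicate[sel_ip], table$replicate[sel_in])
    rep_ratio <- vapply(rep_ids, function(rr)
      2^-((table$ct[sel_ip & table$replicate == rr] -
           table$ct[sel_in & table$replicate == rr]) - dct_ref), numeric(1))
    data.frame(target = tg, condition = cd, dct = dct,
               ddct = dct - dct_ref, ratio = 2^-(dct - dct_ref),
               ratio_sd = if (length(rep_ratio) > 1)
                 stats::sd(rep_ratio) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the comparative delta-delta-Ct method
#'
#' `dCt = mean Ct(target) - mean Ct(reference)` within each condition;
#' `ddCt = dCt(condition) - dCt(calibrator)`; fold change `= 2^-ddCt`.
#' The reference gene's own fold is 1 in every condition and the
#' calibrator condition's folds are 1 by construction.
#'
#' @param table Ct table: columns `target`, `condition`, `replicate`,
#'   `ct` (a `fraction` column, if present, is ignored).
#' @param reference Housekeeping reference gene (default `"dnaA"`).
#' @param calibrator_condition Condition all folds are expressed against.
#' @return data.frame `target`, `condition`, `dct`, `ddct`, `fold`.
#' @export
relative_expression <- function(table, reference = "dnaA",
                                calibrator_condition) {
  check_ct_table(table, need_fraction = FALSE)
  if (!reference %in% table$target)
    stop_fmt("reference target %s absent from the Ct table", reference)
  if (!calibrator_condition %in% table$condition)
    stop_fmt("calibrator condition %s absent from the Ct table",
             calibrator_condition)
  combos <- unique(table[, c("target", "condition")])
  dct <- vapply(seq_len(nrow(combos)), function(i) {
    tg <- combos$target[i]; cd <- combos$condition[i]
    tm <- mean_ct(table, tg, cd)
    rm_ <- mean_ct(table, reference, cd)
    if (anyNA(c(tm, rm_)))
      stop_fmt("reference %s missing in condition %s", reference, cd)
    tm - rm_
  }, numeric(1))
  cal <- stats::setNames(dct, paste(combos$target, combos$condition))
  ddct <- dct - cal[paste(combos$target, calibrator_condition)]
  if (anyNA(ddct))
    stop_fmt("calibrator condition %s lacks some targets",
             calibrator_condition)
  data.frame(target = combos$target, condition = combos$condition,
             dct = dct, ddct = unname(ddct), fold = unname(2^-ddct),
             stringsAsFactors = FALSE)
}
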