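# Readers and writers for the on-disk formats the pipeline touches.
# All coordinates are 0-based half-open internally; BED/narrowPeak/bedGraph
# already use that convention on disk, so no shifting happens at the border.

#' Construct a genome sequence object
#'
#' A genome is a named character vector of uppercase DNA strings over the
#' alphabet `{A,C,G,T,N}`, one element per contig.
#'
#' @param contigs Named character vector of DNA sequences.
#' @return An object of class `genome_sequence`.
#' @export
genome_sequence <- function(contigs) {
  if (length(contigs) == 0L) stop_fmt("genome must contain at least one contig")
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_fmt("every contig needs a non-empty id")
  if (anyDuplicated(ids))
    stop_fmt("duplicate contig id: %s", ids[duplicated(ids)][1L])
  contigs <- toupper(contigs)
  if (any(!nzchar(contigs))) stop_fmt("contig %s has an empty sequence",
                                      ids[!nzchar(contigs)][1L])
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop_fmt("contig %s contains characters outside {A,C,G,T,N}", ids[bad][1L])
  structure(stats::setNames(as.character(contigs), ids),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d contig(s), %d bp total\n",
              length(x), sum(nchar(x))))
  invisible(x)
}

#' Extract a genomic slice
#'
#' @param genome A [genome_sequence()].
#' @param contig Contig id.
#' @param start,end 0-based half-open coordinates.
#' @return A character string of exactly `end - start` bases.
#' @export
genome_slice <- function(genome, contig, start, end) {
  if (!contig %in% names(genome))
    stop_fmt("contig %s not present in genome", contig)
  len <- nchar(genome[[contig]])
  if (start < 0 || end > len || start >= end)
    stop_fmt("slice [%d,%d) out of range for contig %s (length %d)",
             start, end, contig, len)
  substr(genome[[contig]], start + 1L, end)
}

#' Read a FASTA genome
#'
#' Sequences are uppercased; IUPAC ambiguity codes and any other character
#' outside `{A,C,G,T,N}` are collapsed to `N` (count reported via a message).
#' Contig ids are the first whitespace-delimited token of each header and
#' must be unique.
#'
#' @param path FASTA file.
#' @return A [genome_sequence()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop_fmt("not valid FASTA (%s): %s",
                                                path, conditionMessage(e)))
  if (length(seqs) == 0L) stop_fmt("FASTA file %s contains no records", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_fmt("duplicate contig header in %s: %s", path,
             ids[duplicated(ids)][1L])
  x <- toupper(as.character(seqs))
  n_sub <- sum(vapply(gregexpr("[^ACGTN]", x),
                      function(m) if (m[1L] == -1L) 0L else length(m),
                      integer(1)))
  if (n_sub > 0) {
    x <- gsub("[^ACGTN]", "N", x)
    message(sprintf("read_fasta: %d non-ACGTN character(s) mapped to N", n_sub))
  }
  genome_sequence(stats::setNames(x, ids))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence()].
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a peak set
#'
#' @param label Condition/variant tag (e.g. `"H-NS_LB"`).
#' @param peaks data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `name`, `summit_offset` (0-based offset from `start`),
#'   `recruitment` (fold enrichment, > 0).
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(label, peaks) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_fmt("peak set label must be a non-empty string")
  need <- c("contig", "start", "end", "name", "summit_offset", "recruitment")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop_fmt("peaks missing column(s): %s",
                             paste(miss, collapse = ", "))
  peaks <- as.data.frame(peaks)[need]
  if (nrow(peaks)) {
    if (any(peaks$start < 0 | peaks$end <= peaks$start))
      stop_fmt("peak intervals must satisfy 0 <= start < end")
    if (any(peaks$summit_offset < 0 |
            peaks$summit_offset >= peaks$end - peaks$start))
      stop_fmt("summit_offset must lie within the peak interval")
    if (any(peaks$recruitment <= 0))
      stop_fmt("recruitment (fold enrichment) must be > 0")
    if (anyDuplicated(peaks$name))
      stop_fmt("duplicate peak name: %s", peaks$name[duplicated(peaks$name)][1L])
  }
  rownames(peaks) <- NULL
  structure(list(label = label, peaks = peaks), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peak(s)", x$label, nrow(x$peaks)))
  if (nrow(x$peaks))
    cat(sprintf(", recruitment %.3g-%.3g", min(x$peaks$recruitment),
                max(x$peaks$recruitment)))
  cat("\n")
  invisible(x)
}

#' Absolute summit coordinates of a peak set
#' @param peakset A [peak_set()].
#' @return Integer vector of 0-based summit positions.
#' @export
peak_summits <- function(peakset) {
  peakset$peaks$start + peakset$peaks$summit_offset
}

#' Read ENCODE narrowPeak peak calls
#'
#' Requires the 10-column narrowPeak dialect. `signalValue` (column 7) is
#' taken as the recruitment level (fold enrichment); column 10 is the summit
#' offset from `start`, with `-1` falling back to the interval midpoint.
#' Rows with `signalValue <= 0` are dropped with a reported count.
#'
#' @param path narrowPeak file.
#' @param label Peak-set label; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (ncol(tab) < 10L)
    stop_fmt("%s: narrowPeak requires 10 tab-separated columns, found %d",
             path, ncol(tab))
  start <- as.integer(tab[[2]]); end <- as.integer(tab[[3]])
  if (any(is.na(start) | is.na(end)) || any(end <= start))
    stop_fmt("%s: record with end <= start", path)
  signal <- as.numeric(tab[[7]])
  keep <- signal > 0
  if (any(!keep))
    message(sprintf("read_narrowpeak: %d row(s) with signalValue <= 0 rejected",
                    sum(!keep)))
  summit <- as.integer(tab[[10]])
  mid <- (end - start) %/% 2L
  summit <- ifelse(summit < 0L, mid, summit)
  if (any(summit[keep] >= (end - start)[keep]))
    stop_fmt("%s: summit offset outside its peak interval", path)
  nm <- as.character(tab[[4]])
  nm[!nzchar(nm) | nm == "."] <- paste0("peak", which(!nzchar(nm) | nm == "."))
  if (anyDuplicated(nm[keep])) {
    message("read_narrowpeak: duplicated peak names made unique")
    nm <- make.unique(nm)
  }
  peak_set(label, data.frame(
    contig = as.character(tab[[1]])[keep], start = start[keep],
    end = end[keep], name = nm[keep], summit_offset = summit[keep],
    recruitment = signal[keep], stringsAsFactors = FALSE))
}

#' Write a peak set as narrowPeak
#'
#' @param peakset A [peak_set()].
#' @param path Output file.
#' @export
write_narrowpeak <- function(peakset, path) {
  p <- peakset$peaks
  tab <- data.frame(p$contig, p$start, p$end, p$name, 0L, ".",
                    sprintf("%.15g", p$recruitment), -1, -1, p$summit_offset)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcription start sites from BED6
#'
#' The strand column is mandatory. The TSS position is the 0-based `start`
#' for `+` records and `end - 1` for `-` records (identical for the usual
#' 1-bp intervals).
#'
#' @param path BED6 file.
#' @return data.frame with columns `contig`, `position`, `strand`, `gene`.
#' @export
read_bed_tss <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (ncol(tab) < 6L)
    stop_fmt("%s: TSS BED needs 6 columns (strand missing)", path)
  strand <- as.character(tab[[6]])
  if (any(!strand %in% c("+", "-")))
    stop_fmt("%s: strand column must be + or -", path)
  start <- as.integer(tab[[2]]); end <- as.integer(tab[[3]])
  if (any(end <= start)) stop_fmt("%s: record with end <= start", path)
  data.frame(contig = as.character(tab[[1]]),
             position = ifelse(strand == "+", start, end - 1L),
             strand = strand, gene = as.character(tab[[4]]),
             stringsAsFactors = FALSE)
}

#' Write transcription start sites as BED6
#' @param tss data.frame as returned by [read_bed_tss()].
#' @param path Output file.
#' @export
write_bed_tss <- function(tss, path) {
  tab <- data.frame(tss$contig, tss$position, tss$position + 1L, tss$gene,
                    0L, tss$strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a coverage track
#'
#' Segments are 0-based half-open `(start, end, depth)` runs per contig,
#' sorted and non-overlapping; gaps imply depth 0.
#'
#' @param segments data.frame with columns `contig`, `start`, `end`, `depth`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(segments) {
  need <- c("contig", "start", "end", "depth")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop_fmt("coverage track missing column(s): %s",
                             paste(miss, collapse = ", "))
  seg <- as.data.frame(segments)[need]
  if (nrow(seg)) {
    if (any(seg$end <= seg$start)) stop_fmt("segment with end <= start")
    if (any(seg$depth < 0)) stop_fmt("segment with negative depth")
    seg <- seg[order(seg$contig, seg$start), , drop = FALSE]
    ov <- unlist(tapply(seq_len(nrow(seg)), seg$contig, function(i) {
      if (length(i) < 2L) return(FALSE)
      seg$start[i][-1L] < seg$end[i][-length(i)]
    }), use.names = FALSE)
    if (any(ov)) stop_fmt("overlapping bedGraph segments")
  }
  rownames(seg) <- NULL
  structure(seg, class = c("coverage_track", "data.frame"))
}

#' Read a bedGraph coverage track
#' @param path bedGraph file.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (ncol(tab) < 4L) stop_fmt("%s: bedGraph needs 4 columns", path)
  coverage_track(data.frame(contig = as.character(tab[[1]]),
                            start = as.integer(tab[[2]]),
                            end = as.integer(tab[[3]]),
                            depth = as.numeric(tab[[4]]),
                            stringsAsFactors = FALSE))
}

#' Write a coverage track as bedGraph (sorted)
#' @param track A [coverage_track()].
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  seg <- track[order(track$contig, track$start), , drop = FALSE]
  tab <- data.frame(seg$contig, seg$start, seg$end,
                    sprintf("%.15g", seg$depth))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read a table as TSV with a header row
#'
#' Column order is preserved; `read_tsv(write_tsv(x)) == x` for tables of
#' character and numeric columns.
#'
#' @param table data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "", quote = "")
}
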