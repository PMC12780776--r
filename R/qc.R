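# Assembly summary statistics, telomere detection, QV conversion, contig
# accounting.

#' Assembly summary statistics
#'
#' Contig count, total/mean/longest length, GC fraction over non-N bases,
#' and Nx statistics: with contigs sorted by descending length, Nx is the
#' length of the contig at which the cumulative length first reaches x% of
#' the total, and the contig count at Nx is the number of contigs up to and
#' including it.
#'
#' @param genome a [contig_set()].
#' @return An object of class `assembly_stats` (list).
#' @export
assembly_stats <- function(genome) {
  stopifnot(inherits(genome, "contig_set"), length(genome) >= 1)
  lens <- sort(contig_lengths(genome), decreasing = TRUE)
  total <- sum(lens)
  nx <- function(x) {
    cum <- cumsum(as.numeric(lens))
    i <- which(cum >= x / 100 * total)[1]
    c(length = unname(lens[i]), count = i)
  }
  counts <- vapply(unclass(genome), function(s) {
    v <- strsplit(s, "")[[1]]
    c(gc = sum(v %in% c("G", "C")), acgt = sum(v != "N"))
  }, numeric(2))
  structure(list(
    n_contigs = length(genome),
    total_length = unname(total),
    mean_length = unname(total / length(genome)),
    longest = unname(lens[1]),
    gc = unname(sum(counts["gc", ]) / sum(counts["acgt", ])),
    N50 = nx(50), N70 = nx(70), N90 = nx(90)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly_stats: %d contig(s), %.0f bp total, mean %.2f kb, GC %.1f%%\n",
              x$n_contigs, x$total_length, x$mean_length / 1000, 100 * x$gc))
  for (nm in c("N50", "N70", "N90")) {
    cat(sprintf("  %s = %d bp (n = %d)\n", nm, x[[nm]]["length"], x[[nm]]["count"]))
  }
  invisible(x)
}

# scan a sequence's leading end_window bp for a tandem array of motif
# copies; returns the best run allowing a fraction of divergent copies
.scan_motif_5p <- function(seq, motif, end_window, max_divergence) {
  w <- substring(seq, 1, min(nchar(seq), end_window))
  ml <- nchar(motif)
  best <- list(copies = 0L, span = 0L)
  for (off in 0:(ml - 1)) {
    if (nchar(w) < off + ml) next
    starts <- seq(off + 1L, nchar(w) - ml + 1L, by = ml)
    chunks <- substring(w, starts, starts + ml - 1L)
    is_m <- chunks == motif
    # maximal runs where the divergent-copy fraction stays within bound
    i <- 1L
    while (i <= length(is_m)) {
      if (!is_m[i]) { i <- i + 1L; next }
      j <- i; mism <- 0L; last_match <- i
      while (j < length(is_m)) {
        nxt <- j + 1L
        new_mism <- mism + as.integer(!is_m[nxt])
        if (new_mism / (nxt - i + 1L) > max_divergence) break
        j <- nxt; mism <- new_mism
        if (is_m[j]) last_match <- j
      }
      j <- last_match
      copies <- sum(is_m[i:j])
      if (copies > best$copies) {
        best <- list(copies = copies, span = (j - i + 1L) * ml)
      }
      i <- j + 1L
    }
  }
  best
}

#' Detect telomeric tandem arrays at contig ends
#'
#' Scans the first and last `end_window` bp of each contig for tandem
#' arrays of the telomere motif (5' end) or its reverse complement
#' (3' end), allowing a fraction `max_divergence` of divergent copies
#' within an array. An end is reported when the array holds at least
#' `min_copies` motif copies.
#'
#' @param genome a [contig_set()].
#' @param motif telomere motif (default the hymenopteran repeat `AACCT`).
#' @param min_copies minimum motif copies to call a telomere.
#' @param end_window bp scanned at each contig end.
#' @param max_divergence tolerated fraction of divergent copies in an
#'   array.
#' @return data.frame: contig, end (`5p`/`3p`), copies, span_bp.
#' @export
find_telomeres <- function(genome, motif = "AACCT", min_copies = 25,
                           end_window = 10000, max_divergence = 0.1) {
  stopifnot(inherits(genome, "contig_set"), nchar(motif) >= 2)
  out <- NULL
  for (cid in names(genome)) {
    s <- genome[[cid]]
    hit5 <- .scan_motif_5p(s, motif, end_window, max_divergence)
    if (hit5$copies >= min_copies) {
      out <- rbind(out, data.frame(contig = cid, end = "5p",
                                   copies = hit5$copies, span_bp = hit5$span))
    }
    # the 3' end of the contig is the 5' end of its reverse complement
    hit3 <- .scan_motif_5p(revcomp(s), motif, end_window, max_divergence)
    if (hit3$copies >= min_copies) {
      out <- rbind(out, data.frame(contig = cid, end = "3p",
                                   copies = hit3$copies, span_bp = hit3$span))
    }
  }
  if (is.null(out)) {
    out <- data.frame(contig = character(), end = character(),
                      copies = integer(), span_bp = integer())
  }
  out
}

#' Mean contig length in kilobases
#'
#' Summary-report arithmetic: total assembly span over contig count,
#' reported in kb to two decimals.
#' @param total_bp total assembly length in bp.
#' @param n_contigs contig count (>= 1).
#' @return Numeric scalar, kb.
#' @export
contig_mean_length_kb <- function(total_bp, n_contigs) {
  stopifnot(n_contigs >= 1, total_bp >= 0)
  round(total_bp / n_contigs / 1000, 2)
}

#' Convert a Phred-scaled consensus QV to a per-base error rate
#'
#' `error = 10^(-qv/10)`; the reciprocal is also reported rounded to the
#' nearest 1,000 as the familiar "1 error in N bases".
#'
#' @param qv Phred-scaled quality value (>= 0).
#' @return list: `error_rate`, `one_in` (N rounded to the nearest 1000;
#'   unrounded below 1000).
#' @export
qv_to_error_rate <- function(qv) {
  stopifnot(qv >= 0)
  err <- 10^(-qv / 10)
  n <- 1 / err
  list(error_rate = err,
       one_in = if (n >= 1000) round(n / 1000) * 1000 else n)
}

#' Contig accounting across assembly post-processing
#'
#' @param initial contig count of the raw assembly.
#' @param purged contigs removed as duplicate haplotigs.
#' @param mito_removed contigs removed as mitochondrial.
#' @return list: `final` count and a human-readable `ledger` line.
#' @export
contig_accounting <- function(initial, purged = 0, mito_removed = 0) {
  stopifnot(initial >= 0, purged >= 0, mito_removed >= 0)
  final <- initial - purged - mito_removed
  if (final < 0) {
    stop("contig accounting is negative: ", initial, " - ", purged, " - ",
         mito_removed)
  }
  list(final = final,
       ledger = sprintf("%d contigs - %d purged haplotigs - %d mitochondrial = %d",
                        initial, purged, mito_removed, final))
}
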