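# Synthetic base-modification pileups at CpG sites.

# 0-based positions of CpG cytosines on both strands of one sequence:
# plus-strand record at the C of each CG, minus-strand record at the G.
.cpg_positions <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(pos = integer(0), strand = character(0)))
  }
  data.frame(pos = c(m - 1L, m), strand = rep(c("+", "-"), each = length(m)))
}

#' Methylation site table
#'
#' Per-cytosine pileup records in the layout of a bedMethyl-style pileup:
#' one row per (contig, position, strand, modification code), carrying the
#' number of reads with a valid modification call (`valid_coverage`) and the
#' number of those calling the base modified (`modified_count`). Codes are
#' `m` (5mC) and `h` (5hmC), both in CpG context here.
#'
#' @param df data.frame with columns `contig`, `pos` (0-based), `strand`,
#'   `mod_code`, `valid_coverage`, `modified_count`.
#' @return The data.frame with class `methyl_site_table`.
#' @export
methyl_site_table <- function(df) {
  need <- c("contig", "pos", "strand", "mod_code", "valid_coverage", "modified_count")
  if (!all(need %in% names(df))) {
    stop("methyl_site_table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$modified_count > df$valid_coverage)) {
    stop("modified_count must not exceed valid_coverage")
  }
  if (any(df$modified_count < 0) || any(df$valid_coverage < 0)) {
    stop("counts must be non-negative")
  }
  key <- paste(df$contig, df$pos, df$strand, df$mod_code)
  if (anyDuplicated(key)) stop("duplicate (contig, pos, strand, mod_code) records")
  class(df) <- c("methyl_site_table", "data.frame")
  df
}

#' Generate a synthetic CpG methylation pileup
#'
#' Emits one record per cytosine of every CpG dinucleotide (both strands,
#' two records per CpG) and per modification code (`m`, `h`). Site-level
#' methylation states are planted per feature class of the
#' exon/intron/intergenic partition: a site becomes *highly* methylated with
#' probability `high_rate` (modified reads drawn to exceed 20% of coverage)
#' or *weakly-only* methylated with probability `weak_rate - high_rate`
#' (exactly one modified read), so the expected fraction of weak sites per
#' class equals `weak_rate` and of high sites `high_rate`.
#'
#' @param genome a `synthetic_genome` (or list with `contigs` and `features`).
#' @param rates named list per class (`exon`, `intron`, `intergenic`); each
#'   element a list/vector of per-code rates:
#'   `list(m = c(weak, high), h = c(weak, high))`.
#' @param depth mean valid coverage (Poisson).
#' @param seed integer seed.
#' @return A [methyl_site_table()].
#' @export
generate_methylation_pileup <- function(genome,
                                        rates = list(
                                          exon = list(m = c(0.025, 0.005), h = c(0.018, 0.002)),
                                          intron = list(m = c(0.009, 0.002), h = c(0.011, 0.002)),
                                          intergenic = list(m = c(0.010, 0.002), h = c(0.012, 0.002))),
                                        depth = 30, seed = 1) {
  stopifnot(depth >= 1)
  for (cls in names(rates)) {
    v <- unlist(rates[[cls]])
    if (any(v < 0) || any(v > 1)) stop("rates must be in [0, 1]")
  }
  .seed_rng(.child_seed(seed, "methylation"))
  contigs <- genome$contigs
  feats <- genome$features
  recs <- NULL
  for (cid in names(contigs)) {
    cp <- .cpg_positions(contigs[[cid]])
    if (nrow(cp) == 0) next
    cls <- rep("intergenic", nrow(cp))
    in_ex <- .positions_in_track(feature_track(feats, "exon"), rep(cid, nrow(cp)), cp$pos)
    in_in <- .positions_in_track(feature_track(feats, "intron"), rep(cid, nrow(cp)), cp$pos)
    cls[in_in] <- "intron"
    cls[in_ex] <- "exon"
    for (code in c("m", "h")) {
      cov <- stats::rpois(nrow(cp), depth)
      wk <- vapply(cls, function(k) {
        r <- rates[[k]]
        if (is.null(r)) 0 else unlist(r[[code]])[1]
      }, numeric(1))
      hi <- vapply(cls, function(k) {
        r <- rates[[k]]
        if (is.null(r)) 0 else unlist(r[[code]])[2]
      }, numeric(1))
      u <- stats::runif(nrow(cp))
      modc <- integer(nrow(cp))
      is_hi <- u < hi & cov > 0
      is_wk <- !is_hi & u < wk & cov > 0
      # high sites: at least 20% of reads modified
      modc[is_hi] <- pmax(ceiling(0.2 * cov[is_hi]),
                          stats::rbinom(sum(is_hi), cov[is_hi], 0.6))
      # weakly-only sites: one modified read (below 20% at typical depth)
      modc[is_wk] <- 1L
      recs <- rbind(recs, data.frame(contig = cid, pos = cp$pos,
                                     strand = cp$strand, mod_code = code,
                                     valid_coverage = cov, modified_count = modc))
    }
  }
  if (is.null(recs)) {
    recs <- data.frame(contig = character(0), pos = integer(0),
                       strand = character(0), mod_code = character(0),
                       valid_coverage = integer(0), modified_count = integer(0))
  }
  recs <- recs[order(recs$contig, recs$pos, recs$strand, recs$mod_code), ]
  rownames(recs) <- NULL
  methyl_site_table(recs)
}

#' Write / read a bedMethyl-style pileup TSV
#'
#' Columns: contig, start (0-based), end, mod code, valid coverage,
#' modified count, strand.
#' @param x a [methyl_site_table()].
#' @param path file path.
#' @return `path` (write) / a `methyl_site_table` (read).
#' @export
write_bedmethyl <- function(x, path) {
  out <- data.frame(x$contig, x$pos, x$pos + 1L, x$mod_code,
                    x$valid_coverage, x$modified_count, x$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedmethyl
#' @export
read_bedmethyl <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "mod_code",
                                        "valid_coverage", "modified_count", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "integer",
                                         "character"))
  methyl_site_table(data.frame(contig = df$contig, pos = df$start,
                               strand = df$strand, mod_code = df$mod_code,
                               valid_coverage = df$valid_coverage,
                               modified_count = df$modified_count))
}
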