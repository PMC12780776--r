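# Variant filtering and effect classification.

#' Filter a raw variant table
#'
#' Applies the hard site filters in a fixed order — indel removal, minimum
#' QUAL, mean-depth range, missing-genotype fraction — and reports how many
#' sites each rule removed (a site failing several rules is counted once,
#' under the first failing rule). Mean depth is taken across samples with a
#' called genotype (`--min-meanDP` semantics); QUAL and depth bounds are
#' inclusive.
#'
#' @param vt a [variant_table()].
#' @param min_qual minimum site QUAL.
#' @param mean_depth_range inclusive `[low, high]` bounds on mean depth.
#' @param max_missing_frac maximum fraction of samples with missing
#'   genotype.
#' @param drop_indels remove non-SNV records.
#' @return list: `variants` (filtered [variant_table()]) and `report`
#'   (data.frame of per-rule removal counts; input = kept + removals).
#' @export
filter_variants <- function(vt, min_qual = 40, mean_depth_range = c(5, 500),
                            max_missing_frac = 0.20, drop_indels = TRUE) {
  stopifnot(inherits(vt, "variant_table"))
  if (length(vt$samples) == 0) stop("variant table has no samples")
  n <- nrow(vt$sites)
  miss <- vt$gt == "./."
  mean_dp <- vapply(seq_len(n), function(i) {
    ok <- !miss[i, ]
    if (!any(ok)) return(NA_real_)
    mean(vt$dp[i, ok])
  }, numeric(1))
  miss_frac <- rowMeans(miss)
  indel <- .is_indel(vt$sites)

  reason <- rep(NA_character_, n)
  if (drop_indels) reason[is.na(reason) & indel] <- "indel"
  reason[is.na(reason) & vt$sites$qual < min_qual] <- "qual"
  depth_bad <- is.na(mean_dp) | mean_dp < mean_depth_range[1] |
    mean_dp > mean_depth_range[2]
  reason[is.na(reason) & depth_bad] <- "depth"
  reason[is.na(reason) & miss_frac > max_missing_frac] <- "missing"
  keep <- is.na(reason)

  out <- variant_table(vt$sites[keep, , drop = FALSE],
                       vt$gt[keep, , drop = FALSE],
                       vt$dp[keep, , drop = FALSE],
                       vt$samples, vt$contig_lengths)
  report <- data.frame(
    rule = c("input", "indel", "qual", "depth", "missing", "kept"),
    sites = c(n, sum(reason == "indel", na.rm = TRUE),
              sum(reason == "qual", na.rm = TRUE),
              sum(reason == "depth", na.rm = TRUE),
              sum(reason == "missing", na.rm = TRUE), sum(keep)))
  list(variants = out, report = report,
       removed = data.frame(variant_id = vt$sites$variant_id[!keep],
                            reason = reason[!keep]))
}

.EFFECT_SEVERITY <- c("nonsense", "splice_site", "missense", "synonymous",
                      "intron", "upstream", "downstream", "intergenic")

# per-transcript structures cached for effect classification
.tx_index <- function(genes, genome) {
  lapply(genes$transcripts$transcript_id, function(t) {
    row <- genes$transcripts[genes$transcripts$transcript_id == t, ]
    ex <- genes$exons[genes$exons$transcript_id == t, , drop = FALSE]
    cd <- genes$cds[genes$cds$transcript_id == t, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    list(transcript_id = t, gene_id = row$gene_id, contig = row$contig,
         strand = row$strand,
         span = c(min(ex$start), max(ex$end)),
         exons = ex[order(ex$start), c("start", "end"), drop = FALSE],
         cds = cd,
         cds_seq = spliced_cds(genes, t, genome))
  })
}

# CDS offset (translation order, 0-based) of genomic position pos0, or NA
.cds_offset <- function(txi, pos0) {
  cd <- txi$cds
  hit <- which(cd$start <= pos0 & pos0 < cd$end)
  if (length(hit) == 0) return(NA_integer_)
  lens <- cd$end - cd$start
  plus_off <- sum(lens[seq_len(hit - 1)]) + (pos0 - cd$start[hit])
  if (txi$strand == "+") plus_off else sum(lens) - 1L - plus_off
}

#' Classify variant effects against a gene model set
#'
#' Coding SNVs are classified by substituting the alternate base into the
#' reference codon of each overlapping transcript (strand aware, standard
#' code): same amino acid — synonymous; different, non-stop — missense;
#' gain of stop — nonsense. Variants inside the first or last
#' `splice_window` bp of an intron are splice-site; other intronic variants
#' are intronic; variants within `flank` bp of a gene are
#' upstream/downstream of it by strand; everything else is intergenic.
#' The variant-level effect is the most severe across transcripts.
#'
#' @param vt a filtered [variant_table()] of SNVs.
#' @param genes a cleaned [gene_model_set()].
#' @param genome a [contig_set()].
#' @param flank up/downstream flank in bp.
#' @param splice_window intronic bp at each intron end treated as splice
#'   site.
#' @return data.frame: variant_id, effect, gene_id, transcript_id (of the
#'   most severe effect; NA outside genes).
#' @export
classify_effects <- function(vt, genes, genome, flank = 5000, splice_window = 2) {
  stopifnot(inherits(vt, "variant_table"))
  if (any(.is_indel(vt$sites))) stop("classify_effects expects SNVs only")
  idx <- .tx_index(genes, genome)
  by_contig <- split(seq_along(idx),
                     vapply(idx, `[[`, character(1), "contig"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nrow(vt$sites)
  effect <- character(n); gene <- rep(NA_character_, n); txid <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ctg <- vt$sites$contig[i]
    pos0 <- vt$sites$pos[i] - 1L
    ref <- vt$sites$ref[i]
    alt <- strsplit(vt$sites$alt[i], ",")[[1]][1]
    gbase <- contig_subseq(genome, ctg, pos0, pos0 + 1L)
    if (gbase != ref) {
      stop("variant ", vt$sites$variant_id[i], " ref allele ", ref,
           " disagrees with genome base ", gbase, " at ", ctg, ":", pos0 + 1L)
    }
    best <- "intergenic"; bg <- NA_character_; bt <- NA_character_
    consider <- function(e, g, t) {
      if (match(e, .EFFECT_SEVERITY) < match(best, .EFFECT_SEVERITY)) {
        best <<- e; bg <<- g; bt <<- t
      }
    }
    for (k in by_contig[[ctg]] %||0% integer(0)) {
      txi <- idx[[k]]
      if (pos0 >= txi$span[1] && pos0 < txi$span[2]) {
        off <- .cds_offset(txi, pos0)
        if (!is.na(off)) {
          ref_s <- if (txi$strand == "+") ref else unname(comp[ref])
          alt_s <- if (txi$strand == "+") alt else unname(comp[alt])
          if (substring(txi$cds_seq, off + 1, off + 1) != ref_s) {
            stop("variant ", vt$sites$variant_id[i],
                 " is inconsistent with the spliced CDS of ", txi$transcript_id)
          }
          j <- off %/% 3L
          codon <- substring(txi$cds_seq, j * 3 + 1, j * 3 + 3)
          alt_codon <- codon
          substring(alt_codon, off %% 3 + 1, off %% 3 + 1) <- alt_s
          ref_aa <- .aa(codon); alt_aa <- .aa(alt_codon)
          e <- if (alt_aa == ref_aa) "synonymous"
               else if (alt_aa == "*" && ref_aa != "*") "nonsense"
               else "missense"
          consider(e, txi$gene_id, txi$transcript_id)
        } else {
          # intronic (or non-coding exonic; the models here are CDS-only)
          ex <- txi$exons
          splice <- FALSE
          if (nrow(ex) > 1) {
            istart <- ex$end[-nrow(ex)]; iend <- ex$start[-1]
            inside <- istart <= pos0 & pos0 < iend
            if (any(inside)) {
              s <- istart[inside][1]; e2 <- iend[inside][1]
              splice <- pos0 < s + splice_window || pos0 >= e2 - splice_window
            }
          }
          consider(if (splice) "splice_site" else "intron",
                   txi$gene_id, txi$transcript_id)
        }
      } else if (pos0 >= txi$span[1] - flank && pos0 < txi$span[2] + flank) {
        before <- pos0 < txi$span[1]
        e <- if ((before && txi$strand == "+") || (!before && txi$strand == "-")) {
          "upstream"
        } else {
          "downstream"
        }
        consider(e, txi$gene_id, txi$transcript_id)
      }
    }
    effect[i] <- best; gene[i] <- bg; txid[i] <- bt
  }
  data.frame(variant_id = vt$sites$variant_id, effect = effect,
             gene_id = gene, transcript_id = txid)
}
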