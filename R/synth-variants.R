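# Synthetic multi-sample variant tables with planted effects, filter
# artifacts, and block-structured linkage disequilibrium.

#' Variant table
#'
#' Multi-sample SNV/indel records: site fields (contig, 1-based position,
#' ref, alt — comma-separated when multiallelic — and QUAL) plus per-sample
#' genotype (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`, higher allele indices for
#' multiallelic sites) and per-sample depth matrices. Contig lengths are
#' carried so that windowed estimators can count callable (including
#' invariant) sites; the generator emits fully callable contigs.
#'
#' @param sites data.frame with columns `variant_id`, `contig`, `pos`,
#'   `ref`, `alt`, `qual`.
#' @param gt character matrix, sites x samples.
#' @param dp integer matrix, sites x samples.
#' @param samples character vector of sample ids.
#' @param contig_lengths named integer vector.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp, samples, contig_lengths) {
  stopifnot(nrow(gt) == nrow(sites), nrow(dp) == nrow(sites),
            ncol(gt) == length(samples), ncol(dp) == length(samples))
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (!all(sites$contig %in% names(contig_lengths))) {
    stop("sites reference unknown contigs")
  }
  if (any(sites$pos < 1) || any(sites$pos > contig_lengths[sites$contig])) {
    stop("site positions outside contig bounds")
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp, samples = samples,
                 contig_lengths = contig_lengths),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "site(s),", length(x$samples),
      "sample(s),", length(x$contig_lengths), "contig(s)\n")
  invisible(x)
}

#' Number of variant sites
#' @param x a `variant_table`.
#' @return Integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

.is_indel <- function(sites) {
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  nchar(sites$ref) != 1L |
    vapply(alts, function(a) any(nchar(a) != 1L), logical(1))
}

.is_multiallelic <- function(sites) grepl(",", sites$alt, fixed = TRUE)

# allele-frequency-spectrum draw of a derived-allele count in 1..(n-1),
# probability proportional to 1/k (neutral expectation)
.sfs_draw <- function(n_hap, size = 1) {
  k <- seq_len(n_hap - 1)
  sample(k, size, replace = TRUE, prob = 1 / k)
}

# genotype strings from a haplotype carrier set
.gt_from_carriers <- function(carriers, n_samples, alt_index = 1) {
  h1 <- (seq_len(n_samples) * 2L - 1L) %in% carriers
  h2 <- (seq_len(n_samples) * 2L) %in% carriers
  paste(ifelse(h1, alt_index, 0L), ifelse(h2, alt_index, 0L), sep = "/")
}

# spliced sense CDS of a planted locus (primary transcript)
.locus_cds_seq <- function(genome, l) {
  iv <- .map_ivs(l$orf_exons, l$start, l$locus_len, l$strand)
  s <- paste(vapply(seq_len(nrow(iv)), function(i) {
    contig_subseq(genome$contigs, l$contig, iv[i, 1], iv[i, 2])
  }, character(1)), collapse = "")
  if (l$strand == "-") revcomp(s) else s
}

# genomic 0-based position and (genome-strand ref, alt) for a sense CDS
# offset p and sense alt base
.sense_to_genomic <- function(l, p, alt_sense) {
  lens <- l$orf_exons[, 2] - l$orf_exons[, 1]
  cum <- c(0L, cumsum(lens))
  i <- findInterval(p, cum, rightmost.closed = FALSE) # exon index, cum[i] <= p < cum[i+1]
  q <- l$orf_exons[i, 1] + (p - cum[i])               # sense locus coordinate
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (l$strand == "+") {
    list(pos0 = l$start + q, alt = alt_sense)
  } else {
    list(pos0 = l$start + l$locus_len - q - 1L, alt = unname(comp[alt_sense]))
  }
}

.GEN_CODE <- NULL
.aa <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  unname(code[codon])
}

#' Generate a synthetic multi-sample variant table with planted truth
#'
#' Plants three kinds of sites: (i) background polymorphisms at a per-class
#' diversity level `theta` (expected segregating sites per class follow
#' Watterson's relation `E[S] = theta * a_{n-1} * L`), with allele
#' frequencies drawn from the neutral 1/k spectrum; (ii) coding/splice
#' variants of requested effect classes, chosen by inspecting the planted
#' ORFs so the true effect is known; and (iii) filter artifacts (low QUAL,
#' out-of-range depth, excess missingness, indels) that the variant filters
#' must remove. When `ld_block > 0`, all background sites within one
#' `ld_block`-sized window share a single haplotype carrier set (maximal
#' LD), and blocks are independent.
#'
#' @param genome a `synthetic_genome`.
#' @param theta named per-class diversity (per site) for classes of the
#'   exon/intron/intergenic partition.
#' @param n_samples diploid sample count (>= 2).
#' @param effect_counts named counts of planted effects among
#'   `synonymous`, `missense`, `nonsense`, `splice_site`.
#' @param artifacts named counts: `low_qual`, `bad_depth`, `high_missing`,
#'   `indel`, `multiallelic`.
#' @param ld_block bp size of maximal-LD blocks (0 = independent sites).
#' @param depth mean per-sample read depth.
#' @param missing_prob per-site probability that one sample genotype is
#'   missing (kept at or below the 20% missingness filter).
#' @param seed integer seed.
#' @return list with `variants` (a [variant_table()]) and `ledger`
#'   (data.frame: kind, variant_id, detail; effect plants carry
#'   `effect:<class>`, artifact plants `filtered_out:<rule>`, background
#'   sites `background:<class>`).
#' @export
generate_variants <- function(genome,
                              theta = c(exon = 0.0006, intron = 0.0017,
                                        intergenic = 0.0012),
                              n_samples = 10,
                              effect_counts = c(synonymous = 0, missense = 0,
                                                nonsense = 0, splice_site = 0),
                              artifacts = c(low_qual = 0, bad_depth = 0,
                                            high_missing = 0, indel = 0,
                                            multiallelic = 0),
                              ld_block = 0, depth = 19, missing_prob = 0.1,
                              seed = 1) {
  stopifnot(n_samples >= 2, all(theta >= 0), depth >= 1)
  .seed_rng(.child_seed(seed, "variants"))
  contigs <- genome$contigs
  lens <- contig_lengths(contigs)
  n_hap <- 2L * n_samples
  a_n <- sum(1 / seq_len(n_hap - 1))
  ec <- c(synonymous = 0, missense = 0, nonsense = 0, splice_site = 0)
  ec[names(effect_counts)] <- effect_counts
  ac <- c(low_qual = 0, bad_depth = 0, high_missing = 0, indel = 0, multiallelic = 0)
  ac[names(artifacts)] <- artifacts

  taken <- new.env(parent = emptyenv()) # occupied "contig:pos0" keys
  occupy <- function(contig, pos0) {
    key <- paste0(contig, ":", pos0)
    if (!is.null(taken[[key]])) return(FALSE)
    assign(key, TRUE, envir = taken)
    TRUE
  }

  acc <- new.env(parent = emptyenv())
  acc$n <- 0L
  acc$contig <- list(); acc$pos0 <- list(); acc$ref <- list(); acc$alt <- list()
  acc$qual <- list(); acc$gt <- list(); acc$dp <- list()
  acc$kind <- list(); acc$detail <- list()
  block_carriers <- new.env(parent = emptyenv())
  carriers_for <- function(contig, pos0) {
    if (ld_block > 0) {
      key <- paste0(contig, ":", pos0 %/% ld_block)
      cs <- block_carriers[[key]]
      if (is.null(cs)) {
        cs <- sample.int(n_hap, .sfs_draw(n_hap))
        assign(key, cs, envir = block_carriers)
      }
      cs
    } else {
      sample.int(n_hap, .sfs_draw(n_hap))
    }
  }
  add_site <- function(contig, pos0, ref, alt, qual, gt, dp, kind, detail) {
    i <- acc$n + 1L
    acc$n <- i
    acc$contig[[i]] <- contig; acc$pos0[[i]] <- pos0
    acc$ref[[i]] <- ref; acc$alt[[i]] <- alt; acc$qual[[i]] <- qual
    acc$gt[[i]] <- gt; acc$dp[[i]] <- dp
    acc$kind[[i]] <- kind; acc$detail[[i]] <- detail
    invisible(i)
  }
  std_gt <- function(contig, pos0) {
    gt <- .gt_from_carriers(carriers_for(contig, pos0), n_samples)
    if (missing_prob > 0 && n_samples >= 5 && stats::runif(1) < missing_prob) {
      gt[sample.int(n_samples, 1)] <- "./."
    }
    gt
  }
  std_dp <- function() stats::rpois(n_samples, depth) + 1L
  std_qual <- function() round(stats::runif(1, 45, 900), 1)

  # ---- background diversity sites ------------------------------------
  for (cls in names(theta)) {
    tr <- feature_track(genome$features, cls)
    if (nrow(tr) == 0 || theta[[cls]] == 0) next
    Lc <- sum(tr$end - tr$start)
    S <- stats::rpois(1, theta[[cls]] * a_n * Lc)
    if (S == 0) next
    offs <- sample.int(Lc, min(S, Lc))
    cumw <- cumsum(tr$end - tr$start)
    for (o in offs) {
      i <- findInterval(o - 1L, c(0L, cumw), rightmost.closed = FALSE)
      pos0 <- tr$start[i] + (o - 1L) - c(0L, cumw)[i]
      ctg <- tr$contig[i]
      refb <- substring(contigs[[ctg]], pos0 + 1L, pos0 + 1L)
      if (refb == "N" || !occupy(ctg, pos0)) next
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      add_site(ctg, pos0, refb, altb, std_qual(), std_gt(ctg, pos0), std_dp(),
               "variant", paste0("background:", cls))
    }
  }

  # ---- planted effect variants ---------------------------------------
  main <- Filter(function(l) !l$spare, genome$loci)
  if (sum(ec) > 0 && length(main) == 0) stop("no gene loci available for effect plants")
  plant_codon_variant <- function(target) {
    for (attempt in seq_len(400)) {
      l <- main[[sample.int(length(main), 1)]]
      cds <- .locus_cds_seq(genome, l)
      nc <- nchar(cds) %/% 3L
      j <- sample(2:(nc - 1), 1)
      codon <- substring(cds, (j - 1) * 3 + 1, j * 3)
      ref_aa <- .aa(codon)
      ws <- sample(0:2)
      for (w in ws) {
        refb <- substring(codon, w + 1, w + 1)
        for (b in sample(setdiff(c("A", "C", "G", "T"), refb))) {
          alt_codon <- codon
          substring(alt_codon, w + 1, w + 1) <- b
          alt_aa <- .aa(alt_codon)
          hit <- switch(target,
            synonymous = alt_aa == ref_aa && alt_aa != "*",
            missense = alt_aa != ref_aa && alt_aa != "*" && ref_aa != "*",
            nonsense = alt_aa == "*" && ref_aa != "*")
          if (!hit) next
          p <- (j - 1L) * 3L + w
          loc <- .sense_to_genomic(l, p, b)
          if (!occupy(l$contig, loc$pos0)) next
          refg <- substring(contigs[[l$contig]], loc$pos0 + 1L, loc$pos0 + 1L)
          add_site(l$contig, loc$pos0, refg, loc$alt, std_qual(),
                   std_gt(l$contig, loc$pos0), std_dp(),
                   "variant", paste0("effect:", target))
          return(TRUE)
        }
      }
    }
    stop("could not plant a ", target, " variant in the available codons")
  }
  for (target in c("synonymous", "missense", "nonsense")) {
    for (i in seq_len(ec[[target]])) plant_codon_variant(target)
  }
  if (ec[["splice_site"]] > 0) {
    multi <- Filter(function(l) l$n_exons >= 2, main)
    if (length(multi) == 0) stop("no multi-exon loci available for splice_site plants")
    for (i in seq_len(ec[["splice_site"]])) {
      ok <- FALSE
      for (attempt in seq_len(200)) {
        l <- multi[[sample.int(length(multi), 1)]]
        iv <- .map_ivs(l$orf_exons, l$start, l$locus_len, l$strand)
        k <- sample.int(nrow(iv) - 1L, 1) # intron after genomic exon k
        intron <- c(iv[k, 2], iv[k + 1, 1])
        cand <- c(intron[1], intron[1] + 1L, intron[2] - 2L, intron[2] - 1L)
        pos0 <- cand[sample.int(4L, 1)]
        if (!occupy(l$contig, pos0)) next
        refb <- substring(contigs[[l$contig]], pos0 + 1L, pos0 + 1L)
        altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        add_site(l$contig, pos0, refb, altb, std_qual(),
                 std_gt(l$contig, pos0), std_dp(),
                 "variant", "effect:splice_site")
        ok <- TRUE
        break
      }
      if (!ok) stop("could not plant a splice_site variant")
    }
  }

  # ---- artifact plants (positions in intergenic space) ----------------
  inter <- feature_track(genome$features, "intergenic")
  rand_intergenic <- function() {
    for (attempt in seq_len(500)) {
      i <- sample.int(nrow(inter), 1)
      pos0 <- inter$start[i] + sample.int(inter$end[i] - inter$start[i], 1) - 1L
      ctg <- inter$contig[i]
      refb <- substring(contigs[[ctg]], pos0 + 1L, pos0 + 1L)
      if (refb != "N" && pos0 + 2L <= lens[[ctg]] && occupy(ctg, pos0)) {
        return(list(contig = ctg, pos0 = pos0, ref = refb))
      }
    }
    stop("could not find a free intergenic position for an artifact plant")
  }
  for (i in seq_len(ac[["low_qual"]])) {
    s <- rand_intergenic()
    altb <- sample(setdiff(c("A", "C", "G", "T"), s$ref), 1)
    add_site(s$contig, s$pos0, s$ref, altb, round(stats::runif(1, 5, 39.5), 1),
             std_gt(s$contig, s$pos0), std_dp(), "variant", "filtered_out:qual")
  }
  for (i in seq_len(ac[["bad_depth"]])) {
    s <- rand_intergenic()
    altb <- sample(setdiff(c("A", "C", "G", "T"), s$ref), 1)
    dp <- rep(if (i %% 2 == 0) 2L else 600L, n_samples)
    add_site(s$contig, s$pos0, s$ref, altb, std_qual(),
             .gt_from_carriers(carriers_for(s$contig, s$pos0), n_samples), dp,
             "variant", "filtered_out:depth")
  }
  for (i in seq_len(ac[["high_missing"]])) {
    s <- rand_intergenic()
    altb <- sample(setdiff(c("A", "C", "G", "T"), s$ref), 1)
    gt <- .gt_from_carriers(carriers_for(s$contig, s$pos0), n_samples)
    gt[sample.int(n_samples, floor(0.2 * n_samples) + 1L)] <- "./."
    add_site(s$contig, s$pos0, s$ref, altb, std_qual(), gt, std_dp(),
             "variant", "filtered_out:missing")
  }
  for (i in seq_len(ac[["indel"]])) {
    s <- rand_intergenic()
    ref2 <- substring(contigs[[s$contig]], s$pos0 + 1L, s$pos0 + 2L)
    add_site(s$contig, s$pos0, ref2, substring(ref2, 1, 1), std_qual(),
             std_gt(s$contig, s$pos0), std_dp(), "variant", "filtered_out:indel")
  }
  for (i in seq_len(ac[["multiallelic"]])) {
    s <- rand_intergenic()
    alts <- sample(setdiff(c("A", "C", "G", "T"), s$ref), 2)
    gt <- .gt_from_carriers(carriers_for(s$contig, s$pos0), n_samples)
    slot <- which(gt == "0/0")
    gt[if (length(slot)) slot[1] else 1L] <- "0/2"
    add_site(s$contig, s$pos0, s$ref, paste(alts, collapse = ","), std_qual(),
             gt, std_dp(), "variant", "multiallelic")
  }

  if (acc$n == 0) stop("no variants generated; increase theta or counts")
  sites <- data.frame(variant_id = sprintf("v%05d", seq_len(acc$n)),
                      contig = unlist(acc$contig), pos = unlist(acc$pos0) + 1L,
                      ref = unlist(acc$ref), alt = unlist(acc$alt),
                      qual = unlist(acc$qual))
  gt <- matrix(unlist(acc$gt), ncol = n_samples, byrow = TRUE)
  dp <- matrix(as.integer(unlist(acc$dp)), ncol = n_samples, byrow = TRUE)
  ledger <- data.frame(kind = unlist(acc$kind), variant_id = sites$variant_id,
                       detail = unlist(acc$detail))
  ord <- order(sites$contig, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  dp <- dp[ord, , drop = FALSE]
  samples <- sprintf("S%02d", seq_len(n_samples))
  for (cls in names(theta)) {
    ledger <- rbind(ledger, data.frame(kind = "theta", variant_id = NA_character_,
                                       detail = sprintf("%s=%g", cls, theta[[cls]])))
  }
  list(variants = variant_table(sites, gt, dp, samples, lens), ledger = ledger)
}

#' Write / read a VCF v4.2 file
#'
#' Writes the minimal VCF the generator emits: site lines with QUAL and
#' per-sample `GT:DP`. `read_vcf()` parses the same subset back into a
#' [variant_table()]; contig lengths are taken from the `##contig` header
#' lines.
#'
#' @param x a [variant_table()].
#' @param path file path.
#' @return `path` (write) / a `variant_table` (read).
#' @export
write_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=gnomekit", con)
  for (cid in names(x$contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", cid, x$contig_lengths[[cid]]), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples), collapse = "\t"), con)
  if (nrow(x$sites)) {
    smp <- matrix(paste(x$gt, x$dp, sep = ":"), nrow = nrow(x$sites))
    body <- cbind(x$sites$contig, x$sites$pos, x$sites$variant_id, x$sites$ref,
                  x$sites$alt, format(x$sites$qual, trim = TRUE), ".", ".",
                  "GT:DP", smp)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  ctg <- hdr[startsWith(hdr, "##contig=")]
  ids <- sub('.*ID=([^,>]+).*', "\\1", ctg)
  clen <- as.integer(sub(".*length=([0-9]+).*", "\\1", ctg))
  col_line <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(col_line, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    sites <- data.frame(variant_id = character(), contig = character(),
                        pos = integer(), ref = character(), alt = character(),
                        qual = numeric())
    return(variant_table(sites, matrix(character(), 0, length(samples)),
                         matrix(integer(), 0, length(samples)), samples,
                         stats::setNames(clen, ids)))
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  sites <- data.frame(variant_id = f[, 3], contig = f[, 1],
                      pos = as.integer(f[, 2]), ref = f[, 4], alt = f[, 5],
                      qual = as.numeric(f[, 6]))
  sub_gt <- function(v) vapply(strsplit(v, ":"), `[`, character(1), 1)
  sub_dp <- function(v) as.integer(vapply(strsplit(v, ":"), `[`, character(1), 2))
  smp <- f[, -(1:9), drop = FALSE]
  gt <- apply(smp, 2, sub_gt)
  dp <- apply(smp, 2, sub_dp)
  if (is.null(dim(gt))) { gt <- matrix(gt, nrow = 1); dp <- matrix(dp, nrow = 1) }
  variant_table(sites, gt, dp, samples, stats::setNames(clen, ids))
}
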