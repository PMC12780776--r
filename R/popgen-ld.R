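# Linkage-disequilibrium decay, per-sample inbreeding, variant summaries.

#' Linkage-disequilibrium decay curve
#'
#' For every intra-contig pair of biallelic SNVs separated by at most
#' `max_dist` bp, r-squared is the squared Pearson correlation of genotype
#' dosages (0/1/2) over samples with called genotypes at both sites; pairs
#' where either site is monomorphic on the shared samples are skipped.
#' Pairs are grouped into distance bins and averaged.
#'
#' @param vt a filtered [variant_table()].
#' @param max_dist maximum pair distance in bp.
#' @param bin_edges increasing bin edges in bp (last edge caps
#'   `max_dist`).
#' @return data.frame of class `ld_curve`: bin_lo, bin_hi, mean_r2,
#'   n_pairs.
#' @export
ld_decay <- function(vt, max_dist = 100000,
                     bin_edges = c(0, 100, 500, 1000, 5000, 10000, 50000, 100000)) {
  stopifnot(inherits(vt, "variant_table"))
  bin_edges <- sort(unique(c(bin_edges, max_dist)))
  bin_edges <- bin_edges[bin_edges <= max_dist]
  rows <- which(.biallelic_snv_rows(vt))
  if (length(rows) < 2) stop("ld_decay needs at least 2 biallelic SNVs")
  d <- .dosage_matrix(vt)[rows, , drop = FALSE]
  pos <- vt$sites$pos[rows]
  ctg <- vt$sites$contig[rows]
  nb <- length(bin_edges) - 1L
  sums <- numeric(nb); counts <- integer(nb)
  for (cid in unique(ctg)) {
    sel <- which(ctg == cid)
    sel <- sel[order(pos[sel])]
    p <- pos[sel]
    for (ii in seq_along(sel)) {
      if (ii == length(sel)) break
      for (jj in (ii + 1):length(sel)) {
        dist <- p[jj] - p[ii]
        if (dist > max_dist) break
        x <- d[sel[ii], ]; y <- d[sel[jj], ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2) next
        if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
        r2 <- stats::cor(x[ok], y[ok])^2
        b <- findInterval(dist, bin_edges, rightmost.closed = TRUE)
        if (b >= 1 && b <= nb) {
          sums[b] <- sums[b] + r2
          counts[b] <- counts[b] + 1L
        }
      }
    }
  }
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1],
                    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                    n_pairs = counts)
  class(out) <- c("ld_curve", "data.frame")
  out
}

#' Per-sample inbreeding coefficients from homozygote excess
#'
#' For each sample, over the biallelic sites where it has a called
#' genotype: `O` is the observed homozygote count, the expected count is
#' `E = sum(1 - 2 p_i (1 - p_i) * 2 n_i / (2 n_i - 1))` using each site's
#' non-missing allele frequency `p_i` and non-missing sample count `n_i`,
#' and `F = (O - E) / (N - E)` (the method-of-moments estimator reported by
#' `vcftools --het`). `F` is `NA` when `N = E`.
#'
#' @param vt a filtered [variant_table()].
#' @return data.frame: sample, observed_hom, expected_hom, n_sites, F.
#' @export
inbreeding_F <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  rows <- which(.biallelic_snv_rows(vt))
  d <- .dosage_matrix(vt)[rows, , drop = FALSE]
  n_i <- rowSums(!is.na(d))
  p_i <- rowSums(d, na.rm = TRUE) / (2 * n_i)
  # per-site expected homozygosity with the small-sample (2n)/(2n-1)
  # correction
  e_site <- 1 - 2 * p_i * (1 - p_i) * (2 * n_i) / (2 * n_i - 1)
  usable <- n_i >= 1 & !is.na(e_site)
  out <- NULL
  for (s in seq_along(vt$samples)) {
    called <- !is.na(d[, s]) & usable
    N <- sum(called)
    O <- sum(d[called, s] %in% c(0L, 2L))
    E <- sum(e_site[called])
    Fv <- if (N > 0 && abs(N - E) > .Machine$double.eps^0.5) (O - E) / (N - E) else NA_real_
    out <- rbind(out, data.frame(sample = vt$samples[s], observed_hom = O,
                                 expected_hom = E, n_sites = N, F = Fv))
  }
  out
}

#' Variant density and coding-ratio arithmetic
#'
#' `snp_density()` is SNPs per kilobase of effective length, rounded to two
#' decimals; `missense_silent_ratio()` is the missense/synonymous count
#' ratio, rounded to two decimals (`NA` when there are no synonymous
#' variants).
#'
#' @param n_snps SNP count.
#' @param effective_length_bp callable genome length in bp.
#' @return Numeric scalar.
#' @export
snp_density <- function(n_snps, effective_length_bp) {
  if (effective_length_bp <= 0) stop("effective length must be positive")
  round(n_snps / (effective_length_bp / 1000), 2)
}

#' @param n_missense,n_synonymous coding variant counts.
#' @rdname snp_density
#' @export
missense_silent_ratio <- function(n_missense, n_synonymous) {
  if (n_synonymous <= 0) return(NA_real_)
  round(n_missense / n_synonymous, 2)
}

#' Variant summary table
#'
#' Headline numbers of a filtered call set: total SNP count, biallelic
#' fraction, overall density per kilobase of effective (callable) length,
#' per-effect counts with percentages within protein-coding classes, the
#' missense-to-silent ratio, and per-contig densities over contig lengths.
#'
#' @param effects output of [classify_effects()] (may be `NULL` to skip
#'   effect-based rows).
#' @param vt the filtered [variant_table()] the effects were computed from.
#' @param effective_length callable genome length in bp.
#' @return list with `totals`, `effects` (counts and coding percentages),
#'   `per_contig` (densities per kb).
#' @export
variant_summary <- function(effects, vt, effective_length) {
  if (effective_length <= 0) stop("effective_length must be positive")
  n <- nrow(vt$sites)
  density <- snp_density(n, effective_length)
  biallelic <- if (n > 0) sum(!.is_multiallelic(vt$sites)) / n else NA_real_
  eff_tab <- NULL
  ratio <- NA_real_
  if (!is.null(effects) && nrow(effects)) {
    cnt <- table(factor(effects$effect, levels = .EFFECT_SEVERITY))
    coding <- c("synonymous", "missense", "nonsense")
    coding_total <- sum(cnt[coding])
    eff_tab <- data.frame(effect = names(cnt), count = as.integer(cnt))
    eff_tab$coding_pct <- ifelse(eff_tab$effect %in% coding & coding_total > 0,
                                 round(100 * eff_tab$count / coding_total, 1),
                                 NA_real_)
    ratio <- missense_silent_ratio(cnt[["missense"]], cnt[["synonymous"]])
  }
  per_contig <- NULL
  if (n > 0) {
    tab <- table(vt$sites$contig)
    per_contig <- data.frame(contig = names(vt$contig_lengths),
                             n_snps = as.integer(tab[names(vt$contig_lengths)]))
    per_contig$n_snps[is.na(per_contig$n_snps)] <- 0L
    per_contig$density_per_kb <-
      round(per_contig$n_snps / (vt$contig_lengths / 1000), 2)
  }
  list(totals = data.frame(n_snps = n, biallelic_fraction = biallelic,
                           density_per_kb = if (n > 0) density else 0,
                           missense_silent_ratio = ratio),
       effects = eff_tab, per_contig = per_contig)
}
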