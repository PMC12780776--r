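# Windowed nucleotide diversity, per-feature contrasts, and per-chromosome
# enrichment of high-diversity windows.

# dosage matrix (0/1/2 copies of the first alternate allele, NA when
# missing) for biallelic SNV rows
.dosage_matrix <- function(vt) {
  g <- vt$gt
  d <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g))
  d[g == "0/0"] <- 0L
  d[g %in% c("0/1", "1/0")] <- 1L
  d[g == "1/1"] <- 2L
  d
}

# rows usable by the two-allele estimators: biallelic SNVs
.biallelic_snv_rows <- function(vt) {
  !.is_indel(vt$sites) & !.is_multiallelic(vt$sites)
}

# per-site allele summaries: non-missing allele count n_i and alternate
# allele count c_i
.site_allele_counts <- function(vt, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(vt$sites))
  d <- .dosage_matrix(vt)[rows, , drop = FALSE]
  n_al <- 2L * rowSums(!is.na(d))
  c_al <- rowSums(d, na.rm = TRUE)
  data.frame(idx = rows, n_alleles = n_al, alt_count = c_al)
}

.harmonic <- function(m) if (m < 1) NA_real_ else sum(1 / seq_len(m))

# pi/theta for one set of sites over a callable length
.pi_theta <- function(n_alleles, alt_count, callable) {
  if (is.na(callable) || callable <= 0) {
    return(c(pi = NA_real_, theta = NA_real_, S = NA_real_))
  }
  poly <- alt_count > 0 & alt_count < n_alleles & n_alleles >= 2
  num <- sum(alt_count[poly] * (n_alleles[poly] - alt_count[poly]) /
               choose(n_alleles[poly], 2))
  S <- sum(poly)
  if (S == 0) return(c(pi = num / callable, theta = 0, S = 0))
  n_med <- round(stats::median(n_alleles[poly]))
  theta <- if (n_med >= 2) S / (.harmonic(n_med - 1) * callable) else NA_real_
  c(pi = num / callable, theta = theta, S = S)
}

#' Windowed nucleotide diversity and Watterson's theta
#'
#' Windows tile each contig without overlap. Per window,
#' `pi = sum(c_i (n_i - c_i) / choose(n_i, 2)) / n_callable` over
#' polymorphic biallelic sites (c_i alternate-allele count among the n_i
#' non-missing alleles), and `theta_w = S / (a_{n-1} * n_callable)` with the
#' harmonic number taken at the window's median non-missing allele count.
#' The denominator counts callable sites — including invariant ones — not
#' just variant sites; by default every position of the window is callable,
#' or supply per-window counts.
#'
#' @param vt a filtered [variant_table()].
#' @param window window size in bp (10 kb and 100 kb are the conventional
#'   choices).
#' @param callable optional data.frame (contig, start, end, n_callable)
#'   overriding the fully-callable default.
#' @return data.frame of class `diversity_windows`: contig, start, end,
#'   n_callable, n_segregating, pi, theta_w.
#' @export
windowed_diversity <- function(vt, window = 10000, callable = NULL) {
  stopifnot(inherits(vt, "variant_table"), window >= 1)
  rows <- which(.biallelic_snv_rows(vt))
  ac <- .site_allele_counts(vt, rows)
  pos0 <- vt$sites$pos[rows] - 1L
  ctg <- vt$sites$contig[rows]
  out <- NULL
  for (cid in names(vt$contig_lengths)) {
    L <- vt$contig_lengths[[cid]]
    starts <- seq(0L, L - 1L, by = window)
    for (s in starts) {
      e <- min(s + window, L)
      if (!is.null(callable)) {
        hit <- callable$contig == cid & callable$start == s
        ncall <- if (any(hit)) callable$n_callable[hit][1] else NA_real_
      } else {
        ncall <- e - s
      }
      sel <- ctg == cid & pos0 >= s & pos0 < e
      pt <- .pi_theta(ac$n_alleles[sel], ac$alt_count[sel], ncall)
      out <- rbind(out, data.frame(contig = cid, start = s, end = e,
                                   n_callable = ncall,
                                   n_segregating = unname(pt["S"]),
                                   pi = unname(pt["pi"]),
                                   theta_w = unname(pt["theta"])))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("diversity_windows", "data.frame")
  out
}

# intersect a window [s, e) with a class interval set on one contig;
# returns total overlap length and a logical over positions pos0
.class_overlap <- function(track, cid, s, e) {
  tr <- track[track$contig == cid, , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  sum(pmax(0, pmin(tr$end, e) - pmax(tr$start, s)))
}

#' Per-feature nucleotide diversity with rank-sum contrasts
#'
#' Computes pi in windows restricted to each feature class (window callable
#' length = overlap of the window with the class intervals; only sites
#' inside class intervals count) and contrasts each class's window
#' distribution against windows restricted to the complement of the class
#' with a two-sided Wilcoxon rank-sum test (exact for 20 or fewer windows
#' per side, normal approximation with continuity and tie correction
#' otherwise).
#'
#' @param vt a filtered [variant_table()].
#' @param features a [feature_map()].
#' @param classes feature classes to profile.
#' @param window window size in bp.
#' @return list with `windows` (per-class window pi) and `tests`
#'   (data.frame: class, median pi, complement median, W, p, n windows; NA
#'   with a notice when a side has fewer than 2 windows).
#' @export
feature_diversity <- function(vt, features, classes = c("exon", "intron",
                                                        "intergenic", "repeat",
                                                        "low_complexity"),
                              window = 10000) {
  stopifnot(inherits(vt, "variant_table"), inherits(features, "feature_map"))
  rows <- which(.biallelic_snv_rows(vt))
  ac <- .site_allele_counts(vt, rows)
  pos0 <- vt$sites$pos[rows] - 1L
  ctg <- vt$sites$contig[rows]
  win_out <- NULL
  tests <- NULL
  for (cls in classes) {
    track <- feature_track(features, cls)
    inside_cls <- .positions_in_track(track, ctg, pos0)
    for (side in c("class", "complement")) {
      use <- if (side == "class") inside_cls else !inside_cls
      for (cid in names(vt$contig_lengths)) {
        L <- vt$contig_lengths[[cid]]
        starts <- seq(0L, L - 1L, by = window)
        for (s in starts) {
          e <- min(s + window, L)
          ov <- .class_overlap(track, cid, s, e)
          ncall <- if (side == "class") ov else (e - s) - ov
          if (ncall <= 0) next
          sel <- use & ctg == cid & pos0 >= s & pos0 < e
          pt <- .pi_theta(ac$n_alleles[sel], ac$alt_count[sel], ncall)
          win_out <- rbind(win_out,
                           data.frame(class = cls, side = side, contig = cid,
                                      start = s, n_callable = ncall,
                                      pi = unname(pt["pi"])))
        }
      }
    }
    a <- win_out$pi[win_out$class == cls & win_out$side == "class"]
    b <- win_out$pi[win_out$class == cls & win_out$side == "complement"]
    if (length(a) < 2 || length(b) < 2) {
      message("feature_diversity: class '", cls,
              "' has fewer than 2 windows on a side; test skipped")
      tests <- rbind(tests, data.frame(class = cls, n_class = length(a),
                                       n_complement = length(b),
                                       median_pi = stats::median(a),
                                       median_complement = stats::median(b),
                                       W = NA_real_, p = NA_real_))
      next
    }
    if (length(unique(c(a, b))) == 1) {
      # fully tied distributions: no evidence of a shift
      tests <- rbind(tests, data.frame(class = cls, n_class = length(a),
                                       n_complement = length(b),
                                       median_pi = stats::median(a),
                                       median_complement = stats::median(b),
                                       W = length(a) * length(b) / 2, p = 1))
      next
    }
    exact <- length(a) <= 20 && length(b) <= 20
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    tests <- rbind(tests, data.frame(class = cls, n_class = length(a),
                                     n_complement = length(b),
                                     median_pi = stats::median(a),
                                     median_complement = stats::median(b),
                                     W = unname(wt$statistic), p = wt$p.value))
  }
  list(windows = win_out, tests = tests)
}

#' Per-chromosome enrichment of top-diversity windows
#'
#' Flags contigs carrying more of the top `top_frac` highest-pi windows
#' than expected: per contig a 2x2 table (on/off contig x top/background)
#' is tested with a two-sided Fisher's exact test, p-values are adjusted
#' across contigs by Benjamini–Hochberg, and a contig is enriched when the
#' adjusted p is below `alpha` with odds ratio above 1. Ties at the pi
#' threshold are broken by window coordinate.
#'
#' @param windows a `diversity_windows` data.frame.
#' @param top_frac fraction of windows forming the top set.
#' @param alpha adjusted-p threshold.
#' @return data.frame: contig, n_windows, n_top, odds_ratio, p, p_adj,
#'   enriched.
#' @export
chromosome_enrichment <- function(windows, top_frac = 0.05, alpha = 0.01) {
  w <- windows[!is.na(windows$pi), , drop = FALSE]
  contigs <- unique(windows$contig)
  N <- nrow(w)
  if (N < 1 / top_frac || length(contigs) < 2) {
    message("chromosome_enrichment: too few windows (", N, ") or contigs; NA result")
    return(data.frame(contig = contigs, n_windows = NA_integer_,
                      n_top = NA_integer_, odds_ratio = NA_real_,
                      p = NA_real_, p_adj = NA_real_, enriched = NA))
  }
  k <- ceiling(top_frac * N)
  ord <- order(-w$pi, w$contig, w$start)
  top <- logical(N)
  top[ord[seq_len(k)]] <- TRUE
  out <- NULL
  for (cid in contigs) {
    on <- w$contig == cid
    tab <- matrix(c(sum(top & on), sum(!top & on),
                    sum(top & !on), sum(!top & !on)), nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    out <- rbind(out, data.frame(contig = cid, n_windows = sum(on),
                                 n_top = sum(top & on),
                                 odds_ratio = unname(ft$estimate),
                                 p = ft$p.value))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj < alpha & out$odds_ratio > 1
  out
}
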