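# CpG methylation classification and per-feature / windowed summaries.

#' Classify CpG sites by modification support
#'
#' A site (one cytosine record per strand and modification code) is *weakly*
#' methylated when at least `weak_min_modified` read(s) call the base
#' modified, and *highly* methylated when the modified fraction of valid
#' reads reaches `high_fraction` (a high site is necessarily weak). Sites
#' with zero valid coverage are not methylatable and are classified `NA`.
#'
#' @param table a [methyl_site_table()].
#' @param weak_min_modified minimum modified reads for a weak call.
#' @param high_fraction modified-read fraction for a high call; compared
#'   with `>=` unless `high_strict` is `TRUE` (then `>`).
#' @param high_strict use a strict inequality for the high threshold.
#' @return The table with added columns `class` (factor: unmethylated,
#'   weak, high) and `methylatable` (logical).
#' @export
classify_sites <- function(table, weak_min_modified = 1, high_fraction = 0.20,
                           high_strict = FALSE) {
  stopifnot(inherits(table, "methyl_site_table"))
  df <- as.data.frame(table)
  methylatable <- df$valid_coverage >= 1
  frac <- ifelse(methylatable, df$modified_count / df$valid_coverage, NA_real_)
  weak <- methylatable & df$modified_count >= weak_min_modified
  high <- weak & if (high_strict) frac > high_fraction else frac >= high_fraction
  cls <- ifelse(!methylatable, NA_character_,
                ifelse(high, "high", ifelse(weak, "weak", "unmethylated")))
  df$class <- factor(cls, levels = c("unmethylated", "weak", "high"))
  df$methylatable <- methylatable
  class(df) <- c("classified_methyl_table", "data.frame")
  df
}

.FEATURE_CLASSES <- c("exon", "intron", "intergenic", "repeat", "low_complexity")

#' Count methylation classes per feature class
#'
#' A site contributes to *every* feature class whose intervals contain it
#' (feature classes are independent overlays, not a partition), plus the
#' `genome_wide` row. Methylatable means contained and covered by at least
#' one valid read. Weak counts include high sites.
#'
#' @param classified output of [classify_sites()].
#' @param features a [feature_map()].
#' @return data.frame with one row per (feature class, mod code):
#'   `methylatable_sites`, `weak_sites`, `high_sites`.
#' @export
count_by_feature <- function(classified, features) {
  stopifnot(inherits(classified, "classified_methyl_table"),
            inherits(features, "feature_map"))
  for (cls in names(features$tracks)) {
    tr <- features$tracks[[cls]]
    if (nrow(tr) && any(tr$end > features$lengths[tr$contig])) {
      stop("feature intervals of class ", cls, " exceed contig bounds")
    }
  }
  out <- NULL
  for (code in sort(unique(classified$mod_code))) {
    sub <- classified[classified$mod_code == code, , drop = FALSE]
    for (cls in c(.FEATURE_CLASSES, "genome_wide")) {
      inside <- if (cls == "genome_wide") {
        rep(TRUE, nrow(sub))
      } else {
        .positions_in_track(feature_track(features, cls), sub$contig, sub$pos)
      }
      m <- inside & sub$methylatable
      out <- rbind(out, data.frame(
        feature = cls, mod_code = code,
        methylatable_sites = sum(m),
        weak_sites = sum(m & sub$class %in% c("weak", "high")),
        high_sites = sum(m & sub$class == "high")
      ))
    }
  }
  if (is.null(out)) {
    out <- data.frame(feature = character(), mod_code = character(),
                      methylatable_sites = integer(), weak_sites = integer(),
                      high_sites = integer())
  }
  out
}

#' Aggregate classified sites into genomic windows
#'
#' Windows tile each contig as `[0, w), [w, 2w), ...` (half-open; the last
#' window is truncated at the contig end). Per window and feature class the
#' methylatable/weak/high counts are summed; summing the windows of a class
#' reproduces its global counts exactly.
#'
#' @param classified output of [classify_sites()].
#' @param features a [feature_map()].
#' @param window window size in bp (default 100 kb).
#' @return data.frame: contig, window_start, window_end, feature, mod_code,
#'   methylatable_sites, weak_sites, high_sites.
#' @export
window_aggregate <- function(classified, features, window = 100000) {
  stopifnot(window >= 1)
  lens <- features$lengths
  out <- NULL
  for (code in sort(unique(classified$mod_code))) {
    for (cls in .FEATURE_CLASSES) {
      sub <- classified[classified$mod_code == code, , drop = FALSE]
      inside <- .positions_in_track(feature_track(features, cls), sub$contig, sub$pos)
      sub <- sub[inside & sub$methylatable, , drop = FALSE]
      if (nrow(sub) == 0) next
      key <- paste(sub$contig, sub$pos %/% window)
      mat <- cbind(methylatable = rep(1L, nrow(sub)),
                   weak = as.integer(sub$class %in% c("weak", "high")),
                   high = as.integer(sub$class == "high"))
      agg <- rowsum(mat, group = key)
      parts <- strsplit(rownames(agg), " ")
      ctg <- vapply(parts, `[`, character(1), 1)
      wi <- as.integer(vapply(parts, `[`, character(1), 2))
      out <- rbind(out, data.frame(
        contig = ctg, window_start = wi * window,
        window_end = pmin((wi + 1) * window, lens[ctg]),
        feature = cls, mod_code = code,
        methylatable_sites = agg[, "methylatable"],
        weak_sites = agg[, "weak"], high_sites = agg[, "high"]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(contig = character(), window_start = numeric(),
                      window_end = numeric(), feature = character(),
                      mod_code = character(), methylatable_sites = integer(),
                      weak_sites = integer(), high_sites = integer())
  }
  rownames(out) <- NULL
  out
}

#' Methylation percentage table
#'
#' Adds weak/high percentages (100 * count / methylatable, rounded to two
#' decimals with round-half-even) to a per-feature count table. Percentages
#' are `NA` when a class has no methylatable site.
#'
#' @param counts output of [count_by_feature()].
#' @return data.frame with `weak_pct` and `high_pct` columns added.
#' @export
methylation_table <- function(counts) {
  pct <- function(n, d) ifelse(d > 0, round(100 * n / d, 2), NA_real_)
  counts$weak_pct <- pct(counts$weak_sites, counts$methylatable_sites)
  counts$high_pct <- pct(counts$high_sites, counts$methylatable_sites)
  counts
}

#' Genome-wide methylated-site fraction
#'
#' @param table a [methyl_site_table()].
#' @param mod_code modification code to summarise (`"m"` or `"h"`).
#' @param mode `"weak"` (supported by at least one modified read) or
#'   `"high"` (modified fraction at or above 20%).
#' @param high_fraction threshold used in `"high"` mode.
#' @return list: `called_sites` (coverage >= 1), `methylated_sites`,
#'   `fraction` (`NA` when nothing is called).
#' @export
genome_wide_fraction <- function(table, mod_code = "m", mode = c("weak", "high"),
                                 high_fraction = 0.20) {
  mode <- match.arg(mode)
  cl <- classify_sites(table, high_fraction = high_fraction)
  cl <- cl[cl$mod_code == mod_code, , drop = FALSE]
  called <- sum(cl$methylatable)
  meth <- if (mode == "weak") {
    sum(cl$class %in% c("weak", "high"), na.rm = TRUE)
  } else {
    sum(cl$class == "high", na.rm = TRUE)
  }
  list(called_sites = called, methylated_sites = meth,
       fraction = if (called > 0) meth / called else NA_real_)
}

#' Write a methylation profile TSV
#'
#' Column order mirrors a per-feature methylation summary table: feature,
#' then per mod code the percentage, methylated count and methylatable
#' count.
#' @param profile output of [methylation_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
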