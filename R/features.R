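#' Feature map: genomic intervals by feature class
#'
#' Holds interval tracks for the feature classes used throughout the package:
#' `exon`, `intron`, `intergenic`, `repeat`, `low_complexity`. The first three
#' partition each contig; `repeat` and `low_complexity` are independent
#' overlays and may overlap the partition (and each other), mirroring how
#' repeat annotations overlap genic and intergenic space in real assemblies.
#'
#' Intervals are 0-based half-open.
#'
#' @param tracks named list; each element a data.frame with columns
#'   `contig`, `start`, `end` (and optionally `strand`).
#' @param lengths named integer vector of contig lengths, used for bounds
#'   checks.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(tracks, lengths) {
  known <- c("exon", "intron", "intergenic", "repeat", "low_complexity")
  if (length(tracks) && is.null(names(tracks))) stop("tracks must be named by class")
  unknown <- setdiff(names(tracks), known)
  if (length(unknown)) stop("unknown feature class(es): ", paste(unknown, collapse = ", "))
  for (cls in names(tracks)) {
    tr <- tracks[[cls]]
    if (nrow(tr) == 0) next
    if (!all(c("contig", "start", "end") %in% names(tr))) {
      stop("track '", cls, "' must have contig/start/end columns")
    }
    if (any(tr$start >= tr$end)) stop("track '", cls, "' has empty or inverted intervals")
    if (any(tr$start < 0)) stop("track '", cls, "' has negative starts")
    bad <- tr$end > lengths[tr$contig]
    if (any(is.na(bad)) || any(bad)) {
      stop("track '", cls, "' has intervals outside contig bounds")
    }
  }
  for (cls in setdiff(known, names(tracks))) {
    tracks[[cls]] <- data.frame(contig = character(), start = integer(), end = integer())
  }
  structure(list(tracks = tracks[known], lengths = lengths), class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("feature_map over", length(x$lengths), "contig(s)\n")
  for (cls in names(x$tracks)) {
    tr <- x$tracks[[cls]]
    cat(sprintf("  %-15s %6d interval(s), %10d bp\n", cls, nrow(tr),
                if (nrow(tr)) sum(tr$end - tr$start) else 0L))
  }
  invisible(x)
}

#' Feature intervals of one class
#' @param x a `feature_map`.
#' @param class feature class name.
#' @return data.frame with `contig`, `start`, `end`.
#' @export
feature_track <- function(x, class) {
  stopifnot(inherits(x, "feature_map"))
  if (!class %in% names(x$tracks)) stop("unknown feature class: ", class)
  x$tracks[[class]]
}

#' Write a feature map as BED files
#'
#' One 0-based half-open BED file per class, named `<prefix><class>.bed`.
#' @param x a `feature_map`.
#' @param prefix output path prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_feature_bed <- function(x, prefix) {
  out <- character(0)
  for (cls in names(x$tracks)) {
    tr <- x$tracks[[cls]]
    path <- paste0(prefix, cls, ".bed")
    utils::write.table(tr[c("contig", "start", "end")], path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out[cls] <- path
  }
  invisible(out)
}

# Membership test: which of the given positions fall inside any interval of
# the track. Positions are 0-based single bases.
.positions_in_track <- function(track, contig, pos) {
  if (nrow(track) == 0) return(rep(FALSE, length(pos)))
  res <- rep(FALSE, length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    tr <- track[track$contig == ctg, , drop = FALSE]
    if (nrow(tr) == 0) next
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    s <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
    res[sel] <- IRanges::overlapsAny(q, s)
  }
  res
}
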