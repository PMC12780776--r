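#' Contig set: named DNA sequences
#'
#' A `contig_set` is the coordinate frame for every other object in the
#' package: an ordered collection of named DNA sequences over the alphabet
#' A, C, G, T, N. All internal coordinates are 0-based half-open; exported
#' formats use their own conventions (GFF3 1-based closed, BED/bedMethyl
#' 0-based half-open).
#'
#' @param seqs named character vector of DNA sequences.
#' @return An object of class `contig_set`.
#' @export
contig_set <- function(seqs) {
  if (length(seqs) == 0) stop("contig_set needs at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all contigs must have non-empty ids")
  if (anyDuplicated(ids)) stop("contig ids must be unique")
  if (any(!nzchar(seqs))) stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("contig ", ids[which(bad)[1]], " contains characters outside {A,C,G,T,N}")
  }
  structure(as.character(seqs) |> stats::setNames(ids), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set with", length(x), "contig(s), total", sum(nchar(x)), "bp\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) cat(" ", names(x)[i], nchar(x[[i]]), "bp\n")
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Contig lengths
#' @param x a `contig_set`.
#' @return Named integer vector of sequence lengths.
#' @export
contig_lengths <- function(x) {
  stats::setNames(nchar(unclass(x)), names(x))
}

#' Read/write FASTA
#'
#' `read_fasta()` loads a FASTA file into a [contig_set()];
#' `write_fasta()` writes one, wrapped at 60 columns.
#'
#' @param path file path.
#' @return `read_fasta`: a `contig_set`. `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  contig_set(stats::setNames(as.character(dss), sub("\\s.*$", "", names(dss))))
}

#' @param x a `contig_set`.
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x)) {
    writeLines(paste0(">", id), con)
    s <- x[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract a subsequence (0-based half-open)
#' @param x a `contig_set`.
#' @param contig contig id.
#' @param start,end 0-based half-open interval.
#' @return Character scalar.
#' @export
contig_subseq <- function(x, contig, start, end) {
  if (!contig %in% names(x)) stop("unknown contig: ", contig)
  L <- nchar(x[[contig]])
  if (start < 0 || end > L || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds on ", contig, " (length ", L, ")")
  }
  substring(x[[contig]], start + 1L, end)
}

#' Reverse complement of a DNA string
#' @param s character scalar of DNA.
#' @return Character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a DNA coding sequence (standard code)
#'
#' Length must be divisible by 3; stops are rendered `*`.
#' @param s character scalar of DNA, length divisible by 3.
#' @return Character scalar amino-acid string.
#' @export
translate_cds <- function(s) {
  if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
  if (nchar(s) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE))
}
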