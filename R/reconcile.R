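# Two-branch gene-model cleanup and merge.
#
# Evidence branch: split multilocus genes, validate ORFs.
# Orthology branch: filter loss classes, drop cross-scaffold transcripts,
# join exons separated by micro-introns (< 4 bp), split multilocus genes,
# validate ORFs. Finally the evidence set is complemented with orthology
# transcripts whose intron chain (or CDS span, for mono-exon transcripts)
# has no identical evidence counterpart.

.new_removals <- function() {
  data.frame(stage = character(), transcript_id = character(), reason = character())
}

.stage_row <- function(stage, set, input, removed, output, detail = "") {
  data.frame(stage = stage, set = set, input = input, removed = removed,
             output = output, detail = detail)
}

#' Split genes whose transcripts do not overlap into separate genes
#'
#' Within each gene, transcripts are grouped into connected components of
#' the pairwise genomic-overlap graph (overlap of exon-hull spans on the
#' same contig and strand); each component becomes its own gene. Components
#' are numbered `.1`, `.2`, ... in genomic order; genes with a single
#' component are untouched.
#'
#' @param set a [gene_model_set()].
#' @return list(`set`, `report`): the split set and a one-row stage report.
#' @export
split_multilocus_genes <- function(set) {
  spans <- transcript_spans(set)
  tx <- set$transcripts
  n_split <- 0L
  for (g in unique(tx$gene_id)) {
    sp <- spans[spans$gene_id == g, , drop = FALSE]
    if (nrow(sp) < 2) next
    # connected components of the overlap graph
    comp <- seq_len(nrow(sp))
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(nrow(sp) - 1)) {
      for (j in (i + 1):nrow(sp)) {
        same <- sp$contig[i] == sp$contig[j] && sp$strand[i] == sp$strand[j]
        olap <- same && sp$start[i] < sp$end[j] && sp$start[j] < sp$end[i]
        if (olap) comp[find(i)] <- find(j)
      }
    }
    roots <- vapply(seq_len(nrow(sp)), find, integer(1))
    if (length(unique(roots)) == 1) next
    n_split <- n_split + 1L
    # order components by leftmost start (contig id first for determinism)
    comp_start <- tapply(sp$start, roots, min)
    comp_ctg <- tapply(sp$contig, roots, function(x) x[1])
    ord <- order(as.character(comp_ctg), comp_start)
    new_id <- stats::setNames(paste0(g, ".", seq_along(ord)), names(comp_start)[ord])
    tx$gene_id[match(sp$transcript_id, tx$transcript_id)] <-
      new_id[as.character(roots)]
  }
  out <- gene_model_set(tx, set$exons, set$cds)
  list(set = out,
       report = .stage_row("split_multilocus", tx$source[1] %||% "",
                           nrow(set$transcripts), 0L, nrow(tx),
                           detail = sprintf("genes_split=%d", n_split)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Remove orthology transcripts mapped to a different contig than their group
#'
#' Transcripts are grouped by the source gene they were projected from; the
#' contig carrying most transcripts of a group is its majority contig, with
#' ties broken toward the contig with the longest summed transcript span and
#' then lexicographically. Transcripts on any other contig are removed.
#'
#' @param set a [gene_model_set()] with `source_gene` populated on
#'   orthology transcripts.
#' @return list(`set`, `report`, `removals`).
#' @export
drop_cross_scaffold_transcripts <- function(set) {
  tx <- set$transcripts
  orth <- tx$source == "orthology"
  if (any(orth & is.na(tx$source_gene))) {
    bad <- tx$transcript_id[orth & is.na(tx$source_gene)][1]
    stop("orthology transcript ", bad, " has no source_gene")
  }
  spans <- transcript_spans(set)
  drop <- character(0)
  for (sg in unique(tx$source_gene[orth])) {
    ids <- tx$transcript_id[orth & tx$source_gene == sg]
    sp <- spans[match(ids, spans$transcript_id), , drop = FALSE]
    cnt <- table(sp$contig)
    cand <- names(cnt)[cnt == max(cnt)]
    if (length(cand) > 1) {
      spanlen <- vapply(cand, function(ctg) {
        sum((sp$end - sp$start)[sp$contig == ctg])
      }, numeric(1))
      cand <- cand[spanlen == max(spanlen)]
      cand <- sort(cand)[1]
    }
    drop <- c(drop, ids[sp$contig != cand[1]])
  }
  keep <- setdiff(tx$transcript_id, drop)
  out <- subset_transcripts(set, keep)
  removals <- if (length(drop)) {
    data.frame(stage = "cross_scaffold", transcript_id = drop, reason = "cross_scaffold")
  } else .new_removals()
  list(set = out,
       report = .stage_row("cross_scaffold", "orthology", nrow(tx),
                           length(drop), nrow(out$transcripts)),
       removals = removals)
}

# Collapse micro-introns of a single transcript's exon/CDS interval sets.
# Returns list(exons, cds, joins).
.collapse_tx <- function(ex, cd, strand, min_intron) {
  ex <- ex[order(ex$start), , drop = FALSE]
  joins <- 0L
  i <- 1L
  while (i < nrow(ex)) {
    gap <- ex$start[i + 1] - ex$end[i]
    if (gap < min_intron) {
      ex$end[i] <- ex$end[i + 1]
      ex <- ex[-(i + 1), , drop = FALSE]
      joins <- joins + 1L
    } else {
      i <- i + 1L
    }
  }
  if (joins > 0 && nrow(cd) > 1) {
    cd <- cd[order(cd$start), , drop = FALSE]
    ph0 <- if (strand == "+") cd$phase[1] else cd$phase[nrow(cd)]
    i <- 1L
    while (i < nrow(cd)) {
      gap <- cd$start[i + 1] - cd$end[i]
      if (gap < min_intron) {
        cd$end[i] <- cd$end[i + 1]
        cd <- cd[-(i + 1), , drop = FALSE]
      } else {
        i <- i + 1L
      }
    }
    lens <- cd$end - cd$start
    ord <- if (strand == "+") order(cd$start) else order(-cd$start)
    ph <- integer(nrow(cd))
    cum <- c(0L, cumsum(lens[ord]))[seq_len(nrow(cd))]
    ph[ord] <- as.integer((3L - (cum - (if (is.na(ph0)) 0L else ph0)) %% 3L) %% 3L)
    ph[ord][1] <- if (is.na(ph0)) 0L else ph0
    cd$phase <- ph
  }
  list(exons = ex, cds = cd, joins = joins)
}

#' Join adjacent exons separated by less than `min_intron` bp
#'
#' Merges exon pairs whose gap is below the minimum intron width into one
#' exon spanning both plus the gap, iterated left-to-right to a fixed point.
#' CDS intervals bridging a removed micro-intron are re-unioned and phases
#' recomputed from the 5' CDS end.
#'
#' @param set a [gene_model_set()].
#' @param min_intron smallest genuine intron width in bp; gaps strictly
#'   below it are considered spurious (default 4).
#' @return list(`set`, `report`).
#' @export
collapse_micro_introns <- function(set, min_intron = 4L) {
  exons <- set$exons
  cds <- set$cds
  total_joins <- 0L
  new_ex <- list(); new_cd <- list()
  for (t in set$transcripts$transcript_id) {
    ex <- exons[exons$transcript_id == t, c("start", "end"), drop = FALSE]
    cd <- cds[cds$transcript_id == t, c("start", "end", "phase"), drop = FALSE]
    strand <- set$transcripts$strand[set$transcripts$transcript_id == t]
    r <- .collapse_tx(ex, cd, strand, min_intron)
    total_joins <- total_joins + r$joins
    if (nrow(r$exons)) {
      new_ex[[t]] <- data.frame(transcript_id = t, r$exons)
    }
    if (nrow(r$cds)) {
      new_cd[[t]] <- data.frame(transcript_id = t, r$cds)
    }
  }
  out <- gene_model_set(set$transcripts,
                        do.call(rbind, new_ex) %||0% set$exons[0, ],
                        do.call(rbind, new_cd) %||0% set$cds[0, ])
  list(set = out,
       report = .stage_row("collapse_micro_introns", "orthology",
                           nrow(set$transcripts), 0L, nrow(set$transcripts),
                           detail = sprintf("exon_joins=%d", total_joins)))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Keep only orthology predictions of allowed loss classes
#'
#' @param set a [gene_model_set()]; every orthology transcript must carry a
#'   `loss_class`.
#' @param allowed loss classes to keep.
#' @return list(`set`, `report`, `removals`).
#' @export
filter_orthology_classes <- function(set,
                                     allowed = c("intact", "partially intact",
                                                 "uncertain loss")) {
  tx <- set$transcripts
  orth <- tx$source == "orthology"
  if (any(orth & is.na(tx$loss_class))) {
    bad <- tx$transcript_id[orth & is.na(tx$loss_class)][1]
    stop("orthology transcript ", bad, " has no loss_class")
  }
  drop_sel <- orth & !(tx$loss_class %in% allowed)
  drop <- tx$transcript_id[drop_sel]
  out <- subset_transcripts(set, setdiff(tx$transcript_id, drop))
  removals <- if (length(drop)) {
    data.frame(stage = "loss_class", transcript_id = drop,
               reason = paste0("loss_class:", tx$loss_class[drop_sel]))
  } else .new_removals()
  list(set = out,
       report = .stage_row("loss_class", "orthology", nrow(tx), length(drop),
                           nrow(out$transcripts)),
       removals = removals)
}

# ORF verdict for one spliced CDS: "ok" or a removal reason.
.orf_verdict <- function(cds_seq) {
  if (nchar(cds_seq) == 0) return("no_cds")
  if (nchar(cds_seq) %% 3 != 0) return("frame")
  if (substring(cds_seq, 1, 3) != "ATG") return("missing_start")
  aa <- suppressWarnings(translate_cds(cds_seq))
  n <- nchar(aa)
  body <- substring(aa, 1, n - 1)
  if (grepl("*", body, fixed = TRUE)) return("internal_stop")
  if (substring(aa, n, n) != "*") return("missing_stop")
  "ok"
}

#' Remove transcripts without a complete, stop-free ORF
#'
#' Each transcript's CDS is spliced in translation order (reverse
#' complemented on the minus strand), phase-trimmed and translated with the
#' standard code. Transcripts are kept only if the ORF starts with `ATG`,
#' the final codon is a stop, and no stop occurs earlier. Removal reasons
#' are one of `frame`, `missing_start`, `internal_stop`, `missing_stop`.
#'
#' @param set a [gene_model_set()].
#' @param genome a [contig_set()] holding every referenced contig.
#' @return list(`set`, `report`, `removals`).
#' @export
validate_orfs <- function(set, genome) {
  tx <- set$transcripts
  reasons <- character(0)
  drop <- character(0)
  for (t in tx$transcript_id) {
    verdict <- .orf_verdict(spliced_cds(set, t, genome))
    if (verdict != "ok") {
      drop <- c(drop, t)
      reasons <- c(reasons, verdict)
    }
  }
  out <- subset_transcripts(set, setdiff(tx$transcript_id, drop))
  removals <- if (length(drop)) {
    data.frame(stage = "orf", transcript_id = drop, reason = reasons)
  } else .new_removals()
  list(set = out,
       report = .stage_row("orf", tx$source[1] %||% "", nrow(tx), length(drop),
                           nrow(out$transcripts)),
       removals = removals)
}

# isoform identity key: intron chain for multi-exon transcripts, CDS span
# for mono-exon ones; always scoped to contig and strand
.isoform_keys <- function(set) {
  tx <- set$transcripts
  vapply(tx$transcript_id, function(t) {
    ex <- set$exons[set$exons$transcript_id == t, , drop = FALSE]
    row <- tx[tx$transcript_id == t, ]
    if (nrow(ex) >= 2) {
      paste(row$contig, row$strand, "chain", intron_chain_key(ex), sep = "|")
    } else {
      cd <- set$cds[set$cds$transcript_id == t, , drop = FALSE]
      paste(row$contig, row$strand, "span",
            if (nrow(cd)) paste0(min(cd$start), "-", max(cd$end)) else "none",
            sep = "|")
    }
  }, character(1))
}

#' Complement the evidence set with unique orthology transcripts
#'
#' Orthology transcripts whose isoform key (identical ordered intron chain
#' on the same contig and strand; identical CDS span for mono-exon
#' transcripts) matches an evidence transcript are dropped as duplicates.
#' The remaining orthology transcripts are attached as new isoforms to the
#' evidence gene whose span they overlap most (ties to the gene with the
#' smaller start), or founded as new genes when they overlap none. Evidence
#' transcripts are never modified or removed.
#'
#' @param evidence,orthology cleaned [gene_model_set()]s.
#' @param genome optional [contig_set()]; when supplied, both inputs are
#'   checked to contain only valid ORFs and an error is raised otherwise.
#' @return list(`set`, `report`, `stats`): the merged set, a stage report,
#'   and overlap statistics (shared loci, unique to either set, added
#'   isoforms/genes, dropped duplicates).
#' @export
merge_gene_sets <- function(evidence, orthology, genome = NULL) {
  if (!is.null(genome)) {
    for (nm in c("evidence", "orthology")) {
      s <- if (nm == "evidence") evidence else orthology
      for (t in s$transcripts$transcript_id) {
        v <- .orf_verdict(spliced_cds(s, t, genome))
        if (v != "ok") {
          stop("uncleaned ", nm, " input: transcript ", t, " fails ORF check (", v, ")")
        }
      }
    }
  }
  ev_keys <- .isoform_keys(evidence)
  or_keys <- .isoform_keys(orthology)
  dup <- or_keys %in% ev_keys
  uniq_ids <- orthology$transcripts$transcript_id[!dup]

  # evidence gene spans
  ev_spans <- transcript_spans(evidence)
  ev_genes <- unique(ev_spans$gene_id)
  gsp <- do.call(rbind, lapply(ev_genes, function(g) {
    sp <- ev_spans[ev_spans$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, contig = sp$contig[1], strand = sp$strand[1],
               start = min(sp$start), end = max(sp$end))
  }))
  or_spans <- transcript_spans(orthology)

  tx <- orthology$transcripts
  added_iso <- 0L; new_gene_map <- character(0)
  attach_gene <- stats::setNames(rep(NA_character_, length(uniq_ids)), uniq_ids)
  for (t in uniq_ids) {
    sp <- or_spans[or_spans$transcript_id == t, ]
    cand <- gsp[gsp$contig == sp$contig & gsp$strand == sp$strand &
                  gsp$start < sp$end & sp$start < gsp$end, , drop = FALSE]
    if (nrow(cand)) {
      ov <- pmin(cand$end, sp$end) - pmax(cand$start, sp$start)
      best <- cand[order(-ov, cand$start), , drop = FALSE][1, ]
      attach_gene[t] <- best$gene_id
      added_iso <- added_iso + 1L
    }
  }
  founded <- uniq_ids[is.na(attach_gene)]

  out_tx <- evidence$transcripts
  out_ex <- evidence$exons
  out_cd <- evidence$cds
  if (length(uniq_ids)) {
    add_tx <- tx[tx$transcript_id %in% uniq_ids, , drop = FALSE]
    add_tx$gene_id <- ifelse(is.na(attach_gene[add_tx$transcript_id]),
                             add_tx$gene_id,
                             attach_gene[add_tx$transcript_id])
    out_tx <- rbind(out_tx, add_tx)
    out_ex <- rbind(out_ex, orthology$exons[orthology$exons$transcript_id %in% uniq_ids, ])
    out_cd <- rbind(out_cd, orthology$cds[orthology$cds$transcript_id %in% uniq_ids, ])
  }
  merged <- gene_model_set(out_tx, out_ex, out_cd)

  # overlap statistics at gene (locus) level
  or_gene_overlaps <- vapply(unique(or_spans$gene_id), function(g) {
    sp <- or_spans[or_spans$gene_id == g, , drop = FALSE]
    any(gsp$contig %in% sp$contig &
          gsp$start < max(sp$end) & min(sp$start) < gsp$end &
          gsp$strand == sp$strand[1] & gsp$contig == sp$contig[1])
  }, logical(1))
  stats <- list(
    shared_loci = sum(or_gene_overlaps),
    unique_to_evidence = sum(vapply(ev_genes, function(g) {
      sp <- gsp[gsp$gene_id == g, ]
      !any(or_spans$contig == sp$contig & or_spans$strand == sp$strand &
             or_spans$start < sp$end & sp$start < or_spans$end)
    }, logical(1))),
    unique_to_orthology = length(unique(tx$gene_id[tx$transcript_id %in% founded])),
    dropped_duplicates = sum(dup),
    added_isoforms = added_iso,
    added_genes = length(unique(tx$gene_id[tx$transcript_id %in% founded]))
  )
  list(set = merged,
       report = .stage_row("merge", "both",
                           nrow(evidence$transcripts) + nrow(orthology$transcripts),
                           sum(dup), nrow(merged$transcripts),
                           detail = sprintf("added_isoforms=%d;added_genes=%d",
                                            stats$added_isoforms, stats$added_genes)),
       stats = stats)
}

#' Run the full two-branch reconciliation pipeline
#'
#' Stage order: evidence branch — split multilocus genes, validate ORFs;
#' orthology branch — filter loss classes, drop cross-scaffold transcripts,
#' collapse micro-introns, split multilocus genes, validate ORFs; then the
#' merge that complements the evidence set with unique orthology isoforms.
#'
#' @param evidence_raw,orthology_raw raw [gene_model_set()]s.
#' @param genome a [contig_set()].
#' @param min_intron micro-intron threshold passed to
#'   [collapse_micro_introns()].
#' @return An object of class `reconcile_result`: list with `set` (the
#'   merged [gene_model_set()]), `stages` (per-stage counts), `removals`
#'   (per-transcript removal reasons) and `merge_stats`.
#' @export
reconcile_pipeline <- function(evidence_raw, orthology_raw, genome,
                               min_intron = 4L) {
  stages <- NULL
  removals <- .new_removals()
  tag <- function(r, set_name) { r$report$set <- set_name; r }

  e1 <- tag(split_multilocus_genes(evidence_raw), "evidence")
  stages <- rbind(stages, e1$report)
  e2 <- tag(validate_orfs(e1$set, genome), "evidence")
  stages <- rbind(stages, e2$report); removals <- rbind(removals, e2$removals)

  has_orth <- nrow(orthology_raw$transcripts) > 0
  if (has_orth) {
    o1 <- filter_orthology_classes(orthology_raw)
    stages <- rbind(stages, o1$report); removals <- rbind(removals, o1$removals)
    o2 <- drop_cross_scaffold_transcripts(o1$set)
    stages <- rbind(stages, o2$report); removals <- rbind(removals, o2$removals)
    o3 <- collapse_micro_introns(o2$set, min_intron)
    stages <- rbind(stages, o3$report)
    o4 <- tag(split_multilocus_genes(o3$set), "orthology")
    stages <- rbind(stages, o4$report)
    o5 <- tag(validate_orfs(o4$set, genome), "orthology")
    stages <- rbind(stages, o5$report); removals <- rbind(removals, o5$removals)
    orth_clean <- o5$set
  } else {
    orth_clean <- orthology_raw
  }

  m <- merge_gene_sets(e2$set, orth_clean)
  stages <- rbind(stages, m$report)
  structure(list(set = m$set, stages = stages, removals = removals,
                 merge_stats = m$stats),
            class = "reconcile_result")
}

#' @export
print.reconcile_result <- function(x, ...) {
  cat("reconcile_result:", n_genes(x$set), "gene(s),", n_transcripts(x$set),
      "transcript(s) after merge\n")
  print(x$stages, row.names = FALSE)
  if (nrow(x$removals)) {
    cat("removals by reason:\n")
    print(table(x$removals$reason))
  }
  invisible(x)
}

#' Write the per-stage reconciliation report as TSV
#' @param x a `reconcile_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_reconcile_report <- function(x, path) {
  utils::write.table(x$stages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
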