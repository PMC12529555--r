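# Standard-format readers/writers and truth-vs-prediction comparison.
#
# Annotations are exchanged as GFF3 (1-based inclusive, attribute values
# percent-encoded per the format); genomes as FASTA.  Gene segments are
# written as one parent feature (Sequence Ontology style type
# `<X>_gene_segment`) plus `exon` children carrying the exon role.

#' Write / read a genome FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path File path.
#' @return `write_genome_fasta`: invisibly, `path`; `read_genome_fasta`: a
#'   `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

.SEG_GFF_TYPE <- c(V = "V_gene_segment", D = "D_gene_segment",
                   J = "J_gene_segment", C = "C_gene_segment")

#' Write a locus annotation as GFF3
#'
#' @param ann A [locus_annotation()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(ann, path) {
  segs <- ann$segments
  n_ex <- sum(vapply(segs, function(s) nrow(s$exons), integer(1)))
  rows <- vector("list", length(segs) + n_ex)
  k <- 0L
  for (s in segs) {
    k <- k + 1L
    gr <- GenomicRanges::GRanges(
      s$contig, IRanges::IRanges(segment_start(s), segment_end(s)),
      strand = s$strand)
    gr$type <- .SEG_GFF_TYPE[[s$segment_type]]
    gr$ID <- s$gene_id
    gr$segment_type <- s$segment_type
    gr$locus_type <- if (is.na(s$locus_label)) NA_character_ else s$locus_label
    gr$functionality <- s$functionality
    gr$reasons <- if (length(s$reasons)) paste(s$reasons, collapse = ",")
                  else NA_character_
    gr$source_method <- s$source
    gr$exon_role <- NA_character_
    gr$Parent <- NA_character_
    rows[[k]] <- gr
    for (i in seq_len(nrow(s$exons))) {
      k <- k + 1L
      ex <- GenomicRanges::GRanges(
        s$contig, IRanges::IRanges(s$exons$start[i], s$exons$end[i]),
        strand = s$strand)
      ex$type <- "exon"
      ex$ID <- sprintf("%s.exon%d", s$gene_id, i)
      ex$segment_type <- NA_character_
      ex$locus_type <- NA_character_
      ex$functionality <- NA_character_
      ex$reasons <- NA_character_
      ex$source_method <- NA_character_
      ex$exon_role <- s$exons$role[i]
      ex$Parent <- s$gene_id
      rows[[k]] <- ex
    }
  }
  if (!k) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr_all <- do.call(c, rows)
  rtracklayer::export(gr_all, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation written by [write_gff3()]
#'
#' Restores coordinates, strand, segment type, functionality and reason
#' attributes losslessly.  Lines that do not have nine tab-separated fields
#' raise an error naming the offending line; features with an unrecognised
#' segment type are kept with a warning.
#'
#' @param path File path.
#' @param genome_name Recorded in the annotation's provenance.
#' @return A [locus_annotation()].
#' @export
read_gff3 <- function(path, genome_name = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  bad <- body[vapply(strsplit(raw[body], "\t"), length, integer(1)) != 9L]
  if (length(bad))
    stop("malformed GFF3 line ", bad[1L], ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  # attribute columns are absent when no feature carried them
  get_attr <- function(name, i) {
    if (!name %in% names(df)) return(NA_character_)
    v <- df[[name]][i]
    if (is.na(v)) NA_character_ else as.character(v)
  }
  is_parent <- df$type != "exon"
  known <- df$type[is_parent] %in% .SEG_GFF_TYPE
  if (any(!known))
    warning("unknown segment type(s) kept as-is: ",
            paste(unique(df$type[is_parent][!known]), collapse = ", "))
  segs <- list()
  for (i in which(is_parent)) {
    gid <- df$ID[i]
    stype <- get_attr("segment_type", i)
    if (is.na(stype))
      stype <- names(.SEG_GFF_TYPE)[match(df$type[i], .SEG_GFF_TYPE)]
    if (is.na(stype)) stype <- "V"      # passthrough for unknown types
    ex_rows <- which(df$type == "exon" &
                       vapply(df$Parent, function(p) gid %in% p, logical(1)))
    exons <- if (length(ex_rows))
      data.frame(role = vapply(ex_rows, function(r) {
                   v <- get_attr("exon_role", r)
                   if (is.na(v)) "V_EXON" else v
                 }, character(1)),
                 start = df$start[ex_rows], end = df$end[ex_rows])
    else data.frame(role = "V_EXON", start = df$start[i], end = df$end[i])
    reason_str <- get_attr("reasons", i)
    reasons <- if (is.na(reason_str)) character(0)
               else strsplit(reason_str, ",")[[1]]
    fun <- get_attr("functionality", i)
    src <- get_attr("source_method", i)
    segs[[length(segs) + 1L]] <- gene_segment(
      gene_id = gid, segment_type = stype,
      contig = as.character(df$seqnames[i]),
      strand = as.character(df$strand[i]), exons = exons,
      locus_label = get_attr("locus_type", i),
      functionality = if (is.na(fun)) "unclassified" else fun,
      reasons = reasons,
      source = if (is.na(src)) "homology" else src)
  }
  locus_annotation(segs, genome_name = genome_name,
                   metadata = list(source = path))
}

#' Compare a predicted annotation with the truth
#'
#' Greedy one-to-one matching of same-type, same-contig segments whose
#' boundary offsets are each within `tolerance` bp.  Precision is
#' `matched / predicted` (NA when nothing was predicted) and recall
#' `matched / truth`.
#'
#' @param pred,truth [locus_annotation()] objects over the same contig
#'   namespace.
#' @param tolerance Maximum per-boundary offset (bp); 0 (default) demands
#'   exact coordinates.
#' @return A list of class `comparison_report`: `n_truth`, `n_predicted`,
#'   `n_matched`, `precision`, `recall`, `per_type`, `coordinate_tolerance`.
#' @export
compare_to_truth <- function(pred, truth, tolerance = 0L) {
  pd <- as.data.frame(pred)
  td <- as.data.frame(truth)
  types <- sort(unique(c(pd$segment_type, td$segment_type)))
  per_type <- list()
  n_matched <- 0L
  for (tp in types) {
    p <- pd[pd$segment_type == tp, , drop = FALSE]
    t <- td[td$segment_type == tp, , drop = FALSE]
    used <- logical(nrow(p))
    m <- 0L
    if (nrow(t)) for (i in order(t$start)) {
      cand <- which(!used & p$contig == t$contig[i] &
                      abs(p$start - t$start[i]) <= tolerance &
                      abs(p$end - t$end[i]) <= tolerance)
      if (length(cand)) {
        used[cand[1L]] <- TRUE
        m <- m + 1L
      }
    }
    n_matched <- n_matched + m
    per_type[[tp]] <- data.frame(
      segment_type = tp, n_truth = nrow(t), n_predicted = nrow(p),
      n_matched = m,
      precision = if (nrow(p)) m / nrow(p) else NA_real_,
      recall = if (nrow(t)) m / nrow(t) else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(
    n_truth = nrow(td), n_predicted = nrow(pd), n_matched = n_matched,
    precision = if (nrow(pd)) n_matched / nrow(pd) else NA_real_,
    recall = if (nrow(td)) n_matched / nrow(td) else NA_real_,
    per_type = do.call(rbind, per_type),
    coordinate_tolerance = tolerance), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("<comparison_report> truth=%d predicted=%d matched=%d ",
                     "precision=%s recall=%s (tolerance %d bp)\n"),
              x$n_truth, x$n_predicted, x$n_matched,
              format(x$precision, digits = 4), format(x$recall, digits = 4),
              x$coordinate_tolerance))
  invisible(x)
}

#' Write an expression-evidence table
#'
#' @param expression `data.frame` with `gene_id`, `v_expressed`,
#'   `sp_expressed`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_expression_evidence <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
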