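# Core containers: gene segments and locus annotations.
#
# A gene segment is a light-weight list describing one V, D, J or C gene
# model: its exons (with roles), any linked recombination signal sequences,
# and a functionality call with explicit reason codes.  A locus annotation is
# an ordered collection of segments for one contig namespace.

#' Construct a gene segment
#'
#' @param gene_id Character identifier, unique within an annotation.
#' @param segment_type One of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param contig Name of the sequence the segment lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `role`, `start`, `end` (1-based
#'   inclusive).  Roles are drawn from `L1`, `V_EXON`, `J_EXON`, `D_CORE`,
#'   `C_IG`, `M1`, `M2`.  Exons must be non-overlapping and ordered along
#'   the genome.
#' @param rss_links `data.frame` of RSS hits (rows of the table returned by
#'   [scan_rss()]) associated with this segment, or `NULL`.
#' @param locus_label Optional locus name (e.g. `"TRA"`, `"TRB"`).
#' @param functionality `"F"`, `"P"` or `"unclassified"`.
#' @param reasons Character vector of rule identifiers explaining a `"P"`
#'   verdict (see [classify_segment()] for the enumeration).
#' @param source Provenance: `"homology"`, `"rss_pair"`, `"fixture"` or
#'   `"truth"`.
#' @param score Numeric alignment score backing the model (NA when the model
#'   is RSS-derived only).
#' @param evidence Named list of free-form evidence fields (e.g. J motif
#'   status).
#'
#' @return An object of class `gene_segment`.
#' @export
gene_segment <- function(gene_id, segment_type, contig, strand, exons,
                         rss_links = NULL, locus_label = NA_character_,
                         functionality = "unclassified",
                         reasons = character(0), source = "homology",
                         score = NA_real_, evidence = list()) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  segment_type <- match.arg(segment_type, c("V", "D", "J", "C"))
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.data.frame(exons), all(c("role", "start", "end") %in% names(exons)),
            nrow(exons) >= 1L, all(exons$end >= exons$start))
  exons <- exons[order(exons$start), c("role", "start", "end"), drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons of '", gene_id, "' overlap")
  structure(
    list(gene_id = gene_id, segment_type = segment_type, contig = contig,
         strand = strand, exons = exons, rss_links = rss_links,
         locus_label = locus_label, functionality = functionality,
         reasons = reasons, source = source, score = score,
         evidence = evidence),
    class = "gene_segment")
}

#' @export
print.gene_segment <- function(x, ...) {
  cat(sprintf("<gene_segment> %s [%s%s] %s:%d-%d (%s) %s\n",
              x$gene_id, x$segment_type,
              if (!is.na(x$locus_label)) paste0("/", x$locus_label) else "",
              x$contig, segment_start(x), segment_end(x), x$strand,
              x$functionality))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Genomic span of a gene segment (exon extent)
#'
#' @param seg A `gene_segment`.
#' @return Integer coordinate.
#' @export
segment_start <- function(seg) min(seg$exons$start)

#' @rdname segment_start
#' @export
segment_end <- function(seg) max(seg$exons$end)

#' Construct a locus annotation
#'
#' An ordered collection of [gene_segment()] objects plus provenance
#' metadata.  Segments are kept sorted by contig and start coordinate.
#'
#' @param segments List of `gene_segment` objects.
#' @param genome_name Name recorded as provenance (e.g. the FASTA the
#'   segments were annotated on).
#' @param metadata Named list of free-form provenance fields.
#'
#' @return An object of class `locus_annotation`.
#' @export
locus_annotation <- function(segments = list(), genome_name = NA_character_,
                             metadata = list()) {
  stopifnot(is.list(segments),
            all(vapply(segments, inherits, logical(1), "gene_segment")))
  if (length(segments)) {
    ord <- order(vapply(segments, function(s) s$contig, character(1)),
                 vapply(segments, segment_start, numeric(1)))
    segments <- segments[ord]
  }
  structure(list(segments = segments, genome_name = genome_name,
                 metadata = metadata),
            class = "locus_annotation")
}

#' @export
length.locus_annotation <- function(x) length(x$segments)

#' @export
print.locus_annotation <- function(x, ...) {
  tab <- table(vapply(x$segments, function(s) s$segment_type, character(1)))
  cat(sprintf("<locus_annotation> %d segment(s)", length(x)))
  if (length(tab))
    cat(" [", paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "), "]")
  cat("\n")
  invisible(x)
}

#' Flatten a locus annotation to a data frame
#'
#' One row per segment with its span, verdict and reasons; exon detail is
#' collapsed into a `role:start-end` list column representation.
#'
#' @param x A `locus_annotation`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.locus_annotation <- function(x, ...) {
  if (!length(x$segments)) {
    return(data.frame(gene_id = character(0), segment_type = character(0),
                      locus_label = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_exons = integer(0),
                      functionality = character(0), reasons = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$segments, function(s) {
    data.frame(gene_id = s$gene_id, segment_type = s$segment_type,
               locus_label = s$locus_label, contig = s$contig,
               start = segment_start(s), end = segment_end(s),
               strand = s$strand, n_exons = nrow(s$exons),
               functionality = s$functionality,
               reasons = paste(s$reasons, collapse = ","),
               source = s$source, stringsAsFactors = FALSE)
  }))
}

#' Subset the segments of an annotation by type
#'
#' @param ann A `locus_annotation`.
#' @param segment_type Type to keep (`"V"`, `"D"`, `"J"`, `"C"`).
#' @return A list of `gene_segment` objects.
#' @export
segments_of_type <- function(ann, segment_type) {
  Filter(function(s) s$segment_type == segment_type, ann$segments)
}
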