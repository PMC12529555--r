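# End-to-end annotation: RSS scan, homology seeding, gene-model assembly,
# redundancy reduction, classification.

#' Annotate a genome for germline V/D/J/C gene segments
#'
#' Runs the full pipeline: (1) RSS scan on both strands (with
#' `require_cac = FALSE`, so CAC-defective signals are recovered and the
#' classifier - not the scanner - applies the CAC criterion); (2) translated
#' homology search for V, signal-peptide, J and constant-exon references;
#' (3) V-gene assembly (leader + intron + V-exon + downstream 23-RSS),
#' J detection from upstream 12-RSS hits, D detection from 12/23 flanking
#' pairs, C assembly from per-exon seeds; (4) redundancy reduction and
#' signal-peptide confirmation; (5) functionality classification.
#'
#' @param genome Genome sequences (named [Biostrings::DNAStringSet], file
#'   path accepted via [read_genome_fasta()] upstream).
#' @param references List with elements `v` (V-exon proteins), `sp` (leader
#'   L1 peptides), `j` (J peptides), `c` (constant-exon peptides) and
#'   `c_roles` (named map reference id -> exon role).  Only `v` is
#'   mandatory.
#' @param expression Optional expression-evidence table (see
#'   [read_expression_evidence()]).
#' @param cfg A [seeding_config()].
#' @param rss A [rss_params()]; the default used here differs from
#'   `rss_params()` only in `require_cac = FALSE` (see above).
#' @param classifier A [classifier_config()].
#' @param locus_label Label stamped on all output segments.
#'
#' @return A classified [locus_annotation()].
#' @export
annotate_genome <- function(genome, references, expression = NULL,
                            cfg = seeding_config(),
                            rss = rss_params(require_cac = FALSE),
                            classifier = classifier_config(),
                            locus_label = "locus") {
  genome <- as_genome(genome)
  stopifnot(is.list(references), !is.null(references$v))
  hits <- scan_rss(genome, rss)

  v_seeds <- seed_hits(genome, references$v, cfg)
  sp_seeds <- if (!is.null(references$sp))
    seed_hits(genome, references$sp, cfg, min_score = cfg$sp_min_score)
  else NULL
  j_seeds <- if (!is.null(references$j))
    seed_hits(genome, references$j, cfg, min_score = cfg$j_min_score)
  else NULL
  c_seeds <- if (!is.null(references$c))
    seed_hits(genome, references$c, cfg)
  else NULL

  v_segs <- if (nrow(v_seeds)) lapply(seq_len(nrow(v_seeds)), function(i)
    assemble_v_gene(v_seeds[i, ], hits, genome, cfg, sp_seeds,
                    gene_id = sprintf("V_seed_%d", i)))
  else list()
  j_segs <- detect_j_genes(genome, hits, j_seeds)
  d_segs <- detect_d_candidates(genome, hits)
  c_segs <- if (!is.null(c_seeds) && !is.null(references$c_roles))
    assemble_c_genes(c_seeds, references$c_roles)
  else list()

  segs <- reduce_and_confirm(c(v_segs, j_segs, d_segs, c_segs), sp_seeds)

  # stable ids in coordinate order, per type
  counters <- c(V = 0L, D = 0L, J = 0L, C = 0L)
  segs <- lapply(segs, function(s) {
    counters[s$segment_type] <<- counters[s$segment_type] + 1L
    s$gene_id <- sprintf("%s%s_%03d", locus_label, s$segment_type,
                         counters[s$segment_type])
    s$locus_label <- locus_label
    s
  })

  ann <- locus_annotation(segs, genome_name = names(genome)[1L],
                          metadata = list(pipeline = "annotate_genome"))
  classify_annotation(ann, genome, expression, classifier)
}
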