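# Functional / pseudogene classification.
#
# A segment is functional (F) only when every rule of its type-specific set
# passes; otherwise it is a pseudogene (P) and every failing rule is
# recorded as a stable reason code.  The rule sets follow IMGT-style
# criteria: an intact open reading frame across spliced exons, proper
# GT...AG splice sites, the conserved V framework residues (Cys23, Trp41,
# Trp52, Cys104 in IMGT numbering), intact recombination signals obeying
# the 12/23 spacer classes, the J di-glycine bulge (FGXG), and - under the
# expression-requiring policies - transcription evidence for the V region
# and its signal peptide.
#
# Reason code enumeration (stable, in evaluation order):
#   missing_leader, splice_donor, splice_acceptor, frameshift,
#   no_start_codon, orf_stop, conserved_residue_<pos>, rss_absent,
#   rss_heptamer_cac, rss_spacer_class, j_motif_absent, rss_missing_5p,
#   rss_missing_3p, rss_pair_violation, c_exon_missing_<role>,
#   expression_absent

#' Classifier configuration
#'
#' @param conserved_v_residues Named character vector mapping V-region
#'   (IMGT) position to the required residue.
#' @param j_motif Regular expression for the J motif; the default `FG.G`
#'   encodes FGXG with X any residue.
#' @param j_motif_strict When `TRUE` (default) a missing J motif is a
#'   pseudogene cause; when `FALSE` it is recorded as a warning in the
#'   call's `warnings` instead (some loci carry functional J genes with a
#'   divergent motif, e.g. FKKG).
#' @param require_rss,require_splice_sites Toggle the structural rule
#'   groups.
#' @param expression_policy `"structural_only"`,
#'   `"require_gene_expression"` or `"require_gene_and_sp_expression"`
#'   (default, the strictest policy: a structurally intact V without
#'   evidence of both V-region and signal-peptide expression is a
#'   pseudogene).
#' @param l1_aa_len,l2_aa_len Residues of the leader peptide encoded by the
#'   L1 exon and by the start of the V-exon; their sum is the offset at
#'   which V-region (IMGT) numbering starts in the spliced translation.
#' @param nglyc_pattern Regular expression for N-glycosylation sequons.
#'
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(conserved_v_residues = c(`23` = "C", `41` = "W",
                                                       `52` = "W", `104` = "C"),
                              j_motif = "FG.G",
                              j_motif_strict = TRUE,
                              require_rss = TRUE,
                              require_splice_sites = TRUE,
                              expression_policy = c(
                                "require_gene_and_sp_expression",
                                "require_gene_expression",
                                "structural_only"),
                              l1_aa_len = 15L,
                              l2_aa_len = 4L,
                              nglyc_pattern = "N[^P][ST]") {
  expression_policy <- match.arg(expression_policy)
  stopifnot(length(conserved_v_residues) > 0, nzchar(j_motif))
  structure(as.list(environment()), class = "classifier_config")
}

.translate_chr <- function(dna_chr) {
  n <- nchar(dna_chr) %/% 3L
  if (n == 0L) return("")
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(dna_chr, 1L, 3L * n)))))
}

# Spliced coding sequence of a segment, reading in gene orientation.
.spliced_cds <- function(seg, seq, roles = NULL) {
  ex <- seg$exons
  if (!is.null(roles)) ex <- ex[ex$role %in% roles, , drop = FALSE]
  if (!nrow(ex)) return("")
  parts <- vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(seq, ex$start[i], ex$end[i])),
    character(1))
  cds <- paste(parts, collapse = "")
  if (seg$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

# Splice dinucleotide immediately flanking an exon boundary, in gene
# orientation ("donor" follows the upstream exon, "acceptor" precedes the
# downstream exon).
.flank_dinuc <- function(seq, pos, side, strand) {
  L <- length(seq)
  if (strand == "+") {
    rng <- if (side == "donor") c(pos + 1L, pos + 2L) else c(pos - 2L, pos - 1L)
    if (rng[1L] < 1L || rng[2L] > L) return("")
    as.character(Biostrings::subseq(seq, rng[1L], rng[2L]))
  } else {
    rng <- if (side == "donor") c(pos - 2L, pos - 1L) else c(pos + 1L, pos + 2L)
    if (rng[1L] < 1L || rng[2L] > L) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(seq, rng[1L], rng[2L])))
  }
}

.rss_reasons <- function(links, wanted_class) {
  if (is.null(links) || !nrow(links)) return("rss_absent")
  cand <- links[links$spacer_class == wanted_class, , drop = FALSE]
  if (!nrow(cand)) return("rss_spacer_class")
  if (!any(cand$cac_intact)) return("rss_heptamer_cac")
  character(0)
}

#' Classify a gene segment as functional or pseudogene
#'
#' Applies the type-specific rule set (see the reason-code enumeration in
#' the package source) and returns the verdict with every failing rule
#' listed in evaluation order.
#'
#' @param seg A [gene_segment()] with exon coordinates resolvable in
#'   `genome`.
#' @param genome Genome sequences.
#' @param expression Optional expression-evidence table (`gene_id`,
#'   `v_expressed`, `sp_expressed`); rows absent from the table count as
#'   not-expressed under expression-requiring policies.  When no table is
#'   supplied at all, expression rules are skipped (structural-only
#'   behaviour).
#' @param cfg A [classifier_config()].
#'
#' @return A list of class `functionality_call`: `verdict` (`"F"`/`"P"`),
#'   `reasons`, `warnings`, `policy_used`.
#' @export
classify_segment <- function(seg, genome, expression = NULL,
                             cfg = classifier_config()) {
  genome <- as_genome(genome)
  if (!seg$contig %in% names(genome))
    stop("segment contig '", seg$contig, "' not in genome")
  seq <- genome[[seg$contig]]
  if (segment_start(seg) < 1L || segment_end(seg) > length(seq))
    stop("segment '", seg$gene_id, "' outside genome coordinates")
  reasons <- character(0)
  warnings <- character(0)

  if (seg$segment_type == "V") {
    has_leader <- "L1" %in% seg$exons$role
    if (!has_leader) reasons <- c(reasons, "missing_leader")
    if (has_leader && cfg$require_splice_sites) {
      l1 <- seg$exons[seg$exons$role == "L1", ]
      ve <- seg$exons[seg$exons$role == "V_EXON", ]
      don_pos <- if (seg$strand == "+") l1$end else l1$start
      acc_pos <- if (seg$strand == "+") ve$start else ve$end
      if (!identical(.flank_dinuc(seq, don_pos, "donor", seg$strand), "GT"))
        reasons <- c(reasons, "splice_donor")
      if (!identical(.flank_dinuc(seq, acc_pos, "acceptor", seg$strand), "AG"))
        reasons <- c(reasons, "splice_acceptor")
    }
    cds <- .spliced_cds(seg, seq, roles = c("L1", "V_EXON"))
    if (nchar(cds) %% 3L != 0L) reasons <- c(reasons, "frameshift")
    prot <- .translate_chr(cds)
    if (has_leader && substr(prot, 1L, 1L) != "M")
      reasons <- c(reasons, "no_start_codon")
    if (grepl("\\*", prot)) reasons <- c(reasons, "orf_stop")
    offset <- if (has_leader) cfg$l1_aa_len + cfg$l2_aa_len else cfg$l2_aa_len
    for (pn in names(cfg$conserved_v_residues)) {
      p <- offset + as.integer(pn)
      if (p > nchar(prot) || substr(prot, p, p) != cfg$conserved_v_residues[[pn]])
        reasons <- c(reasons, paste0("conserved_residue_", pn))
    }
    if (cfg$require_rss)
      reasons <- c(reasons, .rss_reasons(seg$rss_links, 23L))
    if (cfg$expression_policy != "structural_only" && !is.null(expression)) {
      row <- expression[expression$gene_id == seg$gene_id, , drop = FALSE]
      v_ok <- nrow(row) == 1L && row$v_expressed == 1L
      sp_ok <- nrow(row) == 1L && row$sp_expressed == 1L
      ok <- if (cfg$expression_policy == "require_gene_expression") v_ok
            else v_ok && sp_ok
      if (!ok) reasons <- c(reasons, "expression_absent")
    }
  } else if (seg$segment_type == "J") {
    cds <- .spliced_cds(seg, seq, roles = "J_EXON")
    prot <- .translate_chr(cds)
    if (grepl("\\*", prot)) reasons <- c(reasons, "orf_stop")
    if (!grepl(cfg$j_motif, prot)) {
      if (cfg$j_motif_strict) reasons <- c(reasons, "j_motif_absent")
      else warnings <- c(warnings, "j_motif_absent")
    }
    if (cfg$require_rss)
      reasons <- c(reasons, .rss_reasons(seg$rss_links, 12L))
  } else if (seg$segment_type == "D") {
    links <- seg$rss_links
    if (is.null(links) || nrow(links) < 2L) {
      have <- if (!is.null(links) && nrow(links)) links$spacer_class else integer(0)
      if (!12L %in% have) reasons <- c(reasons, "rss_missing_5p")
      if (!23L %in% have) reasons <- c(reasons, "rss_missing_3p")
    } else {
      if (!check_12_23_pair(links[1L, ], links[2L, ]))
        reasons <- c(reasons, "rss_pair_violation")
      if (!all(links$cac_intact)) reasons <- c(reasons, "rss_heptamer_cac")
    }
  } else if (seg$segment_type == "C") {
    for (role in c("C_IG", "M1", "M2"))
      if (!role %in% seg$exons$role)
        reasons <- c(reasons, paste0("c_exon_missing_", role))
  }

  structure(list(verdict = if (length(reasons)) "P" else "F",
                 reasons = reasons, warnings = warnings,
                 policy_used = cfg$expression_policy),
            class = "functionality_call")
}

#' @export
print.functionality_call <- function(x, ...) {
  cat(sprintf("<functionality_call> %s%s\n", x$verdict,
              if (length(x$reasons))
                paste0(" [", paste(x$reasons, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Classify every segment of an annotation
#'
#' @param ann A [locus_annotation()].
#' @inheritParams classify_segment
#' @return The annotation with `functionality` and `reasons` filled in on
#'   every segment.
#' @export
classify_annotation <- function(ann, genome, expression = NULL,
                                cfg = classifier_config()) {
  ann$segments <- lapply(ann$segments, function(s) {
    call <- classify_segment(s, genome, expression, cfg)
    s$functionality <- call$verdict
    s$reasons <- call$reasons
    s$evidence$classifier_warnings <- call$warnings
    s$evidence$policy_used <- call$policy_used
    s
  })
  ann
}

#' Find N-glycosylation sequons in a protein sequence
#'
#' Reports all positions matching N-X-[S/T] with X != P (1-based), each
#' with its 4-residue context as conventionally printed (e.g. `NDTE` for a
#' site at positions 42-45).
#'
#' @param protein Amino-acid sequence (single string over the 20-letter
#'   alphabet).
#' @param cfg A [classifier_config()] (supplies the sequon pattern).
#' @return `data.frame` with columns `position` and `context`.
#' @export
find_nglyc_sites <- function(protein, cfg = classifier_config()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", protein))
    stop("protein contains non-amino-acid characters")
  m <- gregexpr(paste0("(?=", cfg$nglyc_pattern, ")"), protein, perl = TRUE)[[1]]
  pos <- as.integer(m[m > 0])
  if (!length(pos))
    return(data.frame(position = integer(0), context = character(0),
                      stringsAsFactors = FALSE))
  data.frame(position = pos,
             context = substr(rep(protein, length(pos)), pos,
                              pmin(pos + 3L, nchar(protein))),
             stringsAsFactors = FALSE)
}

#' Read an expression-evidence table
#'
#' Tab-separated with columns `gene_id`, `v_expressed` (0/1), `sp_expressed`
#' (0/1).  Genes absent from the table count as not-expressed under
#' expression-requiring policies.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_expression_evidence <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "v_expressed", "sp_expressed")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  tab$v_expressed <- as.integer(tab$v_expressed)
  tab$sp_expressed <- as.integer(tab$sp_expressed)
  tab
}
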