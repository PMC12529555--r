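# Gene-model construction from homology seeds plus RSS evidence.
#
# The built-in seeder is a translated six-frame local-alignment search:
# exact amino-acid k-mer anchors between the reference and each frame
# translation are clustered into candidate windows, and each window is then
# refined with a Smith-Waterman alignment (BLOSUM62) to obtain coordinates,
# score and identity.  External aligner output can be substituted through
# read_seed_table().

#' Seeding configuration
#'
#' @param evalue_threshold Significance cutoff applied to imported seed
#'   tables that carry an `evalue` column (the built-in search filters on
#'   alignment score).
#' @param min_alignment_score Minimum local-alignment score (BLOSUM62) for a
#'   reported seed.
#' @param sp_min_score,j_min_score Score cutoffs used for the short
#'   signal-peptide and J references, which cannot reach the main cutoff.
#' @param max_intron_span Maximum V-intron length (bp) bridged when linking
#'   a leader exon to a V-exon.
#' @param anchor_k Exact amino-acid k-mer length used for anchoring.
#' @param cluster_gap Anchors further apart than this (aa) start a new
#'   candidate window.
#' @param min_intron_len,min_leader_len,max_leader_len Search bounds (bp)
#'   for the leader/intron scan when no signal-peptide evidence is
#'   available.
#' @param rss_attach_window Maximum distance (bp) between a V-exon end and
#'   the heptamer of its downstream RSS.
#' @param gap_opening,gap_extension Alignment gap penalties.
#' @param substitution_matrix Name of the substitution matrix.
#'
#' @return A list of class `seeding_config`.
#' @export
seeding_config <- function(evalue_threshold = 1e-5,
                           min_alignment_score = 100,
                           sp_min_score = 55,
                           j_min_score = 55,
                           max_intron_span = 3000L,
                           anchor_k = 6L,
                           cluster_gap = 40L,
                           min_intron_len = 60L,
                           min_leader_len = 21L,
                           max_leader_len = 60L,
                           rss_attach_window = 5L,
                           gap_opening = 10,
                           gap_extension = 4,
                           substitution_matrix = "BLOSUM62") {
  stopifnot(evalue_threshold > 0, min_alignment_score > 0,
            max_intron_span > 0, anchor_k >= 3L)
  structure(as.list(environment()), class = "seeding_config")
}

.empty_seeds <- function() {
  out <- data.frame(contig = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    frame = character(0), reference_id = character(0),
                    percent_identity = numeric(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("homology_seeds", "data.frame")
  out
}

#' Translated six-frame homology search
#'
#' Compares a genome against amino-acid references in all six reading
#' frames and reports local-alignment seeds above the score cutoff, sorted
#' by score (descending).
#'
#' @param genome Genome sequences (see [scan_rss()] for accepted forms).
#' @param references Named [Biostrings::AAStringSet] (or named character
#'   vector) of reference protein/peptide sequences.
#' @param cfg A [seeding_config()].
#' @param min_score Override of `cfg$min_alignment_score` (used internally
#'   for short references).
#'
#' @return A `data.frame` (class `homology_seeds`) with genomic interval,
#'   strand, frame, reference id, percent identity and score.
#' @export
seed_hits <- function(genome, references, cfg = seeding_config(),
                      min_score = NULL) {
  genome <- as_genome(genome)
  if (is.character(references))
    references <- Biostrings::AAStringSet(references)
  stopifnot(length(references) > 0L)
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  if (is.null(min_score)) min_score <- cfg$min_alignment_score
  submat <- local({
    e <- new.env()
    utils::data(list = cfg$substitution_matrix, package = "Biostrings",
                envir = e)
    get(cfg$substitution_matrix, envir = e)
  })

  out <- list()
  for (nm in names(genome)) {
    seq <- genome[[nm]]
    L <- length(seq)
    if (L < 3L * cfg$anchor_k) next
    for (strand in c("+", "-")) {
      dna <- if (strand == "+") seq else Biostrings::reverseComplement(seq)
      for (off in 0:2) {
        n_cod <- (L - off) %/% 3L
        if (n_cod < cfg$anchor_k) next
        frame_dna <- Biostrings::subseq(dna, off + 1L, off + 3L * n_cod)
        trans <- as.character(suppressWarnings(Biostrings::translate(frame_dna)))
        nt <- nchar(trans)
        kmers <- substring(trans, seq_len(nt - cfg$anchor_k + 1L),
                           cfg$anchor_k:nt)
        for (rid in names(references)) {
          ref <- as.character(references[[rid]])
          nr <- nchar(ref)
          if (nr < cfg$anchor_k) next
          ref_kmers <- unique(substring(ref, seq_len(nr - cfg$anchor_k + 1L),
                                        cfg$anchor_k:nr))
          anchors <- which(kmers %in% ref_kmers)
          if (!length(anchors)) next
          brk <- c(0L, which(diff(anchors) > cfg$cluster_gap), length(anchors))
          for (ci in seq_len(length(brk) - 1L)) {
            cl <- anchors[(brk[ci] + 1L):brk[ci + 1L]]
            ws <- max(1L, min(cl) - nr)
            we <- min(nt, max(cl) + cfg$anchor_k - 1L + nr)
            win <- substr(trans, ws, we)
            al <- Biostrings::pairwiseAlignment(
              pattern = Biostrings::AAString(ref),
              subject = Biostrings::AAString(win),
              type = "local", substitutionMatrix = submat,
              gapOpening = cfg$gap_opening, gapExtension = cfg$gap_extension)
            sc <- Biostrings::score(al)
            if (sc < min_score) next
            srange <- al@subject@range
            aa_s <- ws + S4Vectors::start(srange) - 1L
            aa_e <- ws + S4Vectors::end(srange) - 1L
            # frame-local aa -> local nucleotide -> plus-strand genomic
            ls <- (aa_s - 1L) * 3L + off + 1L
            le <- aa_e * 3L + off
            if (strand == "+") {
              gs <- ls; ge <- le
            } else {
              gs <- L - le + 1L; ge <- L - ls + 1L
            }
            out[[length(out) + 1L]] <- data.frame(
              contig = nm, start = gs, end = ge, strand = strand,
              frame = paste0(strand, off + 1L), reference_id = rid,
              percent_identity = Biostrings::pid(al), score = sc,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(.empty_seeds())
  seeds <- do.call(rbind, out)
  seeds <- seeds[order(-seeds$score, seeds$contig, seeds$start), ]
  rownames(seeds) <- NULL
  class(seeds) <- c("homology_seeds", "data.frame")
  seeds
}

#' Import an external aligner's tabular seeds
#'
#' Reads a tab-separated table with columns `contig`, `start`, `end`,
#' `strand`, `reference_id`, `identity`, `score` and optionally `evalue`,
#' applies the configured cutoffs, and returns a `homology_seeds` table
#' interchangeable with [seed_hits()] output.
#'
#' @param path File path.
#' @param cfg A [seeding_config()].
#' @return A `homology_seeds` data frame.
#' @export
read_seed_table <- function(path, cfg = seeding_config()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "strand", "reference_id", "identity",
            "score")
  if (!all(need %in% names(tab)))
    stop("seed table must have columns: ", paste(need, collapse = ", "))
  keep <- tab$score >= cfg$min_alignment_score
  if ("evalue" %in% names(tab)) keep <- keep & tab$evalue <= cfg$evalue_threshold
  tab <- tab[keep, , drop = FALSE]
  seeds <- data.frame(contig = tab$contig, start = as.integer(tab$start),
                      end = as.integer(tab$end), strand = tab$strand,
                      frame = NA_character_, reference_id = tab$reference_id,
                      percent_identity = tab$identity, score = tab$score,
                      stringsAsFactors = FALSE)
  seeds <- seeds[order(-seeds$score, seeds$contig, seeds$start), ]
  rownames(seeds) <- NULL
  class(seeds) <- c("homology_seeds", "data.frame")
  seeds
}

.subseq_chr <- function(seq, s, e) {
  if (s < 1L || e > length(seq) || e < s) return("")
  as.character(Biostrings::subseq(seq, s, e))
}

#' Assemble a two-exon V gene model from a homology seed
#'
#' Extends a V-exon seed to a leader(L1)-intron-V-exon model: the leader is
#' located from overlapping signal-peptide seeds when supplied (an L1 exon
#' must start with ATG and be followed by a GT splice donor), falling back
#' to the nearest in-frame ATG...GT candidate within `max_intron_span`; the
#' V-exon must be preceded by an AG splice acceptor; and the nearest
#' downstream 23-class RSS within `rss_attach_window` is linked.  Missing
#' components leave the model assembled with provisional reason codes
#' (`missing_leader`, `rss_absent`) for the classifier.
#'
#' @param seed One row of a `homology_seeds` table (V reference).
#' @param rss_hits `rss_hits` table from [scan_rss()].
#' @param genome Genome sequences.
#' @param cfg A [seeding_config()].
#' @param sp_hits Optional `homology_seeds` table for signal-peptide (L1)
#'   references.
#' @param gene_id Identifier for the new segment.
#'
#' @return A [gene_segment()] of type `"V"`.
#' @export
assemble_v_gene <- function(seed, rss_hits, genome, cfg = seeding_config(),
                            sp_hits = NULL, gene_id = "V_candidate") {
  genome <- as_genome(genome)
  if (seed$strand == "-") {
    m <- .mirror_inputs(genome, seed$contig, seed = seed, rss = rss_hits,
                        sp = sp_hits)
    seg <- assemble_v_gene(m$seed, m$rss, m$genome, cfg, m$sp, gene_id)
    return(.mirror_segment(seg, m$L))
  }
  seq <- genome[[seed$contig]]
  vstart <- seed$start; vend <- seed$end
  reasons <- character(0)
  notes <- character(0)

  acceptor_ok <- identical(.subseq_chr(seq, vstart - 2L, vstart - 1L), "AG")

  leader <- NULL
  leader_source <- NA_character_
  if (!is.null(sp_hits) && nrow(sp_hits)) {
    cand <- sp_hits[sp_hits$contig == seed$contig & sp_hits$strand == "+" &
                      sp_hits$end < vstart &
                      (vstart - sp_hits$end - 1L) <= cfg$max_intron_span, ,
                    drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(vstart - cand$end), , drop = FALSE]   # nearest first
      for (i in seq_len(nrow(cand))) {
        s0 <- cand$start[i]; e0 <- cand$end[i]
        if (identical(.subseq_chr(seq, s0, s0 + 2L), "ATG") &&
            identical(.subseq_chr(seq, e0 + 1L, e0 + 2L), "GT")) {
          leader <- c(s0, e0); leader_source <- "sp_evidence"
          break
        }
      }
    }
  }
  if (is.null(leader)) {
    found <- .scan_leader(seq, vstart, vend, cfg)
    if (!is.null(found)) { leader <- found; leader_source <- "atg_gt_scan" }
  }
  if (is.null(leader)) reasons <- c(reasons, "missing_leader")
  if (!acceptor_ok) notes <- c(notes, "splice_acceptor_missing")

  exons <- if (!is.null(leader))
    data.frame(role = c("L1", "V_EXON"),
               start = c(leader[1L], vstart), end = c(leader[2L], vend))
  else data.frame(role = "V_EXON", start = vstart, end = vend)

  link <- NULL
  if (nrow(rss_hits)) {
    cand <- rss_hits[rss_hits$contig == seed$contig & rss_hits$strand == "+" &
                       rss_hits$spacer_class == 23L &
                       rss_hits$hept_start >= vend + 1L &
                       rss_hits$hept_start <= vend + 1L + cfg$rss_attach_window, ,
                     drop = FALSE]
    if (nrow(cand)) link <- cand[order(cand$hept_start), , drop = FALSE][1L, ]
  }
  if (is.null(link)) reasons <- c(reasons, "rss_absent")

  gene_segment(gene_id = gene_id, segment_type = "V", contig = seed$contig,
               strand = "+", exons = exons, rss_links = link,
               functionality = "unclassified", reasons = reasons,
               source = "homology", score = seed$score,
               evidence = list(leader_source = leader_source,
                               splice_acceptor_ok = acceptor_ok,
                               notes = notes,
                               reference_id = seed$reference_id))
}

# Fallback leader search: nearest (smallest-intron) GT...AG candidate with an
# in-frame upstream ATG and a stop-free spliced leader.
.scan_leader <- function(seq, vstart, vend, cfg) {
  if (!identical(.subseq_chr(seq, vstart - 2L, vstart - 1L), "AG"))
    return(NULL)
  v_exon <- .subseq_chr(seq, vstart, vend)
  for (ilen in cfg$min_intron_len:cfg$max_intron_span) {
    gs <- vstart - ilen
    if (gs < cfg$min_leader_len + 1L) break
    if (!identical(.subseq_chr(seq, gs, gs + 1L), "GT")) next
    for (llen in seq(cfg$min_leader_len, cfg$max_leader_len, by = 3L)) {
      m <- gs - llen
      if (m < 1L) break
      if (!identical(.subseq_chr(seq, m, m + 2L), "ATG")) next
      cds <- paste0(.subseq_chr(seq, m, gs - 1L), v_exon)
      n_cod <- nchar(cds) %/% 3L
      prot <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substr(cds, 1L, 3L * n_cod)))))
      if (!grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
        return(c(m, gs - 1L))
    }
  }
  NULL
}

#' Detect J gene models from upstream 12-class RSS hits
#'
#' For every 12-class RSS, reads the adjacent coding frame on the strand the
#' signal serves until the first in-frame GT splice donor and emits a J
#' model when the translated exon contains the configured motif (default
#' FGXG, the di-glycine bulge) or overlaps a J-reference homology seed.
#' Motif presence is recorded as evidence (`canonical` / `non_canonical`),
#' not used as a functionality filter.
#'
#' @param genome Genome sequences.
#' @param rss_hits `rss_hits` table from [scan_rss()].
#' @param j_seeds Optional `homology_seeds` for J references.
#' @param motif Regular expression for the J motif (`.` = any residue).
#' @param min_exon_len,max_exon_len Exon length bounds (bp, multiples of 3
#'   are scanned).
#' @param id_prefix Prefix for generated gene ids.
#'
#' @return List of [gene_segment()] objects of type `"J"`.
#' @export
detect_j_genes <- function(genome, rss_hits, j_seeds = NULL, motif = "FG.G",
                           min_exon_len = 21L, max_exon_len = 90L,
                           id_prefix = "J") {
  genome <- as_genome(genome)
  segs <- list()
  hits12 <- rss_hits[rss_hits$spacer_class == 12L, , drop = FALSE]
  if (!nrow(hits12)) return(segs)
  for (i in seq_len(nrow(hits12))) {
    h <- hits12[i, ]
    seq <- genome[[h$contig]]
    L <- length(seq)
    if (h$strand == "-") {
      # gene on +: coding starts right after the heptamer's high end
      gstart <- h$end + 1L
      found <- .scan_j_exon(as.character(seq), gstart, min_exon_len,
                            max_exon_len, L)
      gene_strand <- "+"
    } else {
      # gene on -: mirror, scan, mirror back
      rc <- as.character(Biostrings::reverseComplement(seq))
      gstart_rc <- (L - h$start + 1L) + 1L
      found <- .scan_j_exon(rc, gstart_rc, min_exon_len, max_exon_len, L)
      if (!is.null(found))
        found$range <- c(L - found$range[2L] + 1L, L - found$range[1L] + 1L)
      gene_strand <- "-"
    }
    if (is.null(found)) next
    has_motif <- grepl(motif, found$prot)
    seed_support <- FALSE
    if (!is.null(j_seeds) && nrow(j_seeds)) {
      ov <- j_seeds$contig == h$contig &
        j_seeds$start <= found$range[2L] & j_seeds$end >= found$range[1L]
      seed_support <- any(ov)
    }
    if (!has_motif && !seed_support) next
    segs[[length(segs) + 1L]] <- gene_segment(
      gene_id = sprintf("%s_cand_%d", id_prefix, length(segs) + 1L),
      segment_type = "J", contig = h$contig, strand = gene_strand,
      exons = data.frame(role = "J_EXON", start = found$range[1L],
                         end = found$range[2L]),
      rss_links = h, functionality = "unclassified",
      source = if (seed_support && !has_motif) "homology" else "rss_pair",
      evidence = list(
        motif_evidence = if (has_motif) "canonical" else "non_canonical",
        has_stop = grepl("\\*", found$prot),
        homology_support = seed_support))
  }
  segs
}

# Scan forward from `gstart` in plus-orientation character string for the
# first codon-boundary GT splice donor; returns exon range and translation.
.scan_j_exon <- function(s_chr, gstart, min_len, max_len, L) {
  for (len in seq(min_len, max_len, by = 3L)) {
    dend <- gstart + len
    if (dend + 1L > nchar(s_chr)) return(NULL)
    if (substr(s_chr, dend, dend + 1L) == "GT") {
      exon <- substr(s_chr, gstart, gstart + len - 1L)
      prot <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(exon))))
      return(list(range = c(gstart, gstart + len - 1L), prot = prot))
    }
  }
  NULL
}

#' Detect candidate D segments from flanking RSS pairs
#'
#' Reports every genomic segment of length `min_d_len..max_d_len` whose 5'
#' flank is an upstream-oriented RSS of `five_prime_class` and whose 3'
#' flank a downstream-oriented RSS of `three_prime_class` (defaults: 12 and
#' 23, the organisation of TRB D genes).  An empty list is a valid,
#' meaningful outcome: loci without D genes produce no candidates.
#'
#' @param genome Genome sequences.
#' @param rss_hits `rss_hits` table.
#' @param max_d_len,min_d_len Length bounds of the D core (bp).
#' @param five_prime_class,three_prime_class Spacer classes required on each
#'   flank.
#' @param id_prefix Prefix for generated gene ids.
#'
#' @return List of [gene_segment()] objects of type `"D"`, each carrying
#'   exactly two RSS links.
#' @export
detect_d_candidates <- function(genome, rss_hits, max_d_len = 40L,
                                min_d_len = 1L, five_prime_class = 12L,
                                three_prime_class = 23L, id_prefix = "D") {
  segs <- list()
  if (!nrow(rss_hits)) return(segs)
  emit <- function(left, right, strand) {
    for (i in seq_len(nrow(left))) {
      h5 <- left[i, ]
      same <- right[right$contig == h5$contig, , drop = FALSE]
      if (!nrow(same)) next
      gap <- same$start - h5$end - 1L
      ok <- which(gap >= min_d_len & gap <= max_d_len)
      for (jj in ok) {
        h3 <- same[jj, ]
        core <- c(h5$end + 1L, h3$start - 1L)
        segs[[length(segs) + 1L]] <<- gene_segment(
          gene_id = sprintf("%s_cand_%d", id_prefix, length(segs) + 1L),
          segment_type = "D", contig = h5$contig, strand = strand,
          exons = data.frame(role = "D_CORE", start = core[1L], end = core[2L]),
          rss_links = rbind(h5, h3), functionality = "unclassified",
          source = "rss_pair")
      }
    }
  }
  # plus-strand gene: upstream signal reads on "-", downstream on "+"
  emit(rss_hits[rss_hits$strand == "-" &
                  rss_hits$spacer_class == five_prime_class, , drop = FALSE],
       rss_hits[rss_hits$strand == "+" &
                  rss_hits$spacer_class == three_prime_class, , drop = FALSE],
       "+")
  # minus-strand gene: downstream signal on "-" (left), upstream on "+" (right)
  emit(rss_hits[rss_hits$strand == "-" &
                  rss_hits$spacer_class == three_prime_class, , drop = FALSE],
       rss_hits[rss_hits$strand == "+" &
                  rss_hits$spacer_class == five_prime_class, , drop = FALSE],
       "-")
  segs
}

#' Assemble constant-gene models from per-exon homology seeds
#'
#' Groups seeds of constant-domain exon references (roles `C_IG`, `M1`,
#' `M2`) that lie close together on one strand into C gene models in role
#' order.
#'
#' @param c_seeds `homology_seeds` for the constant-exon references.
#' @param roles Named character vector mapping `reference_id` to exon role.
#' @param max_link_span Maximum gap (bp) between consecutive exons of one
#'   gene.
#' @param id_prefix Prefix for generated gene ids.
#'
#' @return List of [gene_segment()] objects of type `"C"`.
#' @export
assemble_c_genes <- function(c_seeds, roles, max_link_span = 2000L,
                             id_prefix = "C") {
  segs <- list()
  if (is.null(c_seeds) || !nrow(c_seeds)) return(segs)
  c_seeds <- c_seeds[order(c_seeds$contig, c_seeds$start), , drop = FALSE]
  c_seeds$role <- unname(roles[c_seeds$reference_id])
  for (key in unique(paste(c_seeds$contig, c_seeds$strand))) {
    sub <- c_seeds[paste(c_seeds$contig, c_seeds$strand) == key, ,
                   drop = FALSE]
    i <- 1L
    while (i <= nrow(sub)) {
      grp <- i
      while (i < nrow(sub) &&
             sub$start[i + 1L] - sub$end[i] <= max_link_span &&
             !(sub$role[i + 1L] %in% sub$role[grp])) {
        i <- i + 1L
        grp <- c(grp, i)
      }
      exons <- data.frame(role = sub$role[grp], start = sub$start[grp],
                          end = sub$end[grp])
      segs[[length(segs) + 1L]] <- gene_segment(
        gene_id = sprintf("%s_cand_%d", id_prefix, length(segs) + 1L),
        segment_type = "C", contig = sub$contig[grp[1L]],
        strand = sub$strand[grp[1L]], exons = exons,
        functionality = "unclassified", source = "homology",
        score = sum(sub$score[grp]),
        evidence = list(roles_found = sub$role[grp]))
      i <- i + 1L
    }
  }
  segs
}

#' Reduce redundant gene models and confirm signal peptides
#'
#' Overlapping models of the same type on the same strand are merged to the
#' single highest-scoring one (ties: longer span, then leftmost).  V models
#' lacking an overlapping signal-peptide seed are retained but flagged
#' `sp_confirmed = FALSE` in their evidence.  The operation is idempotent
#' and never increases the segment count.
#'
#' @param segments List of [gene_segment()] objects.
#' @param sp_hits Optional `homology_seeds` of signal-peptide references.
#' @return The reduced list, sorted by contig and start.
#' @export
reduce_and_confirm <- function(segments, sp_hits = NULL) {
  if (!length(segments)) return(segments)
  df <- data.frame(
    idx = seq_along(segments),
    contig = vapply(segments, function(s) s$contig, character(1)),
    type = vapply(segments, function(s) s$segment_type, character(1)),
    strand = vapply(segments, function(s) s$strand, character(1)),
    start = vapply(segments, segment_start, numeric(1)),
    end = vapply(segments, segment_end, numeric(1)),
    score = vapply(segments, function(s)
      if (is.na(s$score)) 0 else s$score, numeric(1)),
    stringsAsFactors = FALSE)
  keep <- integer(0)
  for (grp in split(seq_len(nrow(df)),
                    paste(df$contig, df$type, df$strand))) {
    grp <- grp[order(df$start[grp])]
    cl_end <- df$end[grp[1L]]
    cluster <- grp[1L]
    flush <- function(cluster) {
      best <- cluster[order(-df$score[cluster],
                            -(df$end[cluster] - df$start[cluster]),
                            df$start[cluster])][1L]
      keep <<- c(keep, df$idx[best])
    }
    for (g in grp[-1L]) {
      if (df$start[g] <= cl_end) {
        cluster <- c(cluster, g)
        cl_end <- max(cl_end, df$end[g])
      } else {
        flush(cluster); cluster <- g; cl_end <- df$end[g]
      }
    }
    flush(cluster)
  }
  out <- segments[sort(keep)]
  if (!is.null(sp_hits)) {
    out <- lapply(out, function(s) {
      if (s$segment_type != "V") return(s)
      ov <- nrow(sp_hits) > 0 && any(
        sp_hits$contig == s$contig &
          sp_hits$start <= segment_end(s) & sp_hits$end >= segment_start(s))
      s$evidence$sp_confirmed <- ov
      s
    })
  }
  ord <- order(vapply(out, function(s) s$contig, character(1)),
               vapply(out, segment_start, numeric(1)))
  out[ord]
}

#' Report presence or absence of a gene family in a genome
#'
#' A family is called absent when no homology seed reaches the configured
#' cutoffs; the best sub-threshold score is still reported.  When flanking
#' marker references are supplied their presence is reported alongside,
#' supporting "synteny conserved, gene absent" conclusions.
#'
#' @param genome Genome sequences.
#' @param references Named [Biostrings::AAStringSet] for the family sought.
#' @param cfg A [seeding_config()].
#' @param markers Optional named `AAStringSet` of flanking-marker proteins.
#'
#' @return A list of class `presence_report`: `present`, `best_score`,
#'   `n_seeds`, and a `markers` data frame.
#' @export
locus_presence <- function(genome, references, cfg = seeding_config(),
                           markers = NULL) {
  if (is.character(references)) references <- Biostrings::AAStringSet(references)
  if (length(references) == 0L) stop("empty reference set")
  all_seeds <- seed_hits(genome, references, cfg, min_score = 1)
  present <- nrow(all_seeds) > 0 && any(all_seeds$score >= cfg$min_alignment_score)
  best <- if (nrow(all_seeds)) max(all_seeds$score) else NA_real_
  marker_df <- NULL
  if (!is.null(markers) && length(markers)) {
    marker_df <- do.call(rbind, lapply(names(markers), function(mn) {
      ms <- seed_hits(genome, markers[mn], cfg, min_score = 1)
      data.frame(marker = mn,
                 present = nrow(ms) > 0 &&
                   any(ms$score >= cfg$min_alignment_score),
                 best_score = if (nrow(ms)) max(ms$score) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(present = present, best_score = best,
                 n_seeds = sum(all_seeds$score >= cfg$min_alignment_score),
                 markers = marker_df),
            class = "presence_report")
}

#' @export
print.presence_report <- function(x, ...) {
  cat(sprintf("<presence_report> %s (best score %s, %d seed(s) above cutoff)\n",
              if (x$present) "PRESENT" else "ABSENT",
              if (is.na(x$best_score)) "none" else format(x$best_score),
              x$n_seeds))
  if (!is.null(x$markers)) {
    cat("  flanking markers located:",
        paste(x$markers$marker[x$markers$present], collapse = ", "), "\n")
  }
  invisible(x)
}

# --- strand-mirroring helpers -----------------------------------------

.mirror_inputs <- function(genome, contig, seed = NULL, rss = NULL, sp = NULL) {
  seq <- genome[[contig]]
  L <- length(seq)
  g <- Biostrings::DNAStringSet(Biostrings::reverseComplement(seq))
  names(g) <- contig
  flip <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    df <- df[df$contig == contig, , drop = FALSE]
    s <- L - df$end + 1L; e <- L - df$start + 1L
    df$start <- s; df$end <- e
    if (all(c("hept_start", "hept_end") %in% names(df))) {
      hs <- L - df$hept_end + 1L; he <- L - df$hept_start + 1L
      ns <- L - df$non_end + 1L; ne <- L - df$non_start + 1L
      df$hept_start <- hs; df$hept_end <- he
      df$non_start <- ns; df$non_end <- ne
    }
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  list(genome = g, L = L, seed = flip(seed), rss = flip(rss), sp = flip(sp))
}

.mirror_segment <- function(seg, L) {
  ex <- seg$exons
  s <- L - ex$end + 1L; e <- L - ex$start + 1L
  ex$start <- s; ex$end <- e
  seg$exons <- ex[order(ex$start), , drop = FALSE]
  if (!is.null(seg$rss_links) && nrow(seg$rss_links)) {
    r <- seg$rss_links
    s <- L - r$end + 1L; e <- L - r$start + 1L
    r$start <- s; r$end <- e
    hs <- L - r$hept_end + 1L; he <- L - r$hept_start + 1L
    ns <- L - r$non_end + 1L; ne <- L - r$non_start + 1L
    r$hept_start <- hs; r$hept_end <- he
    r$non_start <- ns; r$non_end <- ne
    r$strand <- ifelse(r$strand == "+", "-", "+")
    seg$rss_links <- r
  }
  seg$strand <- if (seg$strand == "+") "-" else "+"
  seg
}
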