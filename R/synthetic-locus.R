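# Synthetic locus generation.
#
# Builds genome sequences with planted V, D, J and C gene segments and an
# exact truth annotation, so every downstream stage (RSS scanning, gene-model
# assembly, classification, statistics) can be exercised against known
# coordinates.  The planted architecture follows the germline organisation of
# T-cell receptor loci: each V gene is a leader (L1) exon starting with ATG,
# a GT...AG V-intron, a V-exon carrying the conserved Cys/Trp/Trp/Cys
# framework residues, and a downstream 23-spacer RSS; each J gene carries an
# upstream 12-spacer RSS and an FGXG-encoding exon ending at a splice donor;
# each D core is flanked by a 5' 12-spacer and 3' 23-spacer RSS; each C gene
# has C-Ig, M1 and M2 exons separated by GT...AG introns.

# Fixed amino-acid scaffolds.  The V scaffold is a neutral ~100-residue
# sequence with the four framework residues mandated for a functional V
# (Cys at V-region position 23, Trp at 41 and 52, Cys at 104); only those
# four positions are constrained.  The J scaffold carries the canonical
# di-glycine bulge (FGXG) at residues 9-12 and contains no valine, so the
# exon/donor boundary of a planted J is unambiguous.
.SP_AA  <- "MKWTALLLSLLAHFTGVHS"                      # 19 aa: L1 = 1-15, L2 = 16-19
.V_AA   <- "YQALDWYSGDQPWSNIDQFQRHCALKSHDDWFQDRWNYWEWRNRELHQAYGWFLIMIKNTQPQRWYWQPHHDDGLWFTYMIKTHEAFPQITKLLAYPPSESKQC"
.J_AA   <- "MLGREIKEFGQGAILYM"                        # FGXG at 9-12
.CIG_AA <- "YYWREEESRLMIARRKPRRLQLYYQNPPAQNFKYDKYIYFYNDTEHTNQFMAQSETLGIINWSSTAEKIFQKSREAPTYKWRLDSGYQWIKELIIKDLYM"
.M1_AA  <- "ESILWGPMLQRNRPTDEKAPADFEMGMQWGFRNASKILGW"
.M2_AA  <- "MLISPNLRYWPYLQFWLTRDGAPME"

.RSS_HEPT <- "CACAGTG"
.RSS_NON  <- "ACAAAAACC"

.DEFECT_KINDS <- c("frameshift", "premature_stop", "missing_leader",
                   "rss_cac_defect", "no_expression", "missing_j_motif")
# which defect kinds make sense for which segment type
.DEFECTS_BY_TYPE <- list(
  V = c("frameshift", "premature_stop", "missing_leader", "rss_cac_defect",
        "no_expression"),
  J = c("premature_stop", "rss_cac_defect", "missing_j_motif"),
  D = "rss_cac_defect",
  C = character(0))

#' Specify a synthetic locus
#'
#' The specification is the planting plan: how many segments of each type,
#' what fraction of them carry a pseudogenising defect, how defects are
#' mixed, and the length distributions of V-introns and intergenic spacers.
#' Identical spec + seed produces byte-identical output.
#'
#' @param n_v,n_d,n_j,n_c Segment counts (default: the inventory of a
#'   TRA-like locus - 61 V, 0 D, 36 J, 1 C).
#' @param pseudogene_fraction Fraction of V/D/J segments (per type, rounded)
#'   that receive one planted defect.
#' @param defect_mix Named non-negative weights over the defect kinds
#'   `frameshift`, `premature_stop`, `missing_leader`, `rss_cac_defect`,
#'   `no_expression`, `missing_j_motif`.  Weights are renormalised over the
#'   kinds applicable to each segment type.
#' @param v_intron_length_dist List `(name, meanlog, sdlog)`; the default
#'   log-normal has median 240 bp, inside the 80-250 bp range typical of
#'   V-introns, and is configurable up to the much longer introns seen in
#'   some loci.
#' @param intergenic_length_dist List `(name, meanlog, sdlog)`; default
#'   median 300 bp.
#' @param gc_background GC fraction of background/intergenic sequence.
#' @param genome_cap Maximum total genome length (bp); [build_locus()]
#'   rejects plans that exceed it.
#' @param seed Integer seed driving every random choice.
#'
#' @return A list of class `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(n_v = 61L, n_d = 0L, n_j = 36L, n_c = 1L,
                                 pseudogene_fraction = 0.18,
                                 defect_mix = stats::setNames(
                                   rep(1, length(.DEFECT_KINDS)), .DEFECT_KINDS),
                                 v_intron_length_dist = list(
                                   name = "lognormal", meanlog = log(240), sdlog = 0.45),
                                 intergenic_length_dist = list(
                                   name = "lognormal", meanlog = log(300), sdlog = 0.4),
                                 gc_background = 0.43,
                                 genome_cap = 5e6,
                                 seed = 1L) {
  stopifnot(n_v >= 0, n_d >= 0, n_j >= 0, n_c >= 0,
            pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            gc_background > 0, gc_background < 1,
            all(names(defect_mix) %in% .DEFECT_KINDS),
            all(defect_mix >= 0))
  if (pseudogene_fraction > 0 && sum(defect_mix) == 0)
    stop("defect_mix must have positive total weight when pseudogene_fraction > 0")
  structure(list(n_v = as.integer(n_v), n_d = as.integer(n_d),
                 n_j = as.integer(n_j), n_c = as.integer(n_c),
                 pseudogene_fraction = pseudogene_fraction,
                 defect_mix = defect_mix,
                 v_intron_length_dist = v_intron_length_dist,
                 intergenic_length_dist = intergenic_length_dist,
                 gc_background = gc_background,
                 genome_cap = genome_cap,
                 seed = as.integer(seed)),
            class = "synthetic_locus_spec")
}

.random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Synonymous-codon back-translation.  `ban_gt_initial` excludes codons
# starting with GT (valine) so no codon boundary can mimic a splice donor.
.back_translate <- function(protein, ban_gt_initial = FALSE) {
  code <- Biostrings::GENETIC_CODE
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    cand <- names(code)[code == a]
    if (ban_gt_initial) cand <- cand[substr(cand, 1, 2) != "GT"]
    if (!length(cand)) stop("no usable codon for residue ", a)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1))
  paste(codons, collapse = "")
}

.sample_len <- function(dist, n = 1L, min_len = 50L) {
  stopifnot(identical(dist$name, "lognormal"))
  pmax(min_len, as.integer(round(stats::rlnorm(n, dist$meanlog, dist$sdlog))))
}

# --- cassette builders -------------------------------------------------
# Each returns list(seq, exons (relative 1-based), rss (relative), defects).

.rss_fwd <- function(spacer_len, gc, cac_defect = FALSE) {
  hept <- if (cac_defect) sub("^CAC", "AAC", .RSS_HEPT) else .RSS_HEPT
  paste0(hept, .random_dna(spacer_len, gc), .RSS_NON)
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.v_cassette <- function(defects, intron_len, gc) {
  leader <- !("missing_leader" %in% defects)
  exon2_prot <- paste0(substr(.SP_AA, 16, 19), .V_AA)
  exon2 <- .back_translate(exon2_prot)
  if ("premature_stop" %in% defects) {
    # V-region residue 60 -> codon 64 of the exon
    pos <- (63L * 3L) + 1L
    exon2 <- paste0(substr(exon2, 1, pos - 1L), "TAA",
                    substr(exon2, pos + 3L, nchar(exon2)))
  }
  if ("frameshift" %in% defects) {
    pos <- 100L                              # single-base deletion
    exon2 <- paste0(substr(exon2, 1, pos - 1L),
                    substr(exon2, pos + 1L, nchar(exon2)))
  }
  rss <- .rss_fwd(23L, gc, "rss_cac_defect" %in% defects)
  if (leader) {
    l1 <- .back_translate(substr(.SP_AA, 1, 15))      # 45 bp, starts ATG
    intron <- paste0("GT", .random_dna(intron_len - 4L, gc), "AG")
    seqs <- paste0(l1, intron, exon2, rss)
    e2_start <- 45L + intron_len + 1L
    exons <- data.frame(role = c("L1", "V_EXON"),
                        start = c(1L, e2_start),
                        end = c(45L, e2_start + nchar(exon2) - 1L))
  } else {
    seqs <- paste0(exon2, rss)
    exons <- data.frame(role = "V_EXON", start = 1L, end = nchar(exon2))
  }
  vend <- exons$end[nrow(exons)]
  rss_rel <- data.frame(start = vend + 1L, end = vend + nchar(rss),
                        strand = "+", spacer_class = 23L, spacer_len = 23L,
                        hept_start = vend + 1L, hept_end = vend + 7L,
                        non_start = vend + 8L + 23L, non_end = vend + nchar(rss),
                        hept_mm = as.integer("rss_cac_defect" %in% defects),
                        non_mm = 0L,
                        cac_intact = !("rss_cac_defect" %in% defects))
  list(seq = seqs, exons = exons, rss = rss_rel, defects = defects)
}

.j_cassette <- function(defects, gc) {
  prot <- .J_AA
  if ("missing_j_motif" %in% defects) {
    p <- strsplit(prot, "")[[1]]
    p[10:11] <- c("K", "K")                  # FGQG -> FKKG
    prot <- paste(p, collapse = "")
  }
  exon <- .back_translate(prot, ban_gt_initial = TRUE)
  if ("premature_stop" %in% defects) {
    pos <- (4L * 3L) + 1L                    # codon 5
    exon <- paste0(substr(exon, 1, pos - 1L), "TAA",
                   substr(exon, pos + 3L, nchar(exon)))
  }
  rss_up <- .revcomp_chr(.rss_fwd(12L, gc, "rss_cac_defect" %in% defects))
  seqs <- paste0(rss_up, exon, "GT", .random_dna(4L, gc))
  estart <- nchar(rss_up) + 1L
  exons <- data.frame(role = "J_EXON", start = estart,
                      end = estart + nchar(exon) - 1L)
  rss_rel <- data.frame(start = 1L, end = nchar(rss_up),
                        strand = "-", spacer_class = 12L, spacer_len = 12L,
                        hept_start = nchar(rss_up) - 6L, hept_end = nchar(rss_up),
                        non_start = 1L, non_end = 9L,
                        hept_mm = as.integer("rss_cac_defect" %in% defects),
                        non_mm = 0L,
                        cac_intact = !("rss_cac_defect" %in% defects))
  list(seq = seqs, exons = exons, rss = rss_rel, defects = defects)
}

.d_cassette <- function(defects, gc, core_len = 14L) {
  cac_def <- "rss_cac_defect" %in% defects
  rss_up <- .revcomp_chr(.rss_fwd(12L, gc, cac_def))   # defect goes 5'
  core <- .random_dna(core_len, gc)
  rss_dn <- .rss_fwd(23L, gc, FALSE)
  seqs <- paste0(rss_up, core, rss_dn)
  cstart <- nchar(rss_up) + 1L
  cend <- cstart + core_len - 1L
  exons <- data.frame(role = "D_CORE", start = cstart, end = cend)
  rss_rel <- data.frame(
    start = c(1L, cend + 1L),
    end = c(nchar(rss_up), cend + nchar(rss_dn)),
    strand = c("-", "+"), spacer_class = c(12L, 23L),
    spacer_len = c(12L, 23L),
    hept_start = c(nchar(rss_up) - 6L, cend + 1L),
    hept_end = c(nchar(rss_up), cend + 7L),
    non_start = c(1L, cend + 8L + 23L),
    non_end = c(9L, cend + nchar(rss_dn)),
    hept_mm = c(as.integer(cac_def), 0L), non_mm = c(0L, 0L),
    cac_intact = c(!cac_def, TRUE))
  list(seq = seqs, exons = exons, rss = rss_rel, defects = defects)
}

.c_cassette <- function(gc, intron_len = 150L) {
  e1 <- .back_translate(.CIG_AA)
  e2 <- .back_translate(.M1_AA)
  e3 <- .back_translate(.M2_AA)
  i1 <- paste0("GT", .random_dna(intron_len - 4L, gc), "AG")
  i2 <- paste0("GT", .random_dna(intron_len - 4L, gc), "AG")
  seqs <- paste0(e1, i1, e2, i2, e3)
  s2 <- nchar(e1) + intron_len + 1L
  s3 <- s2 + nchar(e2) + intron_len
  exons <- data.frame(role = c("C_IG", "M1", "M2"),
                      start = c(1L, s2, s3),
                      end = c(nchar(e1), s2 + nchar(e2) - 1L,
                              s3 + nchar(e3) - 1L))
  list(seq = seqs, exons = exons, rss = NULL, defects = character(0))
}

# --- the generator -----------------------------------------------------

#' Build a synthetic locus with truth annotation
#'
#' Plants `n_v` V, `n_d` D, `n_j` J and `n_c` C segments (in that order, all
#' on the plus strand) separated by random intergenic sequence, injecting
#' one defect per designated pseudogene, and returns the genome together
#' with exact truth records.
#'
#' @param spec A [synthetic_locus_spec()].
#' @param contig_name Name of the generated contig.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{genome}{named [Biostrings::DNAStringSet] of length 1}
#'     \item{truth}{`data.frame` of truth records: `gene_id`,
#'       `segment_type`, `start`, `end`, `strand`, `planted_defects`
#'       (comma-joined, `""` for none), `expected_functionality`}
#'     \item{truth_annotation}{[locus_annotation()] with exon-level detail
#'       and planted RSS links}
#'     \item{references}{amino-acid reference sets for annotation: `v`
#'       (L2+V-region scaffold), `sp` (leader L1 peptide), `j`, and `c`
#'       (per-exon constant-domain peptides) with `c_roles`}
#'     \item{expression}{per-gene expression-evidence table (`gene_id`,
#'       `v_expressed`, `sp_expressed`); genes planted with the
#'       `no_expression` defect are marked unexpressed}
#'     \item{spec}{the input spec}
#'   }
#' @export
build_locus <- function(spec, contig_name = "synthetic_locus") {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  gc <- spec$gc_background

  plan <- data.frame(
    segment_type = rep(c("V", "D", "J", "C"),
                       c(spec$n_v, spec$n_d, spec$n_j, spec$n_c)),
    stringsAsFactors = FALSE)
  n_total <- nrow(plan)
  plan$defects <- character(n_total)
  # defect assignment, per type
  for (tp in c("V", "D", "J")) {
    idx <- which(plan$segment_type == tp)
    k <- as.integer(round(spec$pseudogene_fraction * length(idx)))
    if (k == 0L) next
    applicable <- .DEFECTS_BY_TYPE[[tp]]
    w <- spec$defect_mix[applicable]
    w[is.na(w)] <- 0
    if (sum(w) == 0) next
    pick <- if (length(idx) == 1L) idx else sample(idx, k)
    kinds <- sample(applicable, k, replace = TRUE, prob = w)
    plan$defects[pick] <- kinds
  }
  counters <- c(V = 0L, D = 0L, J = 0L, C = 0L)
  plan$gene_id <- vapply(plan$segment_type, function(tp) {
    counters[tp] <<- counters[tp] + 1L
    sprintf("SYN%s_%03d", tp, counters[tp])
  }, character(1))

  # lengths drawn up-front so the size cap can be enforced
  intron_lens <- .sample_len(spec$v_intron_length_dist, spec$n_v, min_len = 60L)
  gap_lens <- .sample_len(spec$intergenic_length_dist, n_total + 1L,
                          min_len = 50L)

  cassettes <- vector("list", n_total)
  vi <- 0L
  for (i in seq_len(n_total)) {
    defects <- if (nzchar(plan$defects[i]))
      strsplit(plan$defects[i], ",")[[1]] else character(0)
    cassettes[[i]] <- switch(plan$segment_type[i],
      V = { vi <- vi + 1L; .v_cassette(defects, intron_lens[vi], gc) },
      D = .d_cassette(defects, gc),
      J = .j_cassette(defects, gc),
      C = .c_cassette(gc))
  }
  total_len <- sum(vapply(cassettes, function(x) nchar(x$seq), numeric(1))) +
    sum(gap_lens)
  if (total_len > spec$genome_cap)
    stop("planned genome length (", total_len, " bp) exceeds genome_cap (",
         spec$genome_cap, " bp)")

  pieces <- character(2L * n_total + 1L)
  offset <- 0L
  segments <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    gap <- .random_dna(gap_lens[i], gc)
    pieces[2L * i - 1L] <- gap
    offset <- offset + gap_lens[i]
    cs <- cassettes[[i]]
    exons <- cs$exons
    exons$start <- exons$start + offset
    exons$end <- exons$end + offset
    rss <- cs$rss
    if (!is.null(rss)) {
      for (col in c("start", "end", "hept_start", "hept_end",
                    "non_start", "non_end"))
        rss[[col]] <- rss[[col]] + offset
      rss <- cbind(contig = contig_name, rss, stringsAsFactors = FALSE)
    }
    segments[[i]] <- gene_segment(
      gene_id = plan$gene_id[i], segment_type = plan$segment_type[i],
      contig = contig_name, strand = "+", exons = exons, rss_links = rss,
      locus_label = "SYN",
      functionality = if (nzchar(plan$defects[i])) "P" else "F",
      reasons = character(0), source = "truth",
      evidence = list(planted_defects = if (nzchar(plan$defects[i]))
        strsplit(plan$defects[i], ",")[[1]] else character(0)))
    pieces[2L * i] <- cs$seq
    offset <- offset + nchar(cs$seq)
  }
  pieces[2L * n_total + 1L] <- .random_dna(gap_lens[n_total + 1L], gc)

  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- contig_name

  truth <- if (n_total) data.frame(
    gene_id = plan$gene_id,
    segment_type = plan$segment_type,
    start = vapply(segments, segment_start, numeric(1)),
    end = vapply(segments, segment_end, numeric(1)),
    strand = "+",
    planted_defects = plan$defects,
    expected_functionality = ifelse(nzchar(plan$defects), "P", "F"),
    stringsAsFactors = FALSE)
  else data.frame(gene_id = character(0), segment_type = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  planted_defects = character(0),
                  expected_functionality = character(0),
                  stringsAsFactors = FALSE)

  references <- list(
    v = Biostrings::AAStringSet(c(Vref = paste0(substr(.SP_AA, 16, 19), .V_AA))),
    sp = Biostrings::AAStringSet(c(SPref = substr(.SP_AA, 1, 15))),
    j = Biostrings::AAStringSet(c(Jref = .J_AA)),
    c = Biostrings::AAStringSet(c(CIGref = .CIG_AA, M1ref = .M1_AA,
                                  M2ref = .M2_AA)),
    c_roles = c(CIGref = "C_IG", M1ref = "M1", M2ref = "M2"))

  expression <- data.frame(
    gene_id = truth$gene_id,
    v_expressed = as.integer(!grepl("no_expression", truth$planted_defects)),
    sp_expressed = as.integer(!grepl("no_expression", truth$planted_defects)),
    stringsAsFactors = FALSE)

  list(genome = genome, truth = truth,
       truth_annotation = locus_annotation(segments, genome_name = contig_name,
                                           metadata = list(source = "build_locus")),
       references = references, expression = expression, spec = spec)
}

#' Locus annotations encoding published axolotl TR gene inventories
#'
#' Returns a fixture annotation whose per-type functional/pseudogene counts
#' equal the reported axolotl inventories: TRA (61 V of which 46 functional,
#' 36 J of which 33 functional, 1 C), TRD (2 V with 1 functional, 2 J, 1 C,
#' no D), and TRB (23 V with 18 functional, 5 D, 17 J, 6 C).  Coordinates
#' are evenly spaced placeholders; only counts and functionality flags are
#' meaningful.
#'
#' @param locus_label One of `"TRA"`, `"TRD"`, `"TRB"`.
#' @return A [locus_annotation()].
#' @export
table_fixture <- function(locus_label = c("TRA", "TRD", "TRB")) {
  locus_label <- match.arg(locus_label)
  counts <- switch(locus_label,
    TRA = list(V = c(F = 46L, P = 15L), J = c(F = 33L, P = 3L),
               C = c(F = 1L, P = 0L)),
    TRD = list(V = c(F = 1L, P = 1L), J = c(F = 2L, P = 0L),
               C = c(F = 1L, P = 0L), D = c(F = 0L, P = 0L)),
    TRB = list(V = c(F = 18L, P = 5L), D = c(F = 5L, P = 0L),
               J = c(F = 17L, P = 0L), C = c(F = 6L, P = 0L)))
  contig <- paste0(locus_label, "_fixture")
  segments <- list()
  pos <- 1L
  for (tp in names(counts)) {
    n_f <- counts[[tp]][["F"]]; n_p <- counts[[tp]][["P"]]
    n <- n_f + n_p
    if (n == 0L) next
    for (i in seq_len(n)) {
      fun <- if (i <= n_f) "F" else "P"
      segments[[length(segments) + 1L]] <- gene_segment(
        gene_id = sprintf("%s%s_%03d", locus_label, tp, i),
        segment_type = tp, contig = contig, strand = "+",
        exons = data.frame(role = switch(tp, V = "V_EXON", J = "J_EXON",
                                         D = "D_CORE", C = "C_IG"),
                           start = pos, end = pos + 299L),
        locus_label = locus_label, functionality = fun,
        reasons = if (fun == "P") "fixture_pseudogene" else character(0),
        source = "fixture")
      pos <- pos + 1000L
    }
  }
  locus_annotation(segments, genome_name = contig,
                   metadata = list(source = "table_fixture",
                                   locus_label = locus_label))
}
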