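# Homology seeding, gene-model assembly and redundancy reduction.

make_locus <- function(...) build_locus(synthetic_locus_spec(...))

test_that("an exactly planted reference is seeded at full identity", {
  bl <- make_locus(n_v = 1L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 17L)
  seeds <- seed_hits(bl$genome, bl$references$v)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$percent_identity, 100)
  ve <- bl$truth_annotation$segments[[1]]$exons
  ve <- ve[ve$role == "V_EXON", ]
  expect_equal(seeds$start, ve$start)
  expect_equal(seeds$end, ve$end)
  expect_equal(seeds$strand, "+")
})

test_that("a ~70% identity homolog is detected; score matches the DP oracle", {
  set.seed(99)
  ref <- as.character(Biostrings::AAString(
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 90,
                 replace = TRUE), collapse = "")))
  mut <- strsplit(ref, "")[[1]]
  # ~30% substitutions; keep both termini intact so the optimal local
  # alignment spans the whole planted window
  flip <- sample(3:88, 27)
  alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in flip) mut[i] <- sample(setdiff(alphabet, mut[i]), 1)
  mut <- paste(mut, collapse = "")
  # back-translate the mutant and plant it
  codons <- vapply(strsplit(mut, "")[[1]], function(a) {
    cand <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    sample(cand, 1)
  }, character(1))
  insert <- paste(codons, collapse = "")
  bg <- as.character(random_genome(4000, 123)[[1]])
  dna <- paste0(substr(bg, 1, 2000), insert, substr(bg, 2001, 4000))
  seeds <- seed_hits(dna, c(ref1 = ref))
  expect_equal(nrow(seeds), 1L)
  expect_gte(seeds$score, seeding_config()$min_alignment_score)
  expect_lt(seeds$percent_identity, 100)
  # coordinates recover the planted window
  expect_equal(seeds$start, 2001L)
  expect_equal(seeds$end, 2000L + nchar(insert))
  # score equals an independent Smith-Waterman on the planted window
  submat <- local({
    e <- new.env()
    utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  expect_equal(seeds$score, oracle_smith_waterman(ref, mut, submat))
})

test_that("a random genome without planted homologs yields no seeds", {
  bl <- make_locus(n_v = 1L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 17L)
  seeds <- seed_hits(random_genome(20000, 31), bl$references$v)
  expect_equal(nrow(seeds), 0L)
})

test_that("minus-strand homologs are found with mirrored coordinates", {
  bl <- make_locus(n_v = 1L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 17L)
  fwd <- seed_hits(bl$genome, bl$references$v)
  L <- Biostrings::width(bl$genome)
  rc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(bl$genome[[1]]))
  names(rc) <- names(bl$genome)
  rev <- seed_hits(rc, bl$references$v)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$strand, "-")
  expect_equal(rev$start, L - fwd$end + 1L)
  expect_equal(rev$end, L - fwd$start + 1L)
  expect_equal(rev$score, fwd$score)
})

test_that("assembled V models recover planted truth exactly", {
  bl <- make_locus(n_v = 20L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 23L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  cfg <- seeding_config()
  v_seeds <- seed_hits(bl$genome, bl$references$v, cfg)
  sp_seeds <- seed_hits(bl$genome, bl$references$sp, cfg,
                        min_score = cfg$sp_min_score)
  expect_equal(nrow(v_seeds), 20L)
  segs <- lapply(seq_len(nrow(v_seeds)), function(i)
    assemble_v_gene(v_seeds[i, ], hits, bl$genome, cfg, sp_seeds))
  got <- data.frame(start = vapply(segs, segment_start, numeric(1)),
                    end = vapply(segs, segment_end, numeric(1)))
  got <- got[order(got$start), ]
  expect_equal(got$start, bl$truth$start)
  expect_equal(got$end, bl$truth$end)
  expect_true(all(vapply(segs, function(s)
    !is.null(s$rss_links) && nrow(s$rss_links) == 1L, logical(1))))
  expect_true(all(vapply(segs, function(s)
    length(s$reasons) == 0L, logical(1))))
})

test_that("a V whose downstream RSS is missing is flagged rss_absent", {
  bl <- make_locus(n_v = 1L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 29L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  v_seeds <- seed_hits(bl$genome, bl$references$v)
  no_rss <- hits[hits$spacer_class != 23L, , drop = FALSE]
  seg <- assemble_v_gene(v_seeds[1, ], no_rss, bl$genome, seeding_config())
  expect_true("rss_absent" %in% seg$reasons)
})

test_that("a V seed on the contig edge without leader room is flagged", {
  # strip everything upstream of the V-exon so no leader can exist
  bl <- make_locus(n_v = 1L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 29L)
  ve <- bl$truth_annotation$segments[[1]]$exons
  ve <- ve[ve$role == "V_EXON", ]
  g2 <- Biostrings::DNAStringSet(Biostrings::subseq(bl$genome[[1]], ve$start))
  names(g2) <- names(bl$genome)
  hits <- scan_rss(g2, rss_params(require_cac = FALSE))
  seeds <- seed_hits(g2, bl$references$v)
  seg <- assemble_v_gene(seeds[1, ], hits, g2, seeding_config())
  expect_true("missing_leader" %in% seg$reasons)
})

test_that("J detection requires an upstream 12-RSS and motif or homology", {
  bl <- make_locus(n_v = 0L, n_d = 0L, n_j = 5L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 37L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  segs <- detect_j_genes(bl$genome, hits)
  expect_equal(length(segs), 5L)
  got <- sort(vapply(segs, segment_start, numeric(1)))
  expect_equal(got, bl$truth$start)
  expect_true(all(vapply(segs, function(s)
    s$evidence$motif_evidence == "canonical", logical(1))))
  # 23-class hits alone produce no J models
  only23 <- hits[hits$spacer_class == 23L, , drop = FALSE]
  expect_equal(length(detect_j_genes(bl$genome, only23)), 0L)
})

test_that("an FKKG-motif J is emitted via homology with non-canonical evidence", {
  bl <- make_locus(n_v = 0L, n_d = 0L, n_j = 4L, n_c = 0L,
                   pseudogene_fraction = 0.25,
                   defect_mix = c(missing_j_motif = 1), seed = 41L)
  expect_equal(sum(bl$truth$planted_defects == "missing_j_motif"), 1L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  cfg <- seeding_config()
  j_seeds <- seed_hits(bl$genome, bl$references$j, cfg,
                       min_score = cfg$j_min_score)
  segs <- detect_j_genes(bl$genome, hits, j_seeds)
  expect_equal(length(segs), 4L)
  ev <- vapply(segs, function(s) s$evidence$motif_evidence, character(1))
  expect_equal(sum(ev == "non_canonical"), 1L)
  # without homology support the FKKG gene is not emitted
  segs_nohom <- detect_j_genes(bl$genome, hits)
  expect_equal(length(segs_nohom), 3L)
})

test_that("D candidates require correctly ordered 12/23 flanks", {
  bl <- make_locus(n_v = 0L, n_d = 5L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 43L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  segs <- detect_d_candidates(bl$genome, hits)
  expect_equal(length(segs), 5L)
  got <- sort(vapply(segs, segment_start, numeric(1)))
  expect_equal(got, bl$truth$start)
  expect_true(all(vapply(segs, function(s) nrow(s$rss_links) == 2L,
                         logical(1))))
  # a TRD-style region (V- and J-RSSs, no paired D flanks) yields nothing
  trd <- make_locus(n_v = 2L, n_d = 0L, n_j = 2L, n_c = 0L,
                    pseudogene_fraction = 0, seed = 47L)
  trd_hits <- scan_rss(trd$genome, rss_params(require_cac = FALSE))
  expect_equal(length(detect_d_candidates(trd$genome, trd_hits)), 0L)
})

test_that("D flanks beyond max_d_len do not pair", {
  dna <- paste0(strrep("A", 30),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(rss_string(12)))),
                strrep("A", 60),   # too far apart
                rss_string(23), strrep("A", 30))
  hits <- scan_rss(dna, rss_params())
  expect_equal(length(detect_d_candidates(dna, hits, max_d_len = 40L)), 0L)
  expect_equal(length(detect_d_candidates(dna, hits, max_d_len = 80L)), 1L)
})

test_that("D detection ignores RSSs violating class or orientation", {
  bl <- make_locus(n_v = 0L, n_d = 3L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 53L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  base <- detect_d_candidates(bl$genome, hits)
  # inject decoys: wrong class/strand combinations near nothing useful
  decoy <- hits[1:2, ]
  decoy$start <- decoy$start + 5000L; decoy$end <- decoy$end + 5000L
  decoy$hept_start <- decoy$hept_start + 5000L
  decoy$hept_end <- decoy$hept_end + 5000L
  decoy$strand <- c("+", "-")
  decoy$spacer_class <- c(12L, 23L)   # downstream-12 / upstream-23: invalid
  more <- detect_d_candidates(bl$genome, rbind(hits, decoy))
  expect_equal(length(more), length(base))
})

test_that("reduce_and_confirm merges duplicates, is idempotent, flags SP", {
  bl <- make_locus(n_v = 3L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 59L)
  hits <- scan_rss(bl$genome, rss_params(require_cac = FALSE))
  cfg <- seeding_config()
  v_seeds <- seed_hits(bl$genome, bl$references$v, cfg)
  sp_seeds <- seed_hits(bl$genome, bl$references$sp, cfg,
                        min_score = cfg$sp_min_score)
  segs <- lapply(seq_len(nrow(v_seeds)), function(i)
    assemble_v_gene(v_seeds[i, ], hits, bl$genome, cfg, sp_seeds))
  dup <- c(segs, segs)   # two identical models per gene
  red <- reduce_and_confirm(dup, sp_seeds)
  expect_equal(length(red), 3L)
  red2 <- reduce_and_confirm(red, sp_seeds)
  expect_equal(vapply(red2, function(s) s$gene_id, character(1)),
               vapply(red, function(s) s$gene_id, character(1)))
  expect_true(all(vapply(red, function(s) isTRUE(s$evidence$sp_confirmed),
                         logical(1))))
  # non-overlapping models pass through unchanged
  expect_equal(length(reduce_and_confirm(segs)), 3L)
  # V without SP evidence is retained but flagged unconfirmed
  red_nosp <- reduce_and_confirm(segs, sp_seeds[0, ])
  expect_equal(length(red_nosp), 3L)
  expect_true(all(!vapply(red_nosp, function(s)
    isTRUE(s$evidence$sp_confirmed), logical(1))))
})

test_that("locus presence distinguishes planted from absent families", {
  bl <- make_locus(n_v = 2L, n_d = 0L, n_j = 0L, n_c = 0L,
                   pseudogene_fraction = 0, seed = 61L)
  present <- locus_presence(bl$genome, bl$references$v)
  expect_true(present$present)
  # an unrelated reference family is absent, markers still located
  set.seed(62)
  absent_ref <- Biostrings::AAStringSet(c(TRGref = paste(
    sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 120, replace = TRUE),
    collapse = "")))
  rep <- locus_presence(bl$genome, absent_ref,
                        markers = bl$references$v)
  expect_false(rep$present)
  expect_true(all(rep$markers$present))
  expect_error(locus_presence(bl$genome, Biostrings::AAStringSet()), "empty")
})

test_that("external seed tables import with cutoff filtering", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tstart\tend\tstrand\treference_id\tidentity\tscore\tevalue",
               "chr1\t100\t400\t+\trefA\t95.0\t250\t1e-30",
               "chr1\t900\t950\t+\trefB\t40.0\t50\t0.5"), path)
  seeds <- read_seed_table(path)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$reference_id, "refA")
})
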