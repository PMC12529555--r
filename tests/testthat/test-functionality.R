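# Functional / pseudogene classification rules and policies.

strict_cfg <- function(...) classifier_config(...)
structural_cfg <- function(...)
  classifier_config(expression_policy = "structural_only", ...)

test_that("a canonical planted V with expression evidence is functional", {
  bl <- build_locus(synthetic_locus_spec(n_v = 2L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 0,
                                         seed = 71L))
  for (s in bl$truth_annotation$segments) {
    call <- classify_segment(s, bl$genome, bl$expression, strict_cfg())
    expect_equal(call$verdict, "F")
    expect_length(call$reasons, 0L)
  }
})

test_that("a structurally intact V without expression is a pseudogene under the expression policy", {
  bl <- build_locus(synthetic_locus_spec(n_v = 1L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 0,
                                         seed = 73L))
  seg <- bl$truth_annotation$segments[[1]]
  silent <- data.frame(gene_id = seg$gene_id, v_expressed = 0L,
                       sp_expressed = 0L)
  call <- classify_segment(seg, bl$genome, silent, strict_cfg())
  expect_equal(call$verdict, "P")
  expect_equal(call$reasons, "expression_absent")
  # structurally it remains intact
  call2 <- classify_segment(seg, bl$genome, silent, structural_cfg())
  expect_equal(call2$verdict, "F")
  # V expressed but signal peptide not: still P under the strictest policy,
  # F when only gene expression is required
  sp_silent <- data.frame(gene_id = seg$gene_id, v_expressed = 1L,
                          sp_expressed = 0L)
  expect_equal(classify_segment(seg, bl$genome, sp_silent,
                                strict_cfg())$verdict, "P")
  expect_equal(classify_segment(
    seg, bl$genome, sp_silent,
    classifier_config(expression_policy = "require_gene_expression"))$verdict,
    "F")
})

test_that("a J whose upstream RSS heptamer lacks CAC is a pseudogene", {
  bl <- build_locus(synthetic_locus_spec(n_v = 0L, n_d = 0L, n_j = 1L,
                                         n_c = 0L, pseudogene_fraction = 1,
                                         defect_mix = c(rss_cac_defect = 1),
                                         seed = 79L))
  seg <- bl$truth_annotation$segments[[1]]
  call <- classify_segment(seg, bl$genome, NULL, strict_cfg())
  expect_equal(call$verdict, "P")
  expect_true("rss_heptamer_cac" %in% call$reasons)
})

test_that("a single-base deletion in the V-exon reads as a frameshift", {
  bl <- build_locus(synthetic_locus_spec(n_v = 1L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 1,
                                         defect_mix = c(frameshift = 1),
                                         seed = 83L))
  seg <- bl$truth_annotation$segments[[1]]
  call <- classify_segment(seg, bl$genome, bl$expression, strict_cfg())
  expect_equal(call$verdict, "P")
  expect_true("frameshift" %in% call$reasons)
})

test_that("a premature stop codon reads as orf_stop and nothing else", {
  bl <- build_locus(synthetic_locus_spec(n_v = 1L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 1,
                                         defect_mix = c(premature_stop = 1),
                                         seed = 89L))
  seg <- bl$truth_annotation$segments[[1]]
  call <- classify_segment(seg, bl$genome, bl$expression, strict_cfg())
  expect_equal(call$verdict, "P")
  expect_equal(call$reasons, "orf_stop")
})

test_that("the J motif switch distinguishes strict from lenient policy", {
  bl <- build_locus(synthetic_locus_spec(n_v = 0L, n_d = 0L, n_j = 1L,
                                         n_c = 0L, pseudogene_fraction = 1,
                                         defect_mix = c(missing_j_motif = 1),
                                         seed = 97L))
  seg <- bl$truth_annotation$segments[[1]]
  strict <- classify_segment(seg, bl$genome, NULL, strict_cfg())
  expect_equal(strict$verdict, "P")
  expect_true("j_motif_absent" %in% strict$reasons)
  lenient <- classify_segment(seg, bl$genome, NULL,
                              classifier_config(j_motif_strict = FALSE))
  expect_equal(lenient$verdict, "F")
  expect_true("j_motif_absent" %in% lenient$warnings)
})

test_that("D segments demand a valid 12/23 flank pair", {
  bl <- build_locus(synthetic_locus_spec(n_v = 0L, n_d = 1L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 0,
                                         seed = 101L))
  seg <- bl$truth_annotation$segments[[1]]
  expect_equal(classify_segment(seg, bl$genome)$verdict, "F")
  broken <- seg
  broken$rss_links <- seg$rss_links[1, ]
  call <- classify_segment(broken, bl$genome)
  expect_equal(call$verdict, "P")
  expect_true("rss_missing_3p" %in% call$reasons)
  same_class <- seg
  same_class$rss_links$spacer_class <- c(12L, 12L)
  expect_true("rss_pair_violation" %in%
                classify_segment(same_class, bl$genome)$reasons)
})

test_that("C segments require all three canonical exon roles", {
  bl <- build_locus(synthetic_locus_spec(n_v = 0L, n_d = 0L, n_j = 0L,
                                         n_c = 1L, pseudogene_fraction = 0,
                                         seed = 103L))
  seg <- bl$truth_annotation$segments[[1]]
  expect_equal(classify_segment(seg, bl$genome)$verdict, "F")
  maimed <- seg
  maimed$exons <- seg$exons[seg$exons$role != "M2", ]
  call <- classify_segment(maimed, bl$genome)
  expect_equal(call$verdict, "P")
  expect_true("c_exon_missing_M2" %in% call$reasons)
})

test_that("expression-policy strictness orders the functional sets", {
  bl <- build_locus(synthetic_locus_spec(n_v = 12L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 0.5,
                                         seed = 107L))
  # make expression evidence patchy: half the expressed genes lack SP evidence
  expr <- bl$expression
  some <- which(expr$sp_expressed == 1L)
  expr$sp_expressed[some[seq_len(floor(length(some) / 2))]] <- 0L
  verdicts <- function(policy) {
    cfg <- classifier_config(expression_policy = policy)
    vapply(bl$truth_annotation$segments, function(s)
      classify_segment(s, bl$genome, expr, cfg)$verdict, character(1))
  }
  f_strict <- which(verdicts("require_gene_and_sp_expression") == "F")
  f_gene <- which(verdicts("require_gene_expression") == "F")
  f_struct <- which(verdicts("structural_only") == "F")
  expect_true(all(f_strict %in% f_gene))
  expect_true(all(f_gene %in% f_struct))
})

test_that("verdicts equal planted truth on a mixed synthetic locus", {
  bl <- build_locus(synthetic_locus_spec(n_v = 15L, n_d = 3L, n_j = 10L,
                                         n_c = 1L, pseudogene_fraction = 0.4,
                                         seed = 109L))
  ann <- classify_annotation(bl$truth_annotation, bl$genome, bl$expression,
                             strict_cfg())
  got <- vapply(ann$segments, function(s) s$functionality, character(1))
  ids <- vapply(ann$segments, function(s) s$gene_id, character(1))
  want <- bl$truth$expected_functionality[match(ids, bl$truth$gene_id)]
  expect_equal(got, want)
})

test_that("adding a defect never turns a pseudogene functional", {
  bl <- build_locus(synthetic_locus_spec(n_v = 1L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 1,
                                         defect_mix = c(frameshift = 1),
                                         seed = 113L))
  seg <- bl$truth_annotation$segments[[1]]
  base <- classify_segment(seg, bl$genome, bl$expression, strict_cfg())
  expect_equal(base$verdict, "P")
  # additionally break the RSS link
  worse <- seg
  worse$rss_links <- NULL
  call <- classify_segment(worse, bl$genome, bl$expression, strict_cfg())
  expect_equal(call$verdict, "P")
  expect_true(all(base$reasons %in% call$reasons))
})

test_that("segments outside the genome raise an error", {
  bl <- build_locus(synthetic_locus_spec(n_v = 1L, n_d = 0L, n_j = 0L,
                                         n_c = 0L, pseudogene_fraction = 0,
                                         seed = 127L))
  seg <- bl$truth_annotation$segments[[1]]
  seg$exons$end <- seg$exons$end + Biostrings::width(bl$genome)
  expect_error(classify_segment(seg, bl$genome), "outside")
})

test_that("N-glycosylation sequons are reported with printed-style context", {
  # a constant-domain-like sequence with NDTE at 42-45
  base <- strrep("A", 100)
  prot <- paste0(substr(base, 1, 41), "NDTE", substr(base, 46, 100))
  sites <- find_nglyc_sites(prot)
  expect_equal(sites$position, 42L)
  expect_equal(sites$context, "NDTE")
  # proline in X position is excluded
  expect_equal(nrow(find_nglyc_sites("NPST")), 0L)
  # TRBC-like NRTK at 51-54
  prot2 <- paste0(strrep("G", 50), "NRTK", strrep("G", 46))
  sites2 <- find_nglyc_sites(prot2)
  expect_equal(sites2$position, 51L)
  expect_equal(sites2$context, "NRTK")
  # overlapping sequons are all reported
  expect_equal(find_nglyc_sites("NNSS")$position, c(1L, 2L))
  expect_error(find_nglyc_sites("NDT3"), "non-amino-acid")
})
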