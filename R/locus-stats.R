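# Locus-level statistics: inventories, functional/pseudogene percentages
# and ratios, locus spans, V-intron lengths, and the Wilcoxon rank-sum and
# Fisher exact analyses used to relate intron length to functionality.

#' Statistics configuration
#'
#' @param long_intron_threshold Introns strictly longer than this (bp) count
#'   as "long" in the contingency analysis.
#' @param percent_decimals Decimals for reported percentages.
#' @param ratio_rounding `"truncate_2dp"` (default) or `"round_2dp"` for the
#'   F/P ratio.  Truncation matches the convention of reported ratios such
#'   as 3.06 for 46/15 (= 3.066...).
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(long_intron_threshold = 650L,
                         percent_decimals = 2L,
                         ratio_rounding = c("truncate_2dp", "round_2dp")) {
  ratio_rounding <- match.arg(ratio_rounding)
  stopifnot(long_intron_threshold > 0)
  structure(list(long_intron_threshold = long_intron_threshold,
                 percent_decimals = as.integer(percent_decimals),
                 ratio_rounding = ratio_rounding),
            class = "stats_config")
}

.fp_ratio <- function(n_f, n_p, mode) {
  if (n_p == 0L) return(NA_real_)
  r <- n_f / n_p
  if (mode == "truncate_2dp") floor(r * 100) / 100 else round(r, 2L)
}

#' Summarise a locus annotation by segment type
#'
#' Counts functional and pseudogene segments per locus label and type and
#' reports percentages and the F/P ratio.  Errors if any segment is still
#' unclassified.
#'
#' @param ann A [locus_annotation()] with verdicts filled in.
#' @param cfg A [stats_config()].
#' @return `data.frame` (class `summary_table`) with columns `locus_label`,
#'   `segment_type`, `n_functional`, `n_pseudogene`, `n_total`,
#'   `pct_functional`, `pct_pseudogene`, `fp_ratio` (NA when no
#'   pseudogenes).
#' @export
summarize_locus <- function(ann, cfg = stats_config()) {
  df <- as.data.frame(ann)
  if (!nrow(df)) stop("annotation is empty")
  if (any(df$functionality == "unclassified"))
    stop(sum(df$functionality == "unclassified"),
         " segment(s) are unclassified; run classify_annotation() first")
  out <- do.call(rbind, lapply(
    split(df, list(df$locus_label, df$segment_type), drop = TRUE),
    function(g) {
      n_f <- sum(g$functionality == "F")
      n_p <- sum(g$functionality == "P")
      n <- n_f + n_p
      data.frame(locus_label = g$locus_label[1L],
                 segment_type = g$segment_type[1L],
                 n_functional = n_f, n_pseudogene = n_p, n_total = n,
                 pct_functional = round(100 * n_f / n, cfg$percent_decimals),
                 pct_pseudogene = round(100 * n_p / n, cfg$percent_decimals),
                 fp_ratio = .fp_ratio(n_f, n_p, cfg$ratio_rounding),
                 stringsAsFactors = FALSE)
    }))
  type_order <- c(V = 1L, D = 2L, J = 3L, C = 4L)
  out <- out[order(out$locus_label, type_order[out$segment_type]), ]
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Span of a locus from its boundary coordinates
#'
#' @param start,end Coordinates in any consistent unit (bp, Mbp, ...).
#' @return `end - start`, in the same unit.
#' @export
locus_span <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  end - start
}

#' V-intron lengths of an annotation
#'
#' The V-intron separates the leader (L1) exon from the V-exon; its length
#' in 1-based inclusive coordinates is `start(V-exon) - end(L1) - 1`.
#' Single-exon V segments (no leader) have no measurable intron and are
#' excluded with a warning.
#'
#' @param ann A [locus_annotation()].
#' @return A list: `per_gene` (`data.frame` with `gene_id`, `intron_bp`,
#'   `functionality`), `mean_bp`, `n_excluded`.
#' @export
intron_lengths <- function(ann) {
  vs <- segments_of_type(ann, "V")
  rows <- list(); excluded <- 0L
  for (s in vs) {
    ex <- s$exons
    if (!all(c("L1", "V_EXON") %in% ex$role)) { excluded <- excluded + 1L; next }
    l1 <- ex[ex$role == "L1", ]; ve <- ex[ex$role == "V_EXON", ]
    len <- if (s$strand == "+") ve$start - l1$end - 1L else l1$start - ve$end - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = s$gene_id, intron_bp = as.integer(len),
      functionality = s$functionality, stringsAsFactors = FALSE)
  }
  if (excluded > 0L)
    warning(excluded, " V segment(s) without a leader exon excluded from ",
            "intron statistics")
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), intron_bp = integer(0),
               functionality = character(0), stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       mean_bp = if (nrow(per_gene)) mean(per_gene$intron_bp) else NA_real_,
       n_excluded = excluded)
}

#' Two-sided Wilcoxon rank-sum test for intron-length comparison
#'
#' Uses the exact null distribution for small samples (combined n <= 30
#' without ties) and the normal approximation with tie and continuity
#' correction otherwise; the method used is recorded in the result.
#'
#' @param a,b Numeric vectors (e.g. intron lengths of functional and
#'   pseudogene V genes).  Both must be nonempty.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) method;
#'   `NULL` (default) selects by the rule above.
#' @return List: `p_value`, `statistic` (W), `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (length(a) + length(b) <= 30L) && !ties
  res <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                             exact = exact, correct = TRUE))
  p <- res$p.value
  if (is.nan(p)) p <- 1   # degenerate: zero rank variance (all values tied)
  list(p_value = p, statistic = unname(res$statistic),
       method = if (exact && !ties) "exact" else "normal_approximation")
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Two-sided p by the probability-mass rule (sum over tables with fixed
#' margins whose hypergeometric probability does not exceed the observed
#' one), odds ratio by conditional maximum likelihood, and the exact
#' conditional 95% confidence interval - the convention under which a table
#' with an empty cell yields an odds ratio of 0 with a finite upper CI.
#'
#' @param tab 2x2 matrix of non-negative counts.  For the long-intron
#'   analysis the convention is rows = (pseudogene, functional), columns =
#'   (long, short), so depletion of long introns among pseudogenes gives an
#'   odds ratio below 1.
#' @return List: `p_value`, `odds_ratio`, `conf_int` (length-2 vector).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative counts")
  res <- stats::fisher.test(tab, conf.level = 0.95)
  list(p_value = res$p.value, odds_ratio = unname(res$estimate),
       conf_int = as.numeric(res$conf.int))
}

#' Cross-classify V genes by functionality and intron length
#'
#' Builds the 2x2 table rows = (pseudogene, functional) x columns = (long,
#' short) using the configured threshold (default: long means > 650 bp).
#' V genes without a measurable intron are excluded.
#'
#' @param ann A [locus_annotation()].
#' @param cfg A [stats_config()].
#' @return 2x2 integer matrix (class preserved for [fisher_exact()]).
#' @export
long_intron_table <- function(ann, cfg = stats_config()) {
  il <- suppressWarnings(intron_lengths(ann))
  pg <- il$per_gene
  long <- pg$intron_bp > cfg$long_intron_threshold
  pseudo <- pg$functionality == "P"
  matrix(c(sum(pseudo & long), sum(pseudo & !long),
           sum(!pseudo & long), sum(!pseudo & !long)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("pseudogene", "functional"), c("long", "short")))
}

#' Enumerate the long-intron contingency family for fixed gene counts
#'
#' For a locus with `n_functional` functional and `n_pseudo_total`
#' pseudogene V genes, none of the pseudogenes having a long intron,
#' enumerates every admissible table: `n_pseudo_with_intron` pseudogenes
#' retain a measurable intron (genes without a leader exon have none and
#' drop out of the test) and `k_long_functional` functional genes carry a
#' long intron.  Each table's two-sided Fisher p, conditional odds ratio
#' and exact 95% CI are returned, so a printed test result can be located
#' within the family.
#'
#' @param n_functional Number of functional V genes (all with introns).
#' @param n_pseudo_total Total pseudogene count.
#' @return `data.frame` with one row per (n_pseudo_with_intron,
#'   k_long_functional) pair.
#' @export
long_intron_fisher_family <- function(n_functional = 46L,
                                      n_pseudo_total = 15L) {
  rows <- list()
  for (np in 0:n_pseudo_total) {
    for (k in 0:n_functional) {
      ft <- fisher_exact(matrix(c(0L, np, k, n_functional - k), 2L, 2L,
                                byrow = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        n_pseudo_with_intron = np, k_long_functional = k,
        p_value = ft$p_value, odds_ratio = ft$odds_ratio,
        ci_lower = ft$conf_int[1L], ci_upper = ft$conf_int[2L])
    }
  }
  do.call(rbind, rows)
}
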