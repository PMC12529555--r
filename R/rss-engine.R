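# Recombination signal sequence (RSS) detection.
#
# An RSS is a conserved heptamer and nonamer separated by a spacer of about
# 12 or 23 bp; V(D)J recombination joins one 12-spacer RSS to one 23-spacer
# RSS (the 12/23 rule).  The scanner below slides both consensus motifs over
# both strands, tolerating configurable mismatch budgets and a +/- 1 bp
# spacer wobble, and records for every hit whether the heptamer starts with
# the 5'-CAC-3' triplet that RAG recognition requires.

#' RSS scan parameters
#'
#' Defaults encode the canonical vertebrate consensus (heptamer `CACAGTG`,
#' nonamer `ACAAAAACC`), a strict heptamer budget (at most 1 mismatch) with
#' the CAC triplet required exact, a permissive nonamer budget (at most 3
#' mismatches), and spacers of 12 or 23 bp with 1 bp tolerance.  Strict
#' heptamer / permissive nonamer mirrors the asymmetry of RAG binding.
#'
#' @param heptamer_consensus 7-mer DNA string.
#' @param nonamer_consensus 9-mer DNA string.
#' @param spacer_classes Integer vector of nominal spacer lengths.
#' @param spacer_tolerance Allowed deviation (bp) from a nominal spacer.
#' @param max_heptamer_mismatches,max_nonamer_mismatches Mismatch budgets.
#' @param require_cac When `TRUE`, the first three heptamer bases must be
#'   exactly `CAC` for a hit to be reported.  Set to `FALSE` to also recover
#'   CAC-defective signals (their `cac_intact` flag is then `FALSE`), e.g.
#'   so a downstream classifier can distinguish "RSS absent" from "RSS
#'   present but CAC-defective".
#'
#' @return A list of class `rss_params`.
#' @export
rss_params <- function(heptamer_consensus = "CACAGTG",
                       nonamer_consensus = "ACAAAAACC",
                       spacer_classes = c(12L, 23L),
                       spacer_tolerance = 1L,
                       max_heptamer_mismatches = 1L,
                       max_nonamer_mismatches = 3L,
                       require_cac = TRUE) {
  stopifnot(nchar(heptamer_consensus) == 7L, nchar(nonamer_consensus) == 9L,
            grepl("^[ACGT]+$", heptamer_consensus),
            grepl("^[ACGT]+$", nonamer_consensus),
            spacer_tolerance >= 0L,
            max_heptamer_mismatches >= 0L, max_nonamer_mismatches >= 0L)
  structure(list(heptamer_consensus = heptamer_consensus,
                 nonamer_consensus = nonamer_consensus,
                 spacer_classes = as.integer(spacer_classes),
                 spacer_tolerance = as.integer(spacer_tolerance),
                 max_heptamer_mismatches = as.integer(max_heptamer_mismatches),
                 max_nonamer_mismatches = as.integer(max_nonamer_mismatches),
                 require_cac = isTRUE(require_cac)),
            class = "rss_params")
}

# Sliding mismatch counts of `pattern` against character vector `s`.
# Returns an integer vector of length length(s) - k + 1.
.mismatch_profile <- function(s, pattern) {
  k <- nchar(pattern)
  L <- length(s)
  if (L < k) return(integer(0))
  p <- strsplit(pattern, "")[[1]]
  n <- L - k + 1L
  mm <- integer(n)
  for (j in seq_len(k)) mm <- mm + (s[j:(n + j - 1L)] != p[j])
  mm
}

# Scan one strand of one contig.  `s` is the plus-strand character vector;
# for strand "-", pass the reverse complement and coordinates are mirrored.
.scan_one <- function(s, contig, strand, L, params) {
  hmm <- .mismatch_profile(s, params$heptamer_consensus)
  nmm <- .mismatch_profile(s, params$nonamer_consensus)
  cac <- if (length(s) >= 3L) {
    n3 <- length(s) - 2L
    s[1:n3] == "C" & s[2:(n3 + 1L)] == "A" & s[3:(n3 + 2L)] == "C"
  } else logical(0)
  spacers <- unlist(lapply(params$spacer_classes, function(cl)
    (cl - params$spacer_tolerance):(cl + params$spacer_tolerance)))
  classes <- rep(params$spacer_classes,
                 each = 2L * params$spacer_tolerance + 1L)
  out <- vector("list", length(spacers))
  for (k in seq_along(spacers)) {
    sp <- spacers[k]
    # heptamer at i..i+6, spacer, nonamer at i+7+sp .. i+15+sp
    off <- 7L + sp
    n_h <- length(hmm); n_n <- length(nmm)
    if (n_h < 1L || n_n < 1L) next
    imax <- min(n_h, n_n - off)
    if (imax < 1L) next
    i <- seq_len(imax)
    ok <- hmm[i] <= params$max_heptamer_mismatches &
      nmm[i + off] <= params$max_nonamer_mismatches
    if (params$require_cac) ok <- ok & cac[i]
    i <- i[ok]
    if (!length(i)) next
    out[[k]] <- data.frame(
      i = i, spacer_len = sp, spacer_class = classes[k],
      hept_mm = hmm[i], non_mm = nmm[i + off], cac = cac[i])
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits) || !nrow(hits)) return(NULL)
  # local coordinates -> plus-strand genomic coordinates
  span <- 16L + hits$spacer_len          # total motif length
  if (strand == "+") {
    start <- hits$i
    hept_start <- start; hept_end <- start + 6L
    non_start <- start + 7L + hits$spacer_len; non_end <- non_start + 8L
    end <- non_end
  } else {
    # local i on the reverse complement: mirror back
    end <- L - hits$i + 1L
    start <- end - span + 1L
    hept_end <- end; hept_start <- end - 6L
    non_end <- start + 8L; non_start <- start
  }
  data.frame(contig = contig, start = start, end = end, strand = strand,
             spacer_class = hits$spacer_class, spacer_len = hits$spacer_len,
             hept_start = hept_start, hept_end = hept_end,
             non_start = non_start, non_end = non_end,
             hept_mm = hits$hept_mm, non_mm = hits$non_mm,
             cac_intact = hits$cac, stringsAsFactors = FALSE)
}

#' Scan a genome for recombination signal sequences
#'
#' Slides the heptamer and nonamer consensus over both strands at every
#' tolerated spacer distance and reports each position where both motifs
#' fall within their mismatch budgets.  A hit's `strand` is the strand on
#' which the consensus reads heptamer -> spacer -> nonamer; on that strand
#' the gene the signal serves sits 5' of the heptamer when the RSS is the
#' downstream (V/D 3') signal, and 3' of it (on the opposite strand) when
#' it is the upstream (J/D 5') signal.  Coordinates are 1-based inclusive on
#' the plus strand; for minus-strand hits the heptamer occupies the
#' high-coordinate end of the interval.
#'
#' @param genome A [Biostrings::DNAStringSet] (or single `DNAString` /
#'   character string) of contigs.
#' @param params An [rss_params()] object.
#' @param dedupe When `TRUE` (default) overlapping same-strand, same-class
#'   candidates are reduced to the lowest total-mismatch hit, ties broken by
#'   smaller start coordinate, then by smaller deviation from the nominal
#'   spacer.
#'
#' @return A `data.frame` (class `rss_hits`) sorted by contig then start,
#'   with heptamer/spacer/nonamer intervals, mismatch counts, spacer class
#'   and length, and the `cac_intact` flag.
#' @export
scan_rss <- function(genome, params = rss_params(), dedupe = TRUE) {
  genome <- as_genome(genome)
  res <- list()
  for (nm in names(genome)) {
    seq <- genome[[nm]]
    L <- length(seq)
    if (L == 0L) next
    s_plus <- strsplit(as.character(seq), "")[[1]]
    s_minus <- strsplit(as.character(Biostrings::reverseComplement(seq)), "")[[1]]
    res[[length(res) + 1L]] <- .scan_one(s_plus, nm, "+", L, params)
    res[[length(res) + 1L]] <- .scan_one(s_minus, nm, "-", L, params)
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       spacer_class = integer(0), spacer_len = integer(0),
                       hept_start = integer(0), hept_end = integer(0),
                       non_start = integer(0), non_end = integer(0),
                       hept_mm = integer(0), non_mm = integer(0),
                       cac_intact = logical(0), stringsAsFactors = FALSE)
    class(hits) <- c("rss_hits", "data.frame")
    return(hits)
  }
  if (dedupe) hits <- .dedupe_rss(hits)
  hits <- hits[order(hits$contig, hits$start, hits$strand, hits$spacer_class), ]
  rownames(hits) <- NULL
  class(hits) <- c("rss_hits", "data.frame")
  hits
}

# Reduce clusters of overlapping heptamer intervals (same contig, strand and
# spacer class) to the single best candidate.
.dedupe_rss <- function(hits) {
  total <- hits$hept_mm + hits$non_mm
  dev <- abs(hits$spacer_len - hits$spacer_class)
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$contig, hits$strand, hits$spacer_class))) {
    grp <- grp[order(hits$hept_start[grp])]
    # chain overlapping heptamer intervals into clusters
    cl_end <- hits$hept_end[grp[1L]]
    cluster <- grp[1L]
    flush <- function(cluster) {
      best <- cluster[order(total[cluster], hits$start[cluster], dev[cluster])][1L]
      keep[best] <<- TRUE
    }
    for (idx in grp[-1L]) {
      if (hits$hept_start[idx] <= cl_end) {
        cluster <- c(cluster, idx)
        cl_end <- max(cl_end, hits$hept_end[idx])
      } else {
        flush(cluster)
        cluster <- idx
        cl_end <- hits$hept_end[idx]
      }
    }
    flush(cluster)
  }
  hits[keep, , drop = FALSE]
}

#' Test the 12/23 pairing rule for two RSS hits
#'
#' @param a,b Single rows of an `rss_hits` table (or lists with a
#'   `spacer_class` element).
#' @return `TRUE` iff one signal is 12-class and the other 23-class.
#' @export
check_12_23_pair <- function(a, b) {
  ca <- if (is.data.frame(a)) a$spacer_class else a[["spacer_class"]]
  cb <- if (is.data.frame(b)) b$spacer_class else b[["spacer_class"]]
  stopifnot(length(ca) == 1L, length(cb) == 1L)
  setequal(c(ca, cb), c(12L, 23L))
}

#' Export RSS hits as BED6
#'
#' Internal coordinates are 1-based inclusive; the BED lines are 0-based
#' half-open per the format.  The name field is `RSS<class>` and the score
#' the total mismatch count.
#'
#' @param hits An `rss_hits` table from [scan_rss()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rss_bed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\tRSS%d\t%d\t%s",
                   hits$contig, hits$start - 1L, hits$end,
                   hits$spacer_class, hits$hept_mm + hits$non_mm, hits$strand)
  writeLines(lines, path)
  invisible(path)
}

# Coerce the accepted genome representations to a named DNAStringSet.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (is.null(names(genome)))
      names(genome) <- paste0("seq", seq_along(genome))
    return(genome)
  }
  if (inherits(genome, "DNAString"))
    genome <- as.character(genome)
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome)))
      names(g) <- paste0("seq", seq_along(g))
    else names(g) <- names(genome)
    return(g)
  }
  stop("cannot interpret 'genome' as DNA sequence(s)")
}
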