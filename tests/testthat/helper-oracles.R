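# Independent oracles used to verify the package's implementations.
# Each is written as plainly as possible (naive loops, full enumeration)
# and never shares code with the functions it checks.

# Brute-force RSS scan: test every offset and spacer length on both strands
# by direct character comparison.  No dedup, no vectorised profile.
oracle_scan_rss <- function(dna_chr, params, contig = "seq1") {
  hept <- strsplit(params$heptamer_consensus, "")[[1]]
  non <- strsplit(params$nonamer_consensus, "")[[1]]
  spacers <- unlist(lapply(params$spacer_classes, function(cl)
    (cl - params$spacer_tolerance):(cl + params$spacer_tolerance)))
  classes <- rep(params$spacer_classes, each = 2L * params$spacer_tolerance + 1L)
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  rows <- list()
  for (strand in c("+", "-")) {
    s <- strsplit(if (strand == "+") dna_chr else revcomp(dna_chr), "")[[1]]
    L <- length(s)
    for (k in seq_along(spacers)) {
      sp <- spacers[k]
      span <- 16L + sp
      for (i in seq_len(max(0L, L - span + 1L))) {
        h_mm <- sum(s[i:(i + 6L)] != hept)
        n_mm <- sum(s[(i + 7L + sp):(i + 15L + sp)] != non)
        cac <- all(s[i:(i + 2L)] == c("C", "A", "C"))
        if (h_mm > params$max_heptamer_mismatches) next
        if (n_mm > params$max_nonamer_mismatches) next
        if (params$require_cac && !cac) next
        if (strand == "+") {
          start <- i; end <- i + span - 1L
        } else {
          end <- L - i + 1L; start <- end - span + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, start = start, end = end, strand = strand,
          spacer_class = classes[k], spacer_len = sp,
          hept_mm = h_mm, non_mm = n_mm, cac_intact = cac,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      spacer_class = integer(0), spacer_len = integer(0),
                      hept_mm = integer(0), non_mm = integer(0),
                      cac_intact = logical(0)))
  out[order(out$contig, out$start, out$strand, out$spacer_class,
            out$spacer_len), ]
}

# Canonical sort + column subset for comparing RSS hit tables.
rss_key <- function(df) {
  df <- df[order(df$contig, df$start, df$strand, df$spacer_class,
                 df$spacer_len), c("contig", "start", "end", "strand",
                                   "spacer_class", "spacer_len", "hept_mm",
                                   "non_mm", "cac_intact")]
  rownames(df) <- NULL
  class(df) <- "data.frame"
  df
}

# Affine-gap Smith-Waterman best local score on amino-acid strings (full
# dynamic program, naive loops).  Coordinates of planted homologs are
# checked against the planting plan, so only the score is needed here.
oracle_smith_waterman <- function(pattern, subject, submat,
                                  gap_open = 10, gap_ext = 4) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  M <- matrix(0, np + 1L, ns + 1L)    # match state
  X <- matrix(-Inf, np + 1L, ns + 1L) # gap in subject
  Y <- matrix(-Inf, np + 1L, ns + 1L) # gap in pattern
  best <- 0
  for (i in 2:(np + 1L)) {
    for (j in 2:(ns + 1L)) {
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                     X[i - 1L, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                     Y[i, j - 1L] - gap_ext)
      sub <- submat[p[i - 1L], s[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L] + sub,
                     X[i - 1L, j - 1L] + sub, Y[i - 1L, j - 1L] + sub)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments, mirroring the classical two-sided doubling rule.
oracle_wilcoxon_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  u_all <- apply(idx, 2L, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) p <- 2 * mean(u_all >= u_obs)
  else p <- 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Fisher two-sided p by enumerating all tables with the observed margins
# and summing hypergeometric probabilities not exceeding the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small random genome helper.
random_genome <- function(n, seed, gc = 0.43, name = "seq1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

# Consensus RSS string (heptamer + spacer + nonamer) for planting.
rss_string <- function(spacer_len, spacer_seq = NULL) {
  if (is.null(spacer_seq))
    spacer_seq <- paste(rep("T", spacer_len), collapse = "")
  paste0("CACAGTG", spacer_seq, "ACAAAAACC")
}
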