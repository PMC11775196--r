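# Internal: coerce a genome (named character vector or DNAStringSet) to a
# named DNAStringSet.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort("`genome` must be a named character vector or DNAStringSet")
}

# Hamming mismatch count of `pattern` at every start position of `subject`.
# N in the subject never matches a pattern base.
half_mismatches <- function(pattern, subject) {
  L <- length(subject)
  w <- nchar(pattern)
  if (L < w) return(integer(0))
  Biostrings::neditStartingAt(Biostrings::DNAString(pattern), subject,
                              starting.at = seq_len(L - w + 1L),
                              with.indels = FALSE, fixed = TRUE)
}

#' Scan a genome for a two-half-site motif with a variable spacer
#'
#' Finds occurrences of `half5 - N(k) - half3` (default the NFI consensus
#' `TTGGC(Nk)GCCAA`) for every spacer length in `spacers`, tolerating up to
#' `max_mismatch_per_half` mismatches in each half-site; the spacer bases are
#' fully degenerate. `N` in the genome never matches. Both strands are
#' scanned; because the default motif is its own reverse complement, an exact
#' hit occurs at the same position on both strands, and such duplicates
#' (identical chromosome, start and spacer at 0 mismatches) are merged,
#' keeping the plus-strand record.
#'
#' @param genome Named character vector of sequences, or a `DNAStringSet`.
#' @param half5,half3 The two half-site consensus strings.
#' @param spacers Integer vector of spacer lengths to scan (default 3:7).
#' @param max_mismatch_per_half Mismatch budget per half-site (default 1).
#' @return A tibble of class `ps_motif_hits`: `chrom`, `start` (0-based),
#'   `strand`, `spacer_len`, `n_mismatches` (total over both halves),
#'   `matched` (the strand-oriented matched sequence, length
#'   `nchar(half5) + k + nchar(half3)`).
#' @export
#' @examples
#' scan_motif(c(chrT = "AATTGGCACGTAGCCAATT"))
scan_motif <- function(genome, half5 = "TTGGC", half3 = "GCCAA",
                       spacers = 3:7, max_mismatch_per_half = 1) {
  genome <- as_genome(genome)
  w5 <- nchar(half5)
  w3 <- nchar(half3)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  hits <- purrr::imap_dfr(as.list(genome), function(subj, chrom) {
    L <- length(subj)
    strand_scan <- function(h5, h3, strand) {
      mm5 <- half_mismatches(h5, subj)
      mm3 <- half_mismatches(h3, subj)
      purrr::map_dfr(sort(unique(as.integer(spacers))), function(k) {
        len <- w5 + k + w3
        if (L < len) return(NULL)
        i <- seq_len(L - len + 1L)
        tot <- mm5[i] + mm3[i + w5 + k]
        ok <- mm5[i] <= max_mismatch_per_half &
          mm3[i + w5 + k] <= max_mismatch_per_half
        if (!any(ok)) return(NULL)
        s <- i[ok]
        seqs <- as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(s, width = len)))
        if (strand == "-") {
          seqs <- vapply(seqs, rc, character(1), USE.NAMES = FALSE)
        }
        tibble(
          chrom = chrom, start = s - 1L, strand = strand,
          spacer_len = k, n_mismatches = as.integer(tot[ok]),
          matched = seqs
        )
      })
    }
    bind_rows(
      strand_scan(half5, half3, "+"),
      # a minus-strand hit reads the reverse complement of the motif on the
      # forward strand
      strand_scan(rc(half3), rc(half5), "-")
    )
  })
  if (nrow(hits) == 0) {
    out <- tibble(chrom = character(), start = integer(),
                  strand = character(), spacer_len = integer(),
                  n_mismatches = integer(), matched = character())
    class(out) <- c("ps_motif_hits", class(out))
    return(out)
  }
  out <- hits %>%
    group_by(.data$chrom, .data$start, .data$spacer_len) %>%
    filter(!(.data$n_mismatches == 0 & .data$strand == "-" &
               any(.data$n_mismatches == 0 & .data$strand == "+"))) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start, .data$spacer_len, .data$strand)
  class(out) <- c("ps_motif_hits", class(out))
  out
}

#' Motif occurrence enrichment in peaks versus shuffled placement
#'
#' Computes the fraction of peaks fully containing at least one motif hit,
#' and an empirical p-value against `n_shuffles` uniform re-placements of
#' equal-length intervals on the same chromosomes:
#' `p = (1 + #shuffles with fraction >= observed) / (1 + n_shuffles)`.
#' The genome is scanned once and hit positions reused across shuffles.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`).
#' @param genome Named character vector of sequences, or a `DNAStringSet`.
#' @param ... Passed to [scan_motif()].
#' @param n_shuffles Number of shuffles (default 200).
#' @param seed Integer seed for the shuffles.
#' @return A list of class `ps_motif_enrichment`: `observed_fraction`,
#'   `p_value`, `n_shuffles`, `shuffle_fractions`, `hits`.
#' @export
motif_enrichment <- function(peaks, genome, ..., n_shuffles = 200, seed = 1L) {
  genome <- as_genome(genome)
  peaks <- as_tibble(peaks)
  hits <- scan_motif(genome, ...)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  frac_with_hit <- function(p) {
    has <- logical(nrow(p))
    for (chr in unique(p$chrom)) {
      h <- hits %>% filter(.data$chrom == chr)
      pi <- which(p$chrom == chr)
      if (nrow(h) == 0) next
      hlen <- nchar(h$matched)
      has[pi] <- vapply(pi, function(j) {
        any(h$start >= p$start[j] & h$start + hlen <= p$end[j])
      }, logical(1))
    }
    mean(has)
  }
  observed <- frac_with_hit(peaks)
  shuffle_fracs <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    width <- peaks$end - peaks$start
    new_start <- floor(runif(nrow(peaks)) *
                         (chrom_len[peaks$chrom] - width + 1))
    frac_with_hit(tibble(chrom = peaks$chrom,
                         start = as.integer(new_start),
                         end = as.integer(new_start + width)))
  }, double(1)))
  out <- list(
    observed_fraction = observed,
    p_value = (1 + sum(shuffle_fracs >= observed)) / (1 + n_shuffles),
    n_shuffles = n_shuffles,
    shuffle_fractions = shuffle_fracs,
    hits = hits
  )
  class(out) <- "ps_motif_enrichment"
  out
}

#' @export
print.ps_motif_enrichment <- function(x, ...) {
  cat("<ps_motif_enrichment> observed fraction ",
      format(x$observed_fraction, digits = 4), ", empirical p = ",
      format(x$p_value, digits = 4), " (", x$n_shuffles, " shuffles)\n",
      sep = "")
  invisible(x)
}
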