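# Internal: tibble of 0-based half-open intervals -> IRanges (1-based closed).
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Overlap-group Venn partition of multiple peak sets
#'
#' Peaks from all sets are grouped by connected components of the overlap
#' graph ("overlap" = at least one shared base; half-open intervals that
#' merely touch do not overlap). Each group — a maximal physical region bound
#' in at least one condition — is assigned to the Venn region named by the
#' set labels it contains, so one region on the genome is counted once no
#' matter how many peaks cover it.
#'
#' @param peaksets A named list of peak tibbles (`chrom`, `start`, `end`,
#'   optionally `name`, `score`).
#' @return An object of class `ps_overlap`: `regions` (tibble `region`, `n`
#'   over all `2^k - 1` label combinations), `groups` (one row per overlap
#'   group with its span and labels), `peaks` (every input peak with its
#'   `group_id`). [tidy()] returns `regions`.
#' @export
overlap_peaks <- function(peaksets) {
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets)))) {
    abort("`peaksets` must be a fully named list")
  }
  labels <- names(peaksets)
  all_peaks <- purrr::imap_dfr(peaksets, function(p, lab) {
    as_tibble(p) %>% mutate(set_label = lab)
  })
  if (nrow(all_peaks) == 0) abort("no peaks supplied")
  all_peaks$group_id <- NA_integer_
  next_id <- 0L
  for (chr in unique(all_peaks$chrom)) {
    idx <- which(all_peaks$chrom == chr)
    ir <- as_iranges0(all_peaks[idx, ])
    # merge only truly overlapping intervals (>= 1 shared base)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L,
                                 select = "first")
    all_peaks$group_id[idx] <- next_id + hit
    next_id <- next_id + length(red)
  }
  groups <- all_peaks %>%
    group_by(.data$group_id) %>%
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      labels = list(sort(unique(.data$set_label))),
      .groups = "drop"
    ) %>%
    mutate(region = purrr::map_chr(.data$labels, paste, collapse = "&"))
  combos <- unlist(lapply(seq_along(labels), function(m) {
    utils::combn(sort(labels), m, paste, collapse = "&")
  }))
  regions <- tibble(region = combos) %>%
    left_join(groups %>% count(.data$region), by = "region") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  out <- list(regions = regions, groups = groups, peaks = all_peaks)
  class(out) <- "ps_overlap"
  out
}

#' @export
tidy.ps_overlap <- function(x, ...) x$regions

#' @export
print.ps_overlap <- function(x, ...) {
  cat("<ps_overlap> ", nrow(x$groups), " overlap groups across ",
      nrow(x$peaks), " peaks\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Nearest-TSS peak annotation
#'
#' Assigns each peak to the gene whose transcription start site is closest to
#' the peak center (`floor((start + end) / 2)`); equidistant candidates break
#' to the lexicographically smallest `gene_id`. Peaks on chromosomes with no
#' gene stay unassigned (`gene_id` NA, `unassigned` TRUE).
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`, ...).
#' @param genes A gene model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @return The peaks with `center`, `gene_id`, `tss_distance`, `unassigned`.
#' @export
annotate_peaks <- function(peaks, genes) {
  peaks <- as_tibble(peaks) %>%
    mutate(center = (.data$start + .data$end) %/% 2L)
  # one candidate per distinct TSS position: the smallest gene_id there
  cand <- as_tibble(genes) %>%
    group_by(.data$chrom, .data$tss) %>%
    summarise(gene_id = min(.data$gene_id), .groups = "drop") %>%
    arrange(.data$chrom, .data$tss)
  out <- peaks %>%
    mutate(gene_id = NA_character_, tss_distance = NA_integer_)
  for (chr in unique(peaks$chrom)) {
    g <- cand %>% filter(.data$chrom == chr)
    idx <- which(peaks$chrom == chr)
    if (nrow(g) == 0) next
    pos <- findInterval(peaks$center[idx], g$tss)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, nrow(g))
    d_lo <- abs(peaks$center[idx] - g$tss[lo])
    d_hi <- abs(peaks$center[idx] - g$tss[hi])
    pick_lo <- d_lo < d_hi |
      (d_lo == d_hi & g$gene_id[lo] <= g$gene_id[hi])
    pick <- if_else(pick_lo, lo, hi)
    out$gene_id[idx] <- g$gene_id[pick]
    out$tss_distance[idx] <- as.integer(pmin(d_lo, d_hi))
  }
  out %>% mutate(unassigned = is.na(.data$gene_id))
}

#' Top-N targetome from a scored peak set
#'
#' Sorts peaks by score descending (ties by chromosome then start, so the
#' result is deterministic even under constant scores), takes the first `n`,
#' annotates them by nearest TSS, and returns the distinct assigned genes.
#'
#' @param peaks A peak tibble with a `score` column.
#' @param genes A gene model tibble.
#' @param n Number of top peaks to keep (default 500).
#' @return A character vector of distinct target gene ids.
#' @export
top_targets <- function(peaks, genes, n = 500) {
  top <- as_tibble(peaks) %>%
    arrange(desc(.data$score), .data$chrom, .data$start) %>%
    head(n)
  ann <- annotate_peaks(top, genes)
  sort(unique(ann$gene_id[!ann$unassigned]))
}

#' Classify binding events between two conditions
#'
#' Classifies condition A's peaks against condition B by one-base overlap:
#' `lost` = A peaks overlapping no B peak, `shared` = A peaks overlapping at
#' least one, `gained` = B peaks overlapping no A peak. `lost` and `shared`
#' partition A, so their sizes always sum to `nrow(cond_a)`.
#'
#' @param cond_a,cond_b Peak tibbles (`chrom`, `start`, `end`, ...).
#' @return A list of class `ps_binding_shift` with tibbles `lost`, `shared`,
#'   `gained`.
#' @export
classify_binding <- function(cond_a, cond_b) {
  cond_a <- as_tibble(cond_a)
  cond_b <- as_tibble(cond_b)
  hits_any <- function(x, y) {
    out <- logical(nrow(x))
    for (chr in unique(x$chrom)) {
      xi <- which(x$chrom == chr)
      yi <- which(y$chrom == chr)
      if (length(yi) == 0) next
      out[xi] <- IRanges::overlapsAny(as_iranges0(x[xi, ]),
                                      as_iranges0(y[yi, ]),
                                      minoverlap = 1L)
    }
    out
  }
  a_in_b <- hits_any(cond_a, cond_b)
  b_in_a <- hits_any(cond_b, cond_a)
  out <- list(
    lost = cond_a[!a_in_b, ],
    shared = cond_a[a_in_b, ],
    gained = cond_b[!b_in_a, ]
  )
  class(out) <- "ps_binding_shift"
  out
}

#' @export
glance.ps_binding_shift <- function(x, ...) {
  tibble(n_lost = nrow(x$lost), n_shared = nrow(x$shared),
         n_gained = nrow(x$gained))
}

#' Peak-centered coverage signal matrix
#'
#' For each peak, averages a bedGraph-style coverage track in fixed-width
#' bins across a symmetric window around the peak center
#' (`[center - window, center + window)`); uncovered bases count as 0.
#' Rows are ordered by the peak's own mean signal, descending, unless a
#' `reference_order` is supplied — the row order of a reference sample's
#' matrix, so that several samples can be displayed against the same
#' ordering.
#'
#' @param coverage A coverage tibble (`chrom`, `start`, `end`, `value`),
#'   non-overlapping within chromosomes, e.g. from [read_bedgraph()].
#' @param peaks A peak tibble.
#' @param window Half-window in bases (default 5000).
#' @param bin Bin width in bases; must divide `window`.
#' @param reference_order Optional integer permutation of `seq_len(nrow(peaks))`
#'   fixing the row order.
#' @return An object of class `ps_signal`: `matrix`
#'   (peaks x bins, ordered), `profile` (column means), `bin_mid` (bin
#'   midpoint offsets from the peak center), `peaks` (the ordered peak
#'   tibble with `mean_signal`), `order` (the permutation applied).
#' @export
signal_matrix <- function(coverage, peaks, window = 5000, bin = 50,
                          reference_order = NULL) {
  if (window %% bin != 0) abort("`bin` must divide `window`")
  peaks <- as_tibble(peaks) %>%
    mutate(center = (.data$start + .data$end) %/% 2L)
  n_bins <- as.integer(2 * window / bin)
  offsets <- -window + (seq_len(n_bins) - 1L) * bin
  # cumulative-integral interpolator per chromosome: F(x) = integral of
  # coverage over [min_knot, x], constant across gaps and outside the track
  integrators <- lapply(split(as_tibble(coverage), coverage$chrom),
                        function(cv) {
    cv <- cv %>% arrange(.data$start)
    area <- cumsum(cv$value * (cv$end - cv$start))
    x <- c(rbind(cv$start, cv$end))
    y <- c(rbind(c(0, head(area, -1)), area))
    keep <- !duplicated(x, fromLast = TRUE)
    stats::approxfun(x[keep], y[keep], rule = 2)
  })
  mat <- matrix(0, nrow = nrow(peaks), ncol = n_bins)
  for (i in seq_len(nrow(peaks))) {
    fn <- integrators[[peaks$chrom[i]]]
    if (is.null(fn)) next
    edges <- peaks$center[i] + c(offsets, window)
    mat[i, ] <- diff(fn(edges)) / bin
  }
  mean_signal <- rowMeans(mat)
  ord <- if (is.null(reference_order)) {
    order(-mean_signal, peaks$chrom, peaks$start)
  } else {
    if (!setequal(reference_order, seq_len(nrow(peaks)))) {
      abort("`reference_order` must be a permutation of the peak rows")
    }
    reference_order
  }
  mat <- mat[ord, , drop = FALSE]
  out <- list(
    matrix = mat,
    profile = colMeans(mat),
    bin_mid = offsets + bin / 2,
    peaks = peaks[ord, ] %>% mutate(mean_signal = mean_signal[ord]),
    order = ord
  )
  class(out) <- "ps_signal"
  out
}

#' Write a signal matrix as a dense TSV
#'
#' Header row of bin midpoint offsets, then one row per peak.
#'
#' @param x A `ps_signal` object.
#' @param path Output path.
#' @export
write_signal_matrix <- function(x, path) {
  df <- as.data.frame(x$matrix)
  names(df) <- as.character(x$bin_mid)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}
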