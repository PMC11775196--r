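# Independent brute-force oracles. These deliberately use different
# algorithms and code paths from the package implementation.

# BFDR by explicit sort + prefix sums + running maximum.
oracle_bfdr <- function(avg_p, avg_spec, prey_id) {
  ord <- order(-avg_p, -avg_spec, prey_id)
  one_minus <- 1 - avg_p[ord]
  prefix <- numeric(length(one_minus))
  acc <- 0
  for (i in seq_along(one_minus)) {
    acc <- acc + one_minus[i]
    prefix[i] <- acc / i
  }
  run_max <- prefix
  for (i in seq_along(run_max)[-1]) {
    run_max[i] <- max(run_max[i - 1], run_max[i])
  }
  list(order = ord, bfdr = run_max)
}

# Connected components of the interval-overlap graph by adjacency matrix
# and breadth-first search (O(n^2)); intervals 0-based half-open.
oracle_overlap_groups <- function(df) {
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- df$chrom[i] == df$chrom[j] &&
        df$start[i] < df$end[j] && df$start[j] < df$end[i]
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Region counts from a brute-force component assignment.
oracle_region_counts <- function(df, comp) {
  sig <- vapply(split(df$set_label, comp), function(labs) {
    paste(sort(unique(labs)), collapse = "&")
  }, character(1))
  table(sig)
}

# Exhaustive sliding-window motif scan over every position, spacer and
# strand, comparing characters one by one. Returns plus-strand windows that
# match on either strand with per-half budgets (strand bookkeeping mirrors
# the documented merge rule).
oracle_scan_motif <- function(genome, half5 = "TTGGC", half3 = "GCCAA",
                              spacers = 3:7, max_mm = 1) {
  revcomp_chr <- function(v) {
    rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v]))
  }
  p5 <- strsplit(half5, "")[[1]]
  p3 <- strsplit(half3, "")[[1]]
  rows <- list()
  for (chrom in names(genome)) {
    g <- strsplit(genome[[chrom]], "")[[1]]
    L <- length(g)
    for (k in spacers) {
      len <- length(p5) + k + length(p3)
      if (L < len) next
      for (s in 0:(L - len)) {
        win <- g[(s + 1):(s + len)]
        for (strand in c("+", "-")) {
          w <- if (strand == "+") win else revcomp_chr(win)
          mm5 <- sum(w[seq_along(p5)] != p5)
          mm3 <- sum(w[(length(p5) + k + 1):len] != p3)
          if (mm5 <= max_mm && mm3 <= max_mm) {
            rows[[length(rows) + 1]] <- data.frame(
              chrom = chrom, start = s, strand = strand,
              spacer_len = k, n_mismatches = mm5 + mm3,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), spacer_len = integer(),
                      n_mismatches = integer()))
  }
  # merge exact palindromic duplicates, keeping the plus-strand record
  key <- paste(out$chrom, out$start, out$spacer_len)
  drop <- out$n_mismatches == 0 & out$strand == "-" &
    key %in% key[out$n_mismatches == 0 & out$strand == "+"]
  out <- out[!drop, ]
  out[order(out$chrom, out$start, out$spacer_len, out$strand), ]
}

# Same exhaustive enumeration (every position, spacer, strand) but with
# vectorised character comparisons, for larger genomes. Still independent of
# the implementation's Biostrings route.
oracle_scan_motif_vec <- function(genome, half5 = "TTGGC", half3 = "GCCAA",
                                  spacers = 3:7, max_mm = 1) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc_str <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                              collapse = "")
  mm_profile <- function(g, pat) {
    p <- strsplit(pat, "")[[1]]
    L <- length(g)
    w <- length(p)
    n <- L - w + 1
    if (n < 1) return(integer(0))
    mm <- integer(n)
    for (j in seq_len(w)) mm <- mm + (g[j:(j + n - 1)] != p[j])
    mm
  }
  rows <- list()
  for (chrom in names(genome)) {
    g <- strsplit(genome[[chrom]], "")[[1]]
    L <- length(g)
    profiles <- list(
      "+" = list(h5 = mm_profile(g, half5), h3 = mm_profile(g, half3),
                 w5 = nchar(half5)),
      "-" = list(h5 = mm_profile(g, rc_str(half3)),
                 h3 = mm_profile(g, rc_str(half5)),
                 w5 = nchar(rc_str(half3)))
    )
    for (strand in c("+", "-")) {
      pr <- profiles[[strand]]
      for (k in spacers) {
        len <- nchar(half5) + k + nchar(half3)
        if (L < len) next
        i <- seq_len(L - len + 1)
        ok <- pr$h5[i] <= max_mm & pr$h3[i + pr$w5 + k] <= max_mm
        if (!any(ok)) next
        s <- i[ok]
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = s - 1L, strand = strand, spacer_len = k,
          n_mismatches = pr$h5[s] + pr$h3[s + pr$w5 + k],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), spacer_len = integer(),
                      n_mismatches = integer()))
  }
  key <- paste(out$chrom, out$start, out$spacer_len)
  drop <- out$n_mismatches == 0 & out$strand == "-" &
    key %in% key[out$n_mismatches == 0 & out$strand == "+"]
  out <- out[!drop, ]
  out[order(out$chrom, out$start, out$spacer_len, out$strand,
            method = "radix"), ]
}

# Hypergeometric upper tail by explicit enumeration of binomial products.
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg by the textbook step-up construction.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Small deterministic run table used across suites: two baits, a control
# series, one obvious interactor per bait and a shared background.
toy_run_table <- function() {
  runs <- tibble::tibble(
    run_id = c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3", "C4"),
    bait_id = c(rep("NFIA", 3), rep("NFIB", 3), rep("GFP", 4)),
    assay = "BIOID",
    labeling_time_h = 16,
    cell_line = "HEK293",
    replicate = c(1:3, 1:3, 1:4),
    is_control = c(rep(FALSE, 6), rep(TRUE, 4))
  )
  counts <- tibble::tibble(
    run_id = c("A1", "A2", "A3", "A1", "A2", "A3",
               "B1", "B2", "B3", "B1",
               "C1", "C2", "C1", "C2", "C3", "C4"),
    prey_id = c("SMARCA4", "SMARCA4", "SMARCA4", "KRT1", "KRT1", "KRT1",
                "MED1", "MED1", "MED1", "SMARCA4",
                "KRT1", "KRT1", "RPL3", "RPL3", "RPL3", "RPL3"),
    count = c(20L, 25L, 18L, 8L, 6L, 7L,
              15L, 12L, 19L, 4L,
              9L, 7L, 3L, 2L, 4L, 3L)
  )
  suppressWarnings(run_table(counts, runs))
}
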