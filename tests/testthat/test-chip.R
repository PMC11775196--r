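peaks_tbl <- function(chrom, start, end, score = 0) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 name = sprintf("pk%02d", seq_along(start)), score = score)
}

random_peaksets <- function(n_sets = 4, n_per_set = 50, seed = 1) {
  set.seed(seed)
  setNames(lapply(seq_len(n_sets), function(i) {
    start <- sample(0:5000, n_per_set)
    peaks_tbl(sample(c("chr1", "chr2"), n_per_set, replace = TRUE),
              start, start + sample(20:120, n_per_set, replace = TRUE),
              score = runif(n_per_set))
  }), LETTERS[seq_len(n_sets)])
}

test_that("peak overlap uses at-least-one-shared-base semantics", {
  ov <- overlap_peaks(list(A = peaks_tbl("chr1", 100, 200),
                           B = peaks_tbl("chr1", 150, 250)))
  expect_equal(ov$regions$n[ov$regions$region == "A&B"], 1)
  expect_equal(sum(ov$regions$n), 1)

  # half-open: touching intervals share no base
  ov2 <- overlap_peaks(list(A = peaks_tbl("chr1", 100, 200),
                            B = peaks_tbl("chr1", 200, 300)))
  n <- setNames(ov2$regions$n, ov2$regions$region)
  expect_equal(unname(n[c("A", "B", "A&B")]), c(1, 1, 0))

  # identical sets populate only the all-labels region
  p <- peaks_tbl("chr1", c(0, 500), c(100, 600))
  ov3 <- overlap_peaks(list(A = p, B = p))
  expect_equal(ov3$regions$n[ov3$regions$region == "A&B"], 2)
  expect_equal(sum(ov3$regions$n), 2)
})

test_that("overlap groups match the quadratic connected-component oracle", {
  for (seed in 1:8) {
    sets <- random_peaksets(4, 50, seed = seed)
    ov <- overlap_peaks(sets)
    df <- do.call(rbind, lapply(names(sets), function(lab) {
      cbind(as.data.frame(sets[[lab]]), set_label = lab)
    }))
    comp <- oracle_overlap_groups(df)
    counts <- oracle_region_counts(df, comp)
    got <- setNames(ov$regions$n, ov$regions$region)
    for (r in names(counts)) {
      expect_equal(unname(got[r]), unname(unclass(counts[r])))
    }
    expect_equal(sum(ov$regions$n), length(unique(comp)))
  }
})

test_that("nearest-TSS annotation breaks ties lexicographically", {
  genes <- tibble::tibble(
    gene_id = c("GENE_B", "GENE_A", "GENE_C"),
    chrom = c("chr1", "chr1", "chr1"),
    tss = c(900L, 1100L, 1500L), strand = "+"
  )
  # center 1000: GENE_B at 900 and GENE_A at 1100 are equidistant -> GENE_A
  ann <- annotate_peaks(peaks_tbl("chr1", 950, 1050), genes)
  expect_equal(ann$gene_id, "GENE_A")
  # center 1400 is closest to 1500
  ann2 <- annotate_peaks(peaks_tbl("chr1", 1350, 1450), genes)
  expect_equal(ann2$gene_id, "GENE_C")
  # no genes on the peak's chromosome: unassigned
  ann3 <- annotate_peaks(peaks_tbl("chrX", 0, 100), genes)
  expect_true(ann3$unassigned)
})

test_that("top targets deduplicate genes and break score ties by position", {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr1", tss = c(100L, 5000L),
    strand = "+"
  )
  pk <- peaks_tbl("chr1", c(50, 150, 4900), c(120, 220, 4980),
                  score = c(10, 5, 1))
  expect_equal(top_targets(pk, genes, n = 10), c("G1", "G2"))
  # two top peaks annotate to the same gene: counted once
  expect_equal(top_targets(pk, genes, n = 2), "G1")
  # constant scores: positional tie-break is deterministic
  pk$score <- 1
  expect_equal(top_targets(pk, genes, n = 2), "G1")
})

test_that("binding classification partitions condition A", {
  a <- peaks_tbl("chr1", c(0, 200), c(100, 300))
  b <- peaks_tbl("chr1", c(250, 500), c(350, 600))
  got <- classify_binding(a, b)
  expect_equal(nrow(got$lost), 1)
  expect_equal(nrow(got$shared), 1)
  expect_equal(nrow(got$gained), 1)
  expect_equal(nrow(got$lost) + nrow(got$shared), nrow(a))

  same <- classify_binding(a, a)
  expect_equal(nrow(same$shared), nrow(a))
  expect_equal(nrow(same$lost) + nrow(same$gained), 0)
})

test_that("classify_binding mirrors the oracle and swaps lost/gained", {
  for (seed in 1:8) {
    sets <- random_peaksets(2, 40, seed = 100 + seed)
    a <- sets[[1]]
    b <- sets[[2]]
    fwd <- classify_binding(a, b)
    rev <- classify_binding(b, a)
    expect_equal(fwd$lost, rev$gained)
    expect_equal(nrow(fwd$lost) + nrow(fwd$shared), nrow(a))
    # quadratic oracle for A-peak classification
    overlaps <- vapply(seq_len(nrow(a)), function(i) {
      any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
    }, logical(1))
    expect_equal(sort(fwd$shared$name), sort(a$name[overlaps]))
  }
})

test_that("signal matrices integrate coverage exactly", {
  cov <- tibble::tibble(chrom = "chr1", start = 0L, end = 100000L,
                        value = 1.0)
  pk <- peaks_tbl("chr1", c(40000, 60000), c(40200, 60200))
  sm <- signal_matrix(cov, pk, window = 1000, bin = 50)
  expect_equal(dim(sm$matrix), c(2, 40))
  expect_true(all(abs(sm$matrix - 1) < 1e-9))
  expect_equal(sm$profile, rep(1, 40), tolerance = 1e-9)

  # coverage only at the centers: center bins dominate flanks
  cov2 <- tibble::tibble(chrom = "chr1",
                         start = c(40090L, 60090L), end = c(40110L, 60110L),
                         value = 5)
  sm2 <- signal_matrix(cov2, pk, window = 1000, bin = 50)
  center_cols <- 20:21
  for (i in 1:2) {
    expect_gt(max(sm2$matrix[i, center_cols]), max(sm2$matrix[i, -center_cols]))
  }
  # profile equals independently recomputed column means
  expect_equal(sm2$profile, apply(sm2$matrix, 2, mean))
})

test_that("signal rows order by own signal or a supplied reference", {
  cov <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                        end = c(1000L, 2000L), value = c(1, 10))
  pk <- peaks_tbl("chr1", c(400, 1400), c(600, 1600))
  sm <- signal_matrix(cov, pk, window = 200, bin = 50)
  expect_equal(sm$peaks$name, c("pk02", "pk01"))  # hotter peak first
  ref <- signal_matrix(cov, pk, window = 200, bin = 50,
                       reference_order = c(1L, 2L))
  expect_equal(ref$peaks$name, c("pk01", "pk02"))
  expect_error(signal_matrix(cov, pk, window = 200, bin = 50,
                             reference_order = c(2L, 2L)), "permutation")
  expect_error(signal_matrix(cov, pk, window = 100, bin = 33), "divide")
})

test_that("motif scanning finds planted spacer variants on both strands", {
  g <- c(chrT = "AATTGGCACGTAGCCAATT")
  hits <- scan_motif(g)
  exact <- hits[hits$n_mismatches == 0, ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$start, 2L)
  expect_equal(exact$spacer_len, 5L)
  expect_equal(exact$strand, "+")
  expect_equal(exact$matched, "TTGGCACGTAGCCAA")

  short <- scan_motif(c(chrT = "TTGGCAAAGCCAA"))
  expect_true(any(short$spacer_len == 3 & short$n_mismatches == 0))

  # N never matches
  expect_equal(nrow(scan_motif(c(chrT = "TTGGCNNNNNGCCAA"),
                               max_mismatch_per_half = 0)), 1)
  noN <- scan_motif(c(chrT = "TTGNCAAAAAGCCAA"), max_mismatch_per_half = 0)
  expect_equal(nrow(noN), 0)
})

test_that("motif scanning equals exhaustive enumeration on random genomes", {
  set.seed(9)
  for (rep in 1:3) {
    g <- setNames(paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                        collapse = ""), "chrR")
    got <- as.data.frame(scan_motif(g))
    ora <- oracle_scan_motif(g)
    got <- got[order(got$chrom, got$start, got$spacer_len, got$strand,
                     method = "radix"), ]
    ora <- ora[order(ora$chrom, ora$start, ora$spacer_len, ora$strand,
                     method = "radix"), ]
    expect_equal(nrow(got), nrow(ora))
    expect_equal(got$start, ora$start)
    expect_equal(got$strand, ora$strand)
    expect_equal(got$spacer_len, ora$spacer_len)
    expect_equal(got$n_mismatches, ora$n_mismatches)
  }
})

test_that("motif enrichment separates planted peaks from shuffled placement", {
  pk <- simulate_peaks(n_baits = 1, n_peaks = 40, frac_shared = 1,
                       genome_lengths = c(chr1 = 100000L), seed = 13)
  me <- motif_enrichment(pk$peaks[[1]], pk$genome, n_shuffles = 50,
                         seed = 2)
  expect_equal(me$observed_fraction, 1.0)
  expect_lt(me$p_value, 0.05)
  me2 <- motif_enrichment(pk$peaks[[1]], pk$genome, n_shuffles = 50,
                          seed = 2)
  expect_identical(me$p_value, me2$p_value)

  # a genome without a single instance scans to fraction 0 and p = 1
  g0 <- setNames(paste(rep("A", 5000), collapse = ""), "chr1")
  me0 <- motif_enrichment(peaks_tbl("chr1", 100, 300), g0,
                          n_shuffles = 20, seed = 3)
  expect_equal(me0$observed_fraction, 0)
  expect_equal(me0$p_value, 1)
})
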