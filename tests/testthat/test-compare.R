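test_that("venn partitions cover every region exactly", {
  v <- venn(list(A = "a", B = "b"))
  n <- setNames(v$n, v$region)
  expect_equal(unname(n[c("A", "B", "A&B")]), c(1, 1, 0))

  v <- venn(list(A = c("x", "y"), B = c("x", "y")))
  n <- setNames(v$n, v$region)
  expect_equal(unname(n[c("A", "B", "A&B")]), c(0, 0, 2))
})

test_that("venn counts equal per-element brute-force classification", {
  set.seed(101)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) sample(sprintf("g%03d", 1:100), 50))
    names(sets) <- LETTERS[1:4]
    v <- venn(sets)
    expect_equal(sum(v$n), length(unique(unlist(sets))))
    # brute force: classify each element of the union independently
    for (el in unique(unlist(sets))) {
      sig <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                      logical(1))], collapse = "&")
      expect_true(el %in% v$members[v$region == sig][[1]])
    }
  }
})

test_that("replicate correlation matches the covariance formula", {
  rt <- toy_run_table()
  expect_equal(replicate_correlation(rt, "A1", "A1"), 1.0)

  runs <- tibble::tibble(
    run_id = c("x", "y"), bait_id = "B", assay = "BIOID",
    labeling_time_h = 3, cell_line = "L", replicate = 1:2,
    is_control = FALSE
  )
  counts <- tibble::tibble(
    run_id = rep(c("x", "y"), each = 3),
    prey_id = rep(c("P1", "P2", "P3"), 2),
    count = c(1L, 2L, 3L, 3L, 2L, 1L)
  )
  rt2 <- run_table(counts, runs)
  expect_equal(replicate_correlation(rt2, "x", "y"), -1.0)

  set.seed(5)
  counts$count <- as.integer(sample(0:20, 6, replace = TRUE))
  rt3 <- run_table(counts, runs)
  a <- counts$count[1:3]
  b <- counts$count[4:6]
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(replicate_correlation(rt3, "x", "y"), manual)
})

test_that("identical isoform count matrices yield all-ns, zero fold change", {
  cfg <- sim_config(seed = 1, n_preys = 50)
  iso <- simulate_isoform_pair(cfg, n_diff_up = 0, n_diff_down = 0,
                               effect_log2fc = 0, seed = 41)
  # duplicate FL counts into SHORT so the two matrices are identical
  tab <- tibble::as_tibble(iso$runs)
  fl <- dplyr::filter(tab, bait_id == "ISO_FL")
  mirrored <- dplyr::mutate(fl,
    run_id = sub("FL", "SHORT", run_id), bait_id = "ISO_SHORT")
  both <- dplyr::bind_rows(fl, mirrored)
  rt <- run_table(both[c("run_id", "prey_id", "count")],
                  dplyr::distinct(both[c("run_id", "bait_id", "assay",
                                         "labeling_time_h", "cell_line",
                                         "replicate", "is_control")]))
  d <- differential_isoform(rt, "ISO_FL", "ISO_SHORT")
  expect_true(all(d$class == "ns"))
  expect_true(all(d$log2fc == 0))
})

test_that("a short-isoform-only prey at high counts is called up", {
  runs <- tibble::tibble(
    run_id = c("f1", "f2", "f3", "s1", "s2", "s3"),
    bait_id = rep(c("FL", "SH"), each = 3),
    assay = "BIOID", labeling_time_h = 16, cell_line = "L",
    replicate = rep(1:3, 2), is_control = FALSE
  )
  counts <- dplyr::bind_rows(
    tibble::tibble(run_id = c("s1", "s2", "s3"), prey_id = "ONLY_SHORT",
                   count = c(40L, 52L, 47L)),
    tibble::tibble(run_id = runs$run_id, prey_id = "FLAT", count = 10L)
  )
  d <- differential_isoform(run_table(counts, runs), "FL", "SH")
  expect_equal(d$class[d$prey_id == "ONLY_SHORT"], "up")
  expect_equal(d$class[d$prey_id == "FLAT"], "ns")
})

test_that("differential analysis is antisymmetric in the two baits", {
  iso <- simulate_isoform_pair(sim_config(seed = 2, n_preys = 60),
                               effect_log2fc = 2, seed = 42)
  fwd <- differential_isoform(iso$runs, "ISO_FL", "ISO_SHORT")
  rev <- differential_isoform(iso$runs, "ISO_SHORT", "ISO_FL")
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$class == "up", rev$class == "down")
})

test_that("BH adjustment equals the step-up construction", {
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  iso <- simulate_isoform_pair(sim_config(seed = 3, n_preys = 40),
                               n_diff_up = 8, n_diff_down = 8,
                               effect_log2fc = 2, seed = 43)
  d <- differential_isoform(iso$runs, "ISO_FL", "ISO_SHORT")
  expect_equal(d$p_adj, oracle_bh(d$p))
  expect_true(all(d$p_adj >= d$p - 1e-12))
})

test_that("fewer than two replicates is an error", {
  runs <- tibble::tibble(
    run_id = c("f1", "s1", "s2"), bait_id = c("FL", "SH", "SH"),
    assay = "BIOID", labeling_time_h = 16, cell_line = "L",
    replicate = c(1L, 1L, 2L), is_control = FALSE
  )
  rt <- run_table(tibble::tibble(run_id = "f1", prey_id = "P", count = 3L),
                  runs)
  expect_error(differential_isoform(rt, "FL", "SH"), "2 replicates")
})

test_that("localization profiles normalize to a unit maximum", {
  map <- tibble::tibble(
    prey_id = c("P1", "P2", "P3", "P4"),
    compartment = c("nucleus", "nucleus", "cytosol", "er"),
    annotation_score = c(5, 3, 2, 1)
  )
  prof <- localization_profile(c("P1", "P2", "P3"), map)
  expect_equal(prof$score[prof$compartment == "nucleus"], 1.0)
  expect_equal(prof$score[prof$compartment == "cytosol"], 0.25)
  expect_equal(prof$score[prof$compartment == "er"], 0)

  empty <- localization_profile(character(0), map)
  expect_true(all(empty$score == 0))
})

test_that("stability scores are bounded, flagged and scale-invariant", {
  runs <- tibble::tibble(
    run_id = c("ap1", "ap2", "bi1", "bi2"),
    bait_id = "NFIA",
    assay = rep(c("APMS", "BIOID"), each = 2),
    labeling_time_h = c(0, 0, 16, 16), cell_line = "L",
    replicate = rep(1:2, 2), is_control = FALSE
  )
  counts <- dplyr::bind_rows(
    tibble::tibble(run_id = c("ap1", "ap2", "bi1", "bi2"),
                   prey_id = "NFIA", count = c(100L, 100L, 50L, 50L)),
    tibble::tibble(run_id = c("ap1", "ap2", "bi1", "bi2"),
                   prey_id = "BOTH", count = c(10L, 10L, 5L, 5L)),
    tibble::tibble(run_id = c("bi1", "bi2"), prey_id = "PROX_ONLY",
                   count = c(8L, 8L)),
    tibble::tibble(run_id = c("ap1", "ap2"), prey_id = "STABLE_ONLY",
                   count = c(4L, 4L))
  )
  rt <- run_table(counts, runs)
  s <- stability_scores(rt, "NFIA")
  expect_equal(s$s[s$prey_id == "BOTH"], 0.5)  # equal normalized abundance
  expect_equal(s$s[s$prey_id == "PROX_ONLY"], 0)
  expect_equal(s$s[s$prey_id == "STABLE_ONLY"], 1)
  expect_equal(s$one_sided, c(FALSE, TRUE, TRUE))

  # doubling the AP-MS bait while doubling all AP-MS prey counts cancels
  counts2 <- dplyr::mutate(counts, count = dplyr::if_else(
    run_id %in% c("ap1", "ap2"), count * 2L, count))
  s2 <- stability_scores(run_table(counts2, runs), "NFIA")
  expect_equal(s2$s, s$s)

  # bait missing from one assay errors
  rt_one <- run_table(dplyr::filter(counts, run_id %in% c("bi1", "bi2")),
                      dplyr::filter(runs, assay == "BIOID"))
  expect_error(stability_scores(rt_one, "NFIA"), "both")
})

test_that("timepoint shift is plain per-bait set algebra", {
  t1 <- tibble::tibble(bait_id = c("A", "A", "B"),
                       prey_id = c("p", "q", "r"))
  t2 <- tibble::tibble(bait_id = c("A", "B", "B"),
                       prey_id = c("q", "r", "s"))
  got <- timepoint_shift(t1, t2)
  expect_equal(got$class[got$bait_id == "A" & got$prey_id == "p"], "lost")
  expect_equal(got$class[got$bait_id == "A" & got$prey_id == "q"], "kept")
  expect_equal(got$class[got$bait_id == "B" & got$prey_id == "s"], "gained")
  expect_equal(got$class[got$bait_id == "B" & got$prey_id == "r"], "kept")
  expect_equal(nrow(got), 4)
})

test_that("dot-plot tables max-normalize within preys and drop absences", {
  hcis <- tibble::tibble(
    bait_id = c("NFIA", "NFIB", "NFIA"),
    prey_id = c("SMARCA4", "SMARCA4", "ARID1A"),
    avg_spec = c(20, 10, 6), bfdr = c(0, 0.001, 0.002)
  )
  tab <- dotplot_table(hcis, c("SMARCA4", "ARID1A", "SMARCC1"))
  expect_equal(
    tab$relative_abundance[tab$prey_id == "SMARCA4"][order(
      tab$bait_id[tab$prey_id == "SMARCA4"])], c(1, 0.5))
  expect_equal(tab$relative_abundance[tab$prey_id == "ARID1A"], 1)
  expect_false("SMARCC1" %in% tab$prey_id)
  expect_true(all(tab$relative_abundance > 0 & tab$relative_abundance <= 1))

  single <- dotplot_table(hcis[hcis$bait_id == "NFIA", ], c("SMARCA4", "ARID1A"))
  expect_true(all(single$relative_abundance == 1))
})
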