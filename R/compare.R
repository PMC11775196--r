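#' Exhaustive Venn partition of labelled sets
#'
#' Classifies every element of the union by its exact membership signature
#' and reports all `2^k - 1` regions, including empty ones.
#'
#' @param sets A named list of character vectors.
#' @return A tibble of class `ps_venn`: `region` (labels joined by `&`),
#'   `labels` (list of label vectors), `n`, `members` (list). Region counts
#'   sum to the union size.
#' @export
#' @examples
#' venn(list(A = c("x", "y"), B = c("y", "z")))
venn <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a fully named list")
  }
  labels <- names(sets)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  if (length(universe) == 0) {
    member <- matrix(logical(0), nrow = 0, ncol = length(labels))
  }
  sig <- apply(member, 1, function(row) {
    paste(labels[row], collapse = "&")
  })
  combos <- unlist(lapply(seq_along(labels), function(m) {
    utils::combn(labels, m, paste, collapse = "&")
  }))
  out <- tibble(
    region = combos,
    labels = purrr::map(combos, ~ strsplit(.x, "&", fixed = TRUE)[[1]]),
    members = purrr::map(combos, ~ sort(universe[sig == .x]))
  ) %>%
    mutate(n = lengths(.data$members)) %>%
    select("region", "labels", "n", "members")
  class(out) <- c("ps_venn", class(out))
  out
}

#' @export
tidy.ps_venn <- function(x, ...) {
  as_tibble(x) %>% select("region", "n")
}

#' Pearson correlation between two replicate runs
#'
#' Aligns the two runs on the union of their preys (missing preys count 0)
#' and returns the standard Pearson correlation of the count vectors.
#'
#' @param runs A `ps_runs` tibble.
#' @param run_a,run_b Run identifiers.
#' @return A single correlation coefficient.
#' @export
replicate_correlation <- function(runs, run_a, run_b) {
  sub <- runs %>%
    filter(.data$run_id %in% c(run_a, run_b), .data$count > 0) %>%
    as_tibble()
  if (!all(c(run_a, run_b) %in% run_metadata(runs)$run_id)) {
    abort("both runs must exist in the run table")
  }
  wide <- sub %>%
    tidyr::pivot_wider(id_cols = "prey_id", names_from = "run_id",
                       values_from = "count", values_fill = 0L)
  for (rid in setdiff(c(run_a, run_b), names(wide))) wide[[rid]] <- 0L
  if (nrow(wide) < 2) abort("need at least 2 preys in the union")
  cor(wide[[run_a]], wide[[run_b]], method = "pearson")
}

#' Differential interactome between two isoform baits
#'
#' Volcano-style comparison of two baits' spectral counts over the union of
#' detected preys: per prey, a Welch two-sample t-test on `log2(count + 1)`
#' across replicates, a fold change `log2((mean_short + 1)/(mean_full + 1))`
#' on the raw replicate means, and Benjamini-Hochberg adjustment over all
#' tested preys. Classes: `up` when `log2fc >= lfc_min` and
#' `p_adj < padj_max`; `down` when `log2fc <= -lfc_min` and
#' `p_adj < padj_max`; otherwise `ns`.
#'
#' @param runs A `ps_runs` tibble containing both baits.
#' @param bait_full,bait_short Bait identifiers (fold change is
#'   short-over-full).
#' @param lfc_min Absolute log2 fold-change threshold, default 1.
#' @param padj_max Adjusted-p threshold, default 0.5.
#' @details Both baits need at least two replicates. When the counts of a
#'   prey are constant across all replicates of both baits the t-test is
#'   undefined; such preys get p = 1 when the two means are equal and p = 0
#'   when they differ deterministically.
#' @return A tibble of class `ps_diff` with `prey_id`, `mean_full`,
#'   `mean_short`, `log2fc`, `p`, `p_adj`, `class`.
#' @export
differential_isoform <- function(runs, bait_full, bait_short,
                                 lfc_min = 1, padj_max = 0.5) {
  meta <- run_metadata(runs)
  runs_full <- meta$run_id[meta$bait_id == bait_full & !meta$is_control]
  runs_short <- meta$run_id[meta$bait_id == bait_short & !meta$is_control]
  if (length(runs_full) < 2 || length(runs_short) < 2) {
    abort("both baits need at least 2 replicates")
  }
  all_runs <- c(runs_full, runs_short)
  wide <- runs %>%
    filter(.data$run_id %in% all_runs, .data$count > 0,
           !(.data$prey_id %in% c(bait_full, bait_short))) %>%
    as_tibble() %>%
    tidyr::pivot_wider(id_cols = "prey_id", names_from = "run_id",
                       values_from = "count", values_fill = 0L)
  for (rid in setdiff(all_runs, names(wide))) wide[[rid]] <- 0L
  mf <- as.matrix(wide[, runs_full, drop = FALSE])
  ms <- as.matrix(wide[, runs_short, drop = FALSE])
  res <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    xf <- log2(mf[i, ] + 1)
    xs <- log2(ms[i, ] + 1)
    p <- tryCatch(t.test(xs, xf)$p.value, error = function(e) {
      if (isTRUE(all.equal(mean(xs), mean(xf)))) 1 else 0
    })
    tibble(
      prey_id = wide$prey_id[i],
      mean_full = mean(mf[i, ]), mean_short = mean(ms[i, ]),
      log2fc = log2((mean(ms[i, ]) + 1) / (mean(mf[i, ]) + 1)),
      p = p
    )
  })
  out <- res %>%
    mutate(
      p_adj = p.adjust(.data$p, method = "BH"),
      class = dplyr::case_when(
        .data$log2fc >= lfc_min & .data$p_adj < padj_max ~ "up",
        .data$log2fc <= -lfc_min & .data$p_adj < padj_max ~ "down",
        TRUE ~ "ns"
      )
    ) %>%
    arrange(.data$prey_id)
  attr(out, "lfc_min") <- lfc_min
  attr(out, "padj_max") <- padj_max
  attr(out, "baits") <- c(full = bait_full, short = bait_short)
  class(out) <- c("ps_diff", class(out))
  out
}

#' @export
glance.ps_diff <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_up = sum(x$class == "up"),
    n_down = sum(x$class == "down"),
    lfc_min = attr(x, "lfc_min"),
    padj_max = attr(x, "padj_max")
  )
}

#' Subcellular localization profile of an interactome
#'
#' MS-microscopy-style profiling: sums the annotation scores of an HCI list's
#' preys per compartment using a reference localization map, then scales the
#' profile so its maximum is 1.
#'
#' @param hci_preys Character vector of prey identifiers.
#' @param reference_map A tibble `prey_id`, `compartment`,
#'   `annotation_score`.
#' @return A tibble `compartment`, `raw_score`, `score` (max-normalized; all
#'   zero when no HCI is annotated).
#' @export
localization_profile <- function(hci_preys, reference_map) {
  reference_map <- as_tibble(reference_map)
  raw <- reference_map %>%
    filter(.data$prey_id %in% hci_preys) %>%
    group_by(.data$compartment) %>%
    summarise(raw_score = sum(.data$annotation_score), .groups = "drop")
  out <- reference_map %>%
    distinct(.data$compartment) %>%
    left_join(raw, by = "compartment") %>%
    mutate(raw_score = dplyr::coalesce(.data$raw_score, 0))
  mx <- max(out$raw_score)
  out %>%
    mutate(score = if (mx > 0) .data$raw_score / mx else 0) %>%
    arrange(desc(.data$score), .data$compartment)
}

#' Interaction-distance stability scores for one bait
#'
#' For a bait profiled by both AP-MS (stable complexes) and proximity
#' labeling (stable plus transient neighbours), computes per prey the mean
#' bait-normalized PSM in each assay — prey count divided by the bait's own
#' self-count in the same run, averaged over that assay's runs — and the
#' bounded stability score `s = nAPMS / (nAPMS + nBioID)`. Scores near 1
#' indicate stable (core-complex) interactions, near 0 proximal/transient
#' ones. Preys seen in only one assay are flagged `one_sided` and pinned to
#' 1 (AP-MS only) or 0 (BioID only).
#'
#' @param runs A `ps_runs` tibble with the bait present in both assays; the
#'   bait's self-PSM must be positive in every used run.
#' @param bait Bait identifier.
#' @param preys Optional character vector restricting the output (e.g. the
#'   bait's HCI preys).
#' @return A tibble `prey_id`, `n_apms`, `n_bioid`, `s`, `one_sided`.
#' @export
stability_scores <- function(runs, bait, preys = NULL) {
  meta <- run_metadata(runs) %>%
    filter(.data$bait_id == bait, !.data$is_control)
  if (!all(c("APMS", "BIOID") %in% meta$assay)) {
    abort("bait must be present in both AP-MS and BioID runs")
  }
  obs <- runs %>%
    filter(.data$run_id %in% meta$run_id, .data$count > 0) %>%
    as_tibble()
  self <- obs %>%
    filter(.data$prey_id == bait) %>%
    select("run_id", self_count = "count")
  if (!all(meta$run_id %in% self$run_id)) {
    abort("bait self-PSM must be > 0 in every run used")
  }
  norm <- obs %>%
    filter(.data$prey_id != bait) %>%
    left_join(self, by = "run_id") %>%
    mutate(norm_psm = .data$count / .data$self_count)
  wide <- norm %>%
    tidyr::pivot_wider(id_cols = "prey_id", names_from = "run_id",
                       values_from = "norm_psm", values_fill = 0)
  for (rid in setdiff(meta$run_id, names(wide))) wide[[rid]] <- 0
  apms_runs <- meta$run_id[meta$assay == "APMS"]
  bioid_runs <- meta$run_id[meta$assay == "BIOID"]
  out <- tibble(
    prey_id = wide$prey_id,
    n_apms = rowMeans(as.matrix(wide[, apms_runs, drop = FALSE])),
    n_bioid = rowMeans(as.matrix(wide[, bioid_runs, drop = FALSE]))
  ) %>%
    filter(.data$n_apms + .data$n_bioid > 0) %>%
    mutate(
      s = .data$n_apms / (.data$n_apms + .data$n_bioid),
      one_sided = .data$n_apms == 0 | .data$n_bioid == 0
    ) %>%
    arrange(.data$prey_id)
  if (!is.null(preys)) out <- out %>% filter(.data$prey_id %in% preys)
  out
}

#' Gained, lost and kept interactions between two labeling times
#'
#' Plain per-bait set algebra between two HCI lists: preys present at the
#' first time only (`lost`), at both (`kept`), or at the second only
#' (`gained`).
#'
#' @param hcis_t1,hcis_t2 Tibbles with `bait_id`, `prey_id`.
#' @return A tibble `bait_id`, `class`, `prey_id`.
#' @export
timepoint_shift <- function(hcis_t1, hcis_t2) {
  t1 <- as_tibble(hcis_t1) %>% distinct(.data$bait_id, .data$prey_id)
  t2 <- as_tibble(hcis_t2) %>% distinct(.data$bait_id, .data$prey_id)
  bind_rows(
    t1 %>% anti_join(t2, by = c("bait_id", "prey_id")) %>%
      mutate(class = "lost"),
    t1 %>% semi_join(t2, by = c("bait_id", "prey_id")) %>%
      mutate(class = "kept"),
    t2 %>% anti_join(t1, by = c("bait_id", "prey_id")) %>%
      mutate(class = "gained")
  ) %>%
    select("bait_id", "class", "prey_id") %>%
    arrange(.data$bait_id, .data$class, .data$prey_id)
}

#' Dot-plot input table for complex-membership views
#'
#' Prepares the long table a dot-plot renderer consumes: abundance is the
#' average spectral count, the score is the BFDR, and the dot size is the
#' prey's abundance relative to its maximum across baits. Restricted to the
#' preys of a supplied complex (e.g. SWI/SNF or Mediator subunits).
#'
#' @param hcis A tibble with `bait_id`, `prey_id`, `avg_spec`, `bfdr`.
#' @param complex_members Character vector of complex subunit gene symbols,
#'   or a gene-set tibble with a `gene` column.
#' @return A tibble `bait_id`, `prey_id`, `avg_spec`,
#'   `relative_abundance` (in (0, 1]), `bfdr`.
#' @export
dotplot_table <- function(hcis, complex_members) {
  if (is.data.frame(complex_members)) {
    complex_members <- complex_members$gene
  }
  as_tibble(hcis) %>%
    filter(toupper(.data$prey_id) %in% toupper(complex_members)) %>%
    group_by(.data$prey_id) %>%
    mutate(relative_abundance = .data$avg_spec / max(.data$avg_spec)) %>%
    ungroup() %>%
    select("bait_id", "prey_id", "avg_spec", "relative_abundance", "bfdr") %>%
    arrange(.data$prey_id, .data$bait_id)
}
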