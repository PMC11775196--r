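#' Score one bait-prey pair from replicate spectral counts
#'
#' Two-component Poisson posterior-odds model with equal priors: for each
#' replicate count x the interaction probability is
#' `p = f1(x) / (f0(x) + f1(x))` where `f0` is Poisson at the control mean
#' and `f1` is Poisson at the pair's own mean test count, clamped from below
#' by the control mean — only enrichment over control counts as evidence,
#' depletion does not. A pseudo-floor keeps `f0` proper when the prey was
#' never seen in controls.
#'
#' @param test_counts Numeric vector of replicate counts (non-empty).
#' @param control_mean Prey's mean count over all control runs.
#' @param pseudo_floor Lower bound on the Poisson means, default 0.1 PSM.
#' @return A list with `rep_probs` (one probability per replicate) and
#'   `avg_p`, their mean.
#' @export
#' @examples
#' score_pair(c(10, 12, 8), control_mean = 1)
score_pair <- function(test_counts, control_mean, pseudo_floor = 0.1) {
  if (length(test_counts) == 0) abort("`test_counts` must be non-empty")
  if (control_mean < 0) abort("`control_mean` must be >= 0")
  mu0 <- max(control_mean, pseudo_floor)
  mu1 <- max(mean(test_counts), mu0)
  lf0 <- stats::dpois(test_counts, mu0, log = TRUE)
  lf1 <- stats::dpois(test_counts, mu1, log = TRUE)
  p <- 1 / (1 + exp(lf0 - lf1))
  list(rep_probs = p, avg_p = mean(p))
}

#' Fill in the Bayesian FDR down a probability-ranked interaction list
#'
#' Records are ranked by averaged interaction probability, descending (ties
#' broken by higher mean spectral count, then lexicographic prey id, for
#' reproducibility); the BFDR at rank i is the cumulative mean of
#' `1 - avg_p` over ranks 1..i, then made monotone non-decreasing by a
#' cumulative maximum down the ranking.
#'
#' @param scored A tibble with columns `avg_p`, `avg_spec`, `prey_id`.
#' @return The tibble in ranked order with a `bfdr` column appended.
#' @export
#' @examples
#' compute_bfdr(tibble::tibble(
#'   prey_id = c("A", "B", "C", "D"), avg_spec = c(9, 8, 7, 2),
#'   avg_p = c(1, 0.95, 0.9, 0.5)
#' ))$bfdr  # 0, 0.025, 0.05, 0.1625
compute_bfdr <- function(scored) {
  scored <- as_tibble(scored)
  if (nrow(scored) == 0) {
    scored$bfdr <- double()
    return(scored)
  }
  scored %>%
    arrange(desc(.data$avg_p), desc(.data$avg_spec), .data$prey_id) %>%
    mutate(bfdr = cummax(cumsum(1 - .data$avg_p) / row_number()))
}

#' Score every bait-prey pair of a run table
#'
#' Groups test runs by (bait, assay, labeling time), scores each prey seen at
#' least once in that group against its control-library mean with
#' [score_pair()] (zeros filled for replicates where the prey was missed),
#' then computes the BFDR with [compute_bfdr()] independently within each
#' (assay, labeling time) stratum, pooling baits. The bait's own self rows
#' are excluded — bait abundance is bookkeeping, not an interaction.
#'
#' @param runs A `ps_runs` tibble.
#' @param controls A `ps_control_library` (from [build_control_library()] or
#'   built automatically from the table's own control runs when `NULL`).
#' @param pseudo_floor Passed to [score_pair()].
#' @return A tibble of class `ps_scored`: one row per (bait, prey, assay,
#'   time) with `avg_spec`, `n_rep`, `rep_probs` (list column), `avg_p`,
#'   `bfdr`.
#' @export
score_run_table <- function(runs, controls = NULL, pseudo_floor = 0.1) {
  meta <- run_metadata(runs)
  if (is.null(controls)) controls <- build_control_library(runs)
  test_meta <- meta %>% filter(!.data$is_control)
  if (nrow(test_meta) == 0) {
    out <- tibble(bait_id = character(), prey_id = character(),
                  assay = character(), labeling_time_h = double(),
                  avg_spec = double(), n_rep = integer(),
                  rep_probs = list(), avg_p = double(), bfdr = double())
    class(out) <- c("ps_scored", class(out))
    return(out)
  }
  groups <- test_meta %>%
    group_by(.data$bait_id, .data$assay, .data$labeling_time_h) %>%
    summarise(run_ids = list(.data$run_id), .groups = "drop")
  obs <- runs %>%
    filter(!.data$is_control, .data$count > 0,
           .data$prey_id != .data$bait_id) %>%
    as_tibble()
  scored <- purrr::pmap_dfr(groups, function(bait_id, assay,
                                             labeling_time_h, run_ids) {
    rows <- obs %>%
      filter(.data$run_id %in% run_ids, .data$bait_id == .env$bait_id,
             .data$assay == .env$assay,
             .data$labeling_time_h == .env$labeling_time_h)
    if (nrow(rows) == 0) return(NULL)
    n_rep <- length(run_ids)
    wide <- rows %>%
      tidyr::pivot_wider(id_cols = "prey_id", names_from = "run_id",
                         values_from = "count", values_fill = 0L)
    for (rid in setdiff(run_ids, names(wide))) wide[[rid]] <- 0L
    cmat <- as.matrix(wide[, run_ids, drop = FALSE])
    ctrl <- control_stats(controls, wide$prey_id)
    res <- purrr::map2(seq_len(nrow(wide)), ctrl$mean_count, function(i, mu0) {
      score_pair(cmat[i, ], mu0, pseudo_floor)
    })
    tibble(
      bait_id = bait_id, prey_id = wide$prey_id, assay = assay,
      labeling_time_h = labeling_time_h,
      avg_spec = rowMeans(cmat), n_rep = n_rep,
      rep_probs = purrr::map(res, "rep_probs"),
      avg_p = purrr::map_dbl(res, "avg_p")
    )
  })
  out <- scored %>%
    group_by(.data$assay, .data$labeling_time_h) %>%
    dplyr::group_modify(~ compute_bfdr(.x)) %>%
    ungroup() %>%
    select("bait_id", "prey_id", "assay", "labeling_time_h", "avg_spec",
           "n_rep", "rep_probs", "avg_p", "bfdr")
  class(out) <- c("ps_scored", class(out))
  out
}
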