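#' High-confidence-interaction filter configuration
#'
#' Thresholds of the HCI ledger. Boundary semantics follow the rules'
#' wording exactly: BFDR cuts are inclusive (<=), the contaminant-frequency
#' rule fires strictly above 20%, its spectral-count override requires
#' strictly more than `override_fold` times the library average, and the
#' minimum-count rule removes strictly below `min_avg_spec` (an average
#' spectral count of exactly three survives).
#'
#' @param bfdr_max_bioid BFDR cut for proximity-labeling records.
#' @param bfdr_max_apms BFDR cut for AP-MS records.
#' @param contaminant_freq_max Control-library detection frequency above
#'   which a prey is deemed a contaminant.
#' @param override_fold Fold over the library mean count that rescues a
#'   contaminant-flagged prey.
#' @param min_avg_spec Minimum average spectral count.
#' @param rescue_enabled Whether the cross-bait rescue rule runs.
#' @return A list of class `ps_filter_config`.
#' @export
filter_config <- function(bfdr_max_bioid = 0.01,
                          bfdr_max_apms = 0.05,
                          contaminant_freq_max = 0.20,
                          override_fold = 3,
                          min_avg_spec = 3,
                          rescue_enabled = TRUE) {
  cfg <- list(bfdr_max_bioid = bfdr_max_bioid, bfdr_max_apms = bfdr_max_apms,
              contaminant_freq_max = contaminant_freq_max,
              override_fold = override_fold, min_avg_spec = min_avg_spec,
              rescue_enabled = isTRUE(rescue_enabled))
  if (cfg$bfdr_max_bioid < 0 || cfg$bfdr_max_bioid > 1 ||
      cfg$bfdr_max_apms < 0 || cfg$bfdr_max_apms > 1 ||
      cfg$contaminant_freq_max < 0 || cfg$contaminant_freq_max > 1 ||
      cfg$override_fold < 0 || cfg$min_avg_spec < 0) {
    abort("filter thresholds out of range")
  }
  class(cfg) <- "ps_filter_config"
  cfg
}

#' Primary BFDR filter
#'
#' Flags records passing the assay-specific BFDR cut: `bfdr <= 0.01` for
#' BioID, `bfdr <= 0.05` for AP-MS (both inclusive).
#'
#' @param scored A `ps_scored` tibble (needs `bfdr`, `assay`).
#' @param config A [filter_config()].
#' @return The tibble with a logical `passed_primary` column.
#' @export
primary_bfdr_filter <- function(scored, config = filter_config()) {
  as_tibble(scored) %>%
    mutate(passed_primary = if_else(
      .data$assay == "BIOID",
      .data$bfdr <= config$bfdr_max_bioid,
      .data$bfdr <= config$bfdr_max_apms
    ))
}

#' Cross-bait rescue
#'
#' In proximity-labeling data, a (bait, prey) record that fails the primary
#' BFDR cut is rescued when the same prey passed the cut with any other bait
#' in the same (assay, labeling time) stratum — provided the failing bait
#' actually detected the prey (`avg_spec > 0`); absence cannot be rescued.
#' The rule is restricted to BioID records and never crosses time points.
#'
#' @param records Output of [primary_bfdr_filter()].
#' @param config A [filter_config()]; `rescue_enabled = FALSE` disables the
#'   rule (all `rescued = FALSE`).
#' @return The tibble with a logical `rescued` column
#'   (`rescued` implies `!passed_primary`).
#' @export
rescue_across_baits <- function(records, config = filter_config()) {
  records <- as_tibble(records)
  if (!config$rescue_enabled || nrow(records) == 0) {
    records$rescued <- rep(FALSE, nrow(records))
    return(records)
  }
  passed <- records %>%
    filter(.data$passed_primary, .data$assay == "BIOID") %>%
    select("assay", "labeling_time_h", "prey_id", passer = "bait_id")
  records %>%
    left_join(
      passed %>%
        group_by(.data$assay, .data$labeling_time_h, .data$prey_id) %>%
        summarise(passers = list(unique(.data$passer)), .groups = "drop"),
      by = c("assay", "labeling_time_h", "prey_id")
    ) %>%
    mutate(rescued = !.data$passed_primary &
             .data$assay == "BIOID" &
             .data$avg_spec > 0 &
             purrr::map2_lgl(.data$passers, .data$bait_id,
                             ~ !is.null(.x) && any(.x != .y))) %>%
    select(-"passers")
}

#' Contaminant-frequency filter with spectral-count override
#'
#' Preys detected in more than `contaminant_freq_max` of the control-library
#' runs are deemed contaminants and removed, unless the record's average
#' spectral count exceeds `override_fold` times the prey's library mean count
#' (mean over all control runs, zeros included), in which case the record is
#' kept and flagged `contaminant_overridden`.
#'
#' @param records A scored/flagged tibble with `prey_id`, `avg_spec`.
#' @param library A `ps_control_library`.
#' @param config A [filter_config()].
#' @return The tibble with `contaminant_flagged`, `contaminant_overridden`,
#'   and `removed_contaminant` logical columns.
#' @export
contaminant_filter <- function(records, library, config = filter_config()) {
  records <- as_tibble(records)
  ctrl <- control_stats(library, records$prey_id)
  records %>%
    mutate(
      contaminant_flagged =
        ctrl$detection_frequency > config$contaminant_freq_max,
      contaminant_overridden = .data$contaminant_flagged &
        .data$avg_spec > config$override_fold * ctrl$mean_count,
      removed_contaminant = .data$contaminant_flagged &
        !.data$contaminant_overridden
    )
}

#' Minimum average-spectral-count filter
#'
#' Removes records with an average spectral count strictly below
#' `min_avg_spec`; a count of exactly the threshold survives.
#'
#' @inheritParams contaminant_filter
#' @return The tibble with a logical `removed_min_count` column.
#' @export
min_count_filter <- function(records, config = filter_config()) {
  as_tibble(records) %>%
    mutate(removed_min_count = .data$avg_spec < config$min_avg_spec)
}

#' Call high-confidence interactions
#'
#' Runs the full HCI ledger in order: primary BFDR filter, cross-bait rescue,
#' contaminant-frequency filter with override, minimum-count filter. Every
#' record ends in exactly one terminal state, recorded in the audit table:
#' `none` (an HCI), `bfdr`, `contaminant`, or `min_count`.
#'
#' @param scored A `ps_scored` tibble from [score_run_table()].
#' @param library A `ps_control_library`.
#' @param config A [filter_config()].
#' @return An object of class `ps_hci`: list with `hci` (surviving records),
#'   `audit` (every record with flags and `removed_reason`), and `config`.
#'   [tidy()] returns the audit table, [glance()] a one-row summary.
#' @export
call_hcis <- function(scored, library, config = filter_config()) {
  audit <- scored %>%
    primary_bfdr_filter(config) %>%
    rescue_across_baits(config) %>%
    contaminant_filter(library, config) %>%
    min_count_filter(config) %>%
    mutate(removed_reason = dplyr::case_when(
      !.data$passed_primary & !.data$rescued ~ "bfdr",
      .data$removed_contaminant ~ "contaminant",
      .data$removed_min_count ~ "min_count",
      TRUE ~ "none"
    ))
  hci <- audit %>% filter(.data$removed_reason == "none")
  out <- list(hci = hci, audit = audit, config = config)
  class(out) <- "ps_hci"
  out
}

#' @export
tidy.ps_hci <- function(x, ...) as_tibble(x$audit)

#' @export
glance.ps_hci <- function(x, ...) {
  tibble(
    n_scored = nrow(x$audit),
    n_hci = nrow(x$hci),
    n_rescued = sum(x$hci$rescued),
    n_overridden = sum(x$hci$contaminant_overridden),
    n_removed_bfdr = sum(x$audit$removed_reason == "bfdr"),
    n_removed_contaminant = sum(x$audit$removed_reason == "contaminant"),
    n_removed_min_count = sum(x$audit$removed_reason == "min_count")
  )
}

#' @export
print.ps_hci <- function(x, ...) {
  cat("<ps_hci> ", nrow(x$hci), " HCIs from ", nrow(x$audit),
      " scored records\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Pooled validation percentage
#'
#' Aggregates per-bait validation counts (e.g. dot-blot confirmations of
#' predicted interactions) into one overall percentage:
#' `100 * sum(validated) / sum(tested)`.
#'
#' @param counts A data frame with columns `n_validated` and `n_tested`.
#' @return A single percentage.
#' @export
#' @examples
#' validation_summary(tibble::tibble(
#'   n_validated = c(16, 15, 11, 12), n_tested = rep(16, 4)
#' ))  # 84.375
validation_summary <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$n_validated > counts$n_tested)) {
    abort("cannot validate more interactions than tested")
  }
  if (sum(counts$n_tested) == 0) abort("no tested interactions")
  100 * sum(counts$n_validated) / sum(counts$n_tested)
}

#' Known/novel bookkeeping against a reference interaction list
#'
#' Labels each HCI as known when its (bait, prey) gene pair appears in the
#' reference in either direction (symbols compared upper-cased), and
#' tabulates known, novel and total per bait, assay and labeling time.
#' `known + novel = total` holds by construction.
#'
#' @param hcis A tibble of HCIs (`bait_id`, `prey_id`, `assay`,
#'   `labeling_time_h`), e.g. `call_hcis(...)$hci`.
#' @param reference A tibble `bait_gene`, `prey_gene` from
#'   [read_reference_interactions()].
#' @return A tibble with `bait_id`, `assay`, `labeling_time_h`, `known`,
#'   `novel`, `total`.
#' @export
summarize_known_novel <- function(hcis, reference) {
  hcis <- as_tibble(hcis)
  key <- function(a, b) paste(toupper(a), toupper(b), sep = "\r")
  ref_keys <- c(key(reference$bait_gene, reference$prey_gene),
                key(reference$prey_gene, reference$bait_gene))
  hcis %>%
    mutate(known = key(.data$bait_id, .data$prey_id) %in% ref_keys) %>%
    group_by(.data$bait_id, .data$assay, .data$labeling_time_h) %>%
    summarise(total = dplyr::n(), known = sum(.data$known),
              .groups = "drop") %>%
    mutate(novel = .data$total - .data$known) %>%
    select("bait_id", "assay", "labeling_time_h", "known", "novel", "total")
}
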