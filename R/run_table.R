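#' Assemble and validate a run table
#'
#' The run table is the universal input of the pipeline: one row per observed
#' (run, prey) spectral count, with the run metadata carried alongside. Pairs
#' absent from the table are implicitly zero.
#'
#' @param counts A data frame with columns `run_id`, `prey_id`, `count`
#'   (non-negative integer PSM counts).
#' @param runs A data frame with one row per run and columns `run_id`,
#'   `bait_id`, `assay` (`"APMS"` or `"BIOID"`), `labeling_time_h`,
#'   `cell_line`, `replicate` (>= 1), `is_control`.
#'
#' @details Invariants enforced: `run_id` unique in `runs`; every count row
#'   references a declared run; all counts are non-negative integers;
#'   replicates are positive integers. A control run whose bait label is also
#'   used by a non-control run triggers a warning, since control baits
#'   (GFP-style pulldowns) are expected to be dedicated.
#'
#' @return A tibble of class `ps_runs`: the count rows joined to their run
#'   metadata, columns `run_id`, `bait_id`, `assay`, `labeling_time_h`,
#'   `cell_line`, `replicate`, `is_control`, `prey_id`, `count`.
#' @export
#' @examples
#' runs <- tibble::tibble(
#'   run_id = c("r1", "r2"), bait_id = "NFIA", assay = "BIOID",
#'   labeling_time_h = 16, cell_line = "HEK293", replicate = 1:2,
#'   is_control = FALSE
#' )
#' counts <- tibble::tibble(
#'   run_id = c("r1", "r1", "r2"),
#'   prey_id = c("SMARCA4", "MED1", "SMARCA4"), count = c(12L, 5L, 9L)
#' )
#' run_table(counts, runs)
run_table <- function(counts, runs) {
  runs <- as_tibble(runs)
  counts <- as_tibble(counts)
  req_runs <- c("run_id", "bait_id", "assay", "labeling_time_h",
                "cell_line", "replicate", "is_control")
  missing_cols <- setdiff(req_runs, names(runs))
  if (length(missing_cols) > 0) {
    abort(paste0("`runs` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(runs$run_id)) {
    dup <- unique(runs$run_id[duplicated(runs$run_id)])
    abort(paste0("duplicate run_id in `runs`: ", paste(dup, collapse = ", ")))
  }
  if (!all(runs$assay %in% c("APMS", "BIOID"))) {
    abort("`assay` must be \"APMS\" or \"BIOID\"")
  }
  if (any(runs$replicate < 1 | runs$replicate != as.integer(runs$replicate))) {
    abort("`replicate` must be a positive integer")
  }
  if (any(is.na(runs$labeling_time_h)) || any(runs$labeling_time_h < 0)) {
    abort("`labeling_time_h` must be non-negative (0 allowed for AP-MS)")
  }
  missing_run <- setdiff(counts$run_id, runs$run_id)
  if (length(missing_run) > 0) {
    abort(paste0("counts reference undeclared run_id: ",
                 paste(missing_run, collapse = ", ")))
  }
  bad <- which(is.na(counts$count) | counts$count < 0 |
                 counts$count != floor(counts$count))
  if (length(bad) > 0) {
    abort(paste0("counts must be non-negative integers; offending row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  ctrl_baits <- unique(runs$bait_id[runs$is_control])
  test_baits <- unique(runs$bait_id[!runs$is_control])
  shared <- intersect(ctrl_baits, test_baits)
  if (length(shared) > 0) {
    warn(paste0("control run(s) share a bait label with test runs: ",
                paste(shared, collapse = ", ")))
  }
  out <- counts %>%
    mutate(count = as.integer(.data$count)) %>%
    left_join(runs, by = "run_id") %>%
    select(all_of(req_runs), "prey_id", "count")
  class(out) <- c("ps_runs", class(out))
  out
}

#' Extract the per-run metadata from a run table
#'
#' @param x A `ps_runs` tibble from [run_table()] or a reader.
#' @return One row per run with the metadata columns.
#' @export
run_metadata <- function(x) {
  x %>%
    select("run_id", "bait_id", "assay", "labeling_time_h",
           "cell_line", "replicate", "is_control") %>%
    distinct() %>%
    as_tibble()
}

#' Build a contaminant control library from control runs
#'
#' Summarises the negative-control (GFP-style) runs of a run table into a
#' per-prey frequency/abundance reference, the in-house analogue of a
#' CRAPome-style contaminant catalogue.
#'
#' @param x A `ps_runs` tibble containing at least one run with
#'   `is_control = TRUE`.
#' @details `detection_frequency` is the fraction of control runs in which the
#'   prey was seen with a count above zero. `mean_count` is the prey's mean
#'   spectral count over ALL control runs, zeros included, so a prey seen once
#'   at 12 PSM across 6 controls has mean 2.
#' @return A tibble of class `ps_control_library` with columns `prey_id`,
#'   `detection_frequency`, `mean_count`, and attribute `n_control_runs`.
#' @export
build_control_library <- function(x) {
  meta <- run_metadata(x)
  ctrl_runs <- meta$run_id[meta$is_control]
  if (length(ctrl_runs) == 0) {
    abort("no control runs (`is_control = TRUE`) in the run table")
  }
  n_ctrl <- length(ctrl_runs)
  lib <- x %>%
    filter(.data$run_id %in% ctrl_runs, .data$count > 0) %>%
    group_by(.data$prey_id) %>%
    summarise(
      detection_frequency = dplyr::n_distinct(.data$run_id) / n_ctrl,
      mean_count = sum(.data$count) / n_ctrl,
      .groups = "drop"
    ) %>%
    arrange(.data$prey_id)
  attr(lib, "n_control_runs") <- n_ctrl
  class(lib) <- c("ps_control_library", class(lib))
  lib
}

#' Look up control-library statistics for a prey
#'
#' Preys absent from the library have frequency 0 and mean count 0.
#'
#' @param library A `ps_control_library` tibble.
#' @param prey_ids Character vector of prey identifiers.
#' @return A tibble with `prey_id`, `detection_frequency`, `mean_count`.
#' @export
control_stats <- function(library, prey_ids) {
  tibble(prey_id = prey_ids) %>%
    left_join(as_tibble(library), by = "prey_id") %>%
    mutate(
      detection_frequency = dplyr::coalesce(.data$detection_frequency, 0),
      mean_count = dplyr::coalesce(.data$mean_count, 0)
    )
}
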