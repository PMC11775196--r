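# Internal: derive a per-stage seed from the master seed by stable string
# hashing, so stages are decoupled and toggling one never shifts another's
# stream. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Assembles and validates the nested configuration of an end-to-end run.
#' Unknown keys anywhere in the structure are rejected before any stage runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-stage seeds are derived by stable hashing of
#'   the stage name.
#' @param sim A [sim_config()] for the interactome simulation.
#' @param filter A [filter_config()].
#' @param stages Named logical list toggling `simulate`, `score`, `filter`,
#'   `compare`, `chip`, `enrich`.
#' @param chip Named list of peak-simulation settings passed to
#'   [simulate_peaks()] (e.g. `n_peaks`, `frac_shared`, `genome_lengths`).
#' @param gene_sets Optional path to a GMT file; required when the `enrich`
#'   stage is on (the targetome is enriched against it).
#' @param top_n Top-peak count for targetome construction.
#' @return A validated list of class `ps_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = sim_config(),
                            filter = filter_config(),
                            stages = list(),
                            chip = list(),
                            gene_sets = NULL,
                            top_n = 50) {
  stage_defaults <- list(simulate = TRUE, score = TRUE, filter = TRUE,
                         compare = TRUE, chip = TRUE, enrich = FALSE)
  unknown <- setdiff(names(stages), names(stage_defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown stage toggle(s): ", paste(unknown, collapse = ", ")))
  }
  stage_defaults[names(stages)] <- stages
  chip_defaults <- list(n_baits = sim$n_baits,
                        genome_lengths = c(chr1 = 200000L, chr2 = 200000L),
                        n_peaks = 100, frac_shared = 0.5, peak_width = 200L)
  unknown <- setdiff(names(chip), names(chip_defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown chip setting(s): ", paste(unknown, collapse = ", ")))
  }
  chip_defaults[names(chip)] <- chip
  if (isTRUE(stage_defaults$enrich) && is.null(gene_sets)) {
    abort("the enrich stage needs a `gene_sets` GMT path")
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              filter = filter, stages = stage_defaults, chip = chip_defaults,
              gene_sets = gene_sets, top_n = top_n)
  stopifnot(inherits(sim, "ps_sim_config"), inherits(filter, "ps_filter_config"))
  class(cfg) <- "ps_pipeline_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate, score, filter, compare, chip and (optionally) enrich
#' in dependency order, writing every product as tab-separated text under
#' `config$out_dir`, and returns a machine-readable manifest: per stage, the
#' parameters used and the MD5 checksum of every output file. Re-running
#' with an identical configuration and seed reproduces identical checksums.
#' Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list, also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ps_pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  record <- function(stage, params, files) {
    sums <- as.list(tools::md5sum(unlist(files)))
    names(sums) <- basename(names(sums))
    manifest$stages[[stage]] <<- list(parameters = params,
                                      outputs = sums, status = "ok")
  }
  run_stage <- function(stage, fn) {
    if (!isTRUE(config$stages[[stage]])) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage `", stage, "` failed: ",
                   conditionMessage(e)))
    })
  }
  path <- function(...) file.path(config$out_dir, ...)

  run_stage("simulate", function() {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    state$sim <- simulate_interactome(sim_cfg)
    write_run_table(state$sim$runs, path("runs.tsv"))
    readr::write_tsv(as_tibble(state$sim$control_library),
                     path("controls.tsv"), progress = FALSE)
    readr::write_tsv(state$sim$truth$true_pairs, path("truth_pairs.tsv"),
                     progress = FALSE)
    record("simulate", unclass(sim_cfg),
           path(c("runs.tsv", "controls.tsv", "truth_pairs.tsv")))
  })

  run_stage("score", function() {
    if (is.null(state$sim)) abort("score requires the simulate stage")
    state$scored <- score_run_table(state$sim$runs,
                                    state$sim$control_library)
    readr::write_tsv(as_tibble(state$scored) %>% select(-"rep_probs"),
                     path("scored.tsv"), progress = FALSE)
    record("score", list(pseudo_floor = 0.1), path("scored.tsv"))
  })

  run_stage("filter", function() {
    if (is.null(state$scored)) abort("filter requires the score stage")
    state$hci <- call_hcis(state$scored, state$sim$control_library,
                           config$filter)
    readr::write_tsv(as_tibble(state$hci$hci) %>% select(-"rep_probs"),
                     path("hci.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(state$hci$audit) %>% select(-"rep_probs"),
                     path("audit.tsv"), progress = FALSE)
    record("filter", unclass(config$filter), path(c("hci.tsv", "audit.tsv")))
  })

  run_stage("compare", function() {
    if (is.null(state$hci)) abort("compare requires the filter stage")
    hci <- state$hci$hci
    times <- sort(unique(hci$labeling_time_h))
    venn_tabs <- purrr::map_dfr(times, function(tt) {
      sets <- hci %>%
        filter(.data$labeling_time_h == tt) %>%
        group_by(.data$bait_id) %>%
        summarise(preys = list(.data$prey_id), .groups = "drop")
      tidy(venn(setNames(sets$preys, sets$bait_id))) %>%
        mutate(labeling_time_h = tt)
    })
    readr::write_tsv(venn_tabs, path("venn.tsv"), progress = FALSE)
    files <- path("venn.tsv")
    if (length(times) == 2) {
      shift <- timepoint_shift(
        hci %>% filter(.data$labeling_time_h == times[1]),
        hci %>% filter(.data$labeling_time_h == times[2])
      )
      readr::write_tsv(shift, path("timepoint_shift.tsv"), progress = FALSE)
      files <- c(files, path("timepoint_shift.tsv"))
    }
    record("compare", list(times = times), files)
  })

  run_stage("chip", function() {
    ch <- config$chip
    sim_peaks <- simulate_peaks(
      n_baits = ch$n_baits, genome_lengths = ch$genome_lengths,
      n_peaks = ch$n_peaks, frac_shared = ch$frac_shared,
      seed = stage_seed(config$seed, "chip"), peak_width = ch$peak_width
    )
    state$peaks <- sim_peaks
    ov <- overlap_peaks(sim_peaks$peaks)
    readr::write_tsv(ov$regions, path("peak_overlap.tsv"), progress = FALSE)
    genes <- toy_gene_model(sim_peaks)
    targets <- purrr::imap_dfr(sim_peaks$peaks, function(p, lab) {
      tibble(bait_id = lab, gene_id = top_targets(p, genes, config$top_n))
    })
    readr::write_tsv(targets, path("targets.tsv"), progress = FALSE)
    state$targets <- targets
    hits <- scan_motif(sim_peaks$genome)
    readr::write_tsv(as_tibble(hits), path("motif_hits.tsv"),
                     progress = FALSE)
    record("chip", ch[c("n_baits", "n_peaks", "frac_shared")],
           path(c("peak_overlap.tsv", "targets.tsv", "motif_hits.tsv")))
  })

  run_stage("enrich", function() {
    if (is.null(state$targets)) abort("enrich requires the chip stage")
    sets <- read_gene_sets(config$gene_sets)
    res <- enrich(unique(state$targets$gene_id), sets)
    readr::write_tsv(as_tibble(res), path("enrichment.tsv"),
                     progress = FALSE)
    record("enrich", list(gmt = config$gene_sets), path("enrichment.tsv"))
  })

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Toy gene model for a simulated peak landscape
#'
#' Deterministically derives a gene-model table from a [simulate_peaks()]
#' result: one gene per distinct planted peak, its TSS at the peak start, so
#' nearest-TSS annotation has a well-defined answer on synthetic data.
#'
#' @param sim_peaks A `ps_sim_peaks` object.
#' @return A gene model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
toy_gene_model <- function(sim_peaks) {
  all_peaks <- bind_rows(sim_peaks$peaks) %>%
    distinct(.data$chrom, .data$start, .data$name)
  tibble(
    gene_id = paste0("GENE_", all_peaks$name),
    chrom = all_peaks$chrom,
    tss = all_peaks$start,
    strand = "+"
  ) %>% arrange(.data$gene_id)
}
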