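#' Simulation configuration for synthetic interactome data
#'
#' Bundles the parameters of the spectral-count generator. Defaults describe a
#' four-bait proximity-labeling screen in biological triplicate with a
#' GFP-style control series, two biotinylation times, negative-binomial
#' (overdispersed) counts, and a frequency-structured contaminant background.
#'
#' @param n_baits Number of baits (default 4, one per NFI family member).
#' @param n_preys Size of the detectable prey space.
#' @param n_true_per_bait Planted true interactors per bait at the short
#'   labeling time.
#' @param frac_shared_true Fraction of each bait's true preys drawn from a
#'   family-shared core (interacting with all baits).
#' @param n_replicates Biological replicates per bait and time.
#' @param n_control_runs Negative-control (GFP) runs.
#' @param signal_mean Mean PSM count of a true bait-prey pair (lambda1).
#' @param background_mean Mean PSM count of a background pair (lambda0).
#' @param contaminant_fraction Fraction of preys that are sticky contaminants.
#' @param contaminant_frequency Probability a contaminant is detected in any
#'   given control run (its control-library frequency in expectation).
#' @param contaminant_mean Mean PSM of a contaminant when detected.
#' @param bait_self_mean Named numeric, mean bait self-PSM per labeling time
#'   (hours as names). Bait abundance drops at the long time as labeling
#'   disperses over a broader proteome.
#' @param time_effect Multiplier (> 1) on the number of true interactors at
#'   the longest labeling time: prolonged labeling captures a broader,
#'   more transient neighborhood.
#' @param dispersion Negative-binomial size parameter; counts approach
#'   Poisson as it grows. Spectral counts are overdispersed, default 2.
#' @param labeling_times_h Labeling times in hours (two by default).
#' @param assay `"BIOID"` or `"APMS"`.
#' @param cell_line Cell line label stamped on the runs.
#' @param seed Integer seed fixing the whole stream.
#' @return A validated list of class `ps_sim_config`.
#' @export
sim_config <- function(n_baits = 4,
                       n_preys = 200,
                       n_true_per_bait = 30,
                       frac_shared_true = 0.25,
                       n_replicates = 3,
                       n_control_runs = 6,
                       signal_mean = 50,
                       background_mean = 0.5,
                       contaminant_fraction = 0.05,
                       contaminant_frequency = 0.5,
                       contaminant_mean = 6,
                       bait_self_mean = c("3" = 200, "16" = 100),
                       time_effect = 1.2,
                       dispersion = 2,
                       labeling_times_h = c(3, 16),
                       assay = "BIOID",
                       cell_line = "HEK293",
                       seed = 1L) {
  cfg <- list(
    n_baits = n_baits, n_preys = n_preys, n_true_per_bait = n_true_per_bait,
    frac_shared_true = frac_shared_true, n_replicates = n_replicates,
    n_control_runs = n_control_runs, signal_mean = signal_mean,
    background_mean = background_mean,
    contaminant_fraction = contaminant_fraction,
    contaminant_frequency = contaminant_frequency,
    contaminant_mean = contaminant_mean,
    bait_self_mean = bait_self_mean, time_effect = time_effect,
    dispersion = dispersion, labeling_times_h = labeling_times_h,
    assay = assay, cell_line = cell_line, seed = as.integer(seed)
  )
  if (signal_mean <= 0 || background_mean <= 0 || contaminant_mean <= 0 ||
      any(bait_self_mean <= 0)) {
    abort("all means must be > 0")
  }
  for (f in c("frac_shared_true", "contaminant_fraction",
              "contaminant_frequency")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must be in [0,1]"))
  }
  if (n_replicates < 1 || n_control_runs < 1) {
    abort("need at least one replicate and one control run")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (!all(as.character(labeling_times_h) %in% names(bait_self_mean))) {
    abort("`bait_self_mean` must name every labeling time")
  }
  class(cfg) <- "ps_sim_config"
  cfg
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# NB draw with mean mu and size parameter; vectorised over mu.
rnb <- function(n, mu, size) rnbinom(n, mu = mu, size = size)

#' Simulate a multi-bait spectral-count screen with ground truth
#'
#' Generates a run table with planted true interactions, frequency-structured
#' contaminants and negative-binomial background, plus the control library
#' built from its own simulated GFP runs and the exhaustive ground truth.
#'
#' True pairs draw counts at `signal_mean`, everything else at
#' `background_mean`. Contaminant preys follow one sticky process in every
#' run, test or control, regardless of bait: present with probability
#' `contaminant_frequency` at `contaminant_mean` — the frequency filter, not
#' the score, is what should remove them, since their test abundance matches
#' their control-library average. At the longest labeling time each bait's true set expands by
#' `time_effect` while the bait's own PSM drops per `bait_self_mean`,
#' mirroring how proximity labeling broadens with exposure.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ps_sim`: `runs` (a `ps_runs` tibble),
#'   `control_library`, and `truth` with `true_pairs`
#'   (bait_id, prey_id, labeling_time_h) and `contaminant_preys`.
#' @export
simulate_interactome <- function(config = sim_config()) {
  stopifnot(inherits(config, "ps_sim_config"))
  with_seed(config$seed, {
    preys <- sprintf("PREY%04d", seq_len(config$n_preys))
    baits <- sprintf("BAIT%02d", seq_len(config$n_baits))
    n_contam <- round(config$contaminant_fraction * config$n_preys)
    contam <- sample(preys, n_contam)
    clean <- setdiff(preys, contam)

    n_shared <- round(config$frac_shared_true * config$n_true_per_bait)
    shared_core <- sample(clean, n_shared)
    pool <- setdiff(clean, shared_core)
    t_long <- max(config$labeling_times_h)
    n_long_extra <- round(config$n_true_per_bait * (config$time_effect - 1))
    true_pairs <- purrr::map_dfr(baits, function(b) {
      uniq <- sample(pool, config$n_true_per_bait - n_shared + n_long_extra)
      base <- c(shared_core, uniq[seq_len(config$n_true_per_bait - n_shared)])
      purrr::map_dfr(config$labeling_times_h, function(tt) {
        members <- if (tt == t_long && length(config$labeling_times_h) > 1) {
          c(base, setdiff(uniq, base))
        } else {
          base
        }
        tibble(bait_id = b, prey_id = members, labeling_time_h = tt)
      })
    })

    rows <- list()
    run_meta <- list()
    for (tt in config$labeling_times_h) {
      for (b in baits) {
        true_set <- true_pairs$prey_id[true_pairs$bait_id == b &
                                         true_pairs$labeling_time_h == tt]
        for (r in seq_len(config$n_replicates)) {
          rid <- sprintf("%s_t%g_rep%d", b, tt, r)
          run_meta[[rid]] <- tibble(
            run_id = rid, bait_id = b, assay = config$assay,
            labeling_time_h = if (config$assay == "APMS") 0 else tt,
            cell_line = config$cell_line, replicate = r, is_control = FALSE
          )
          mu <- rep(config$background_mean, config$n_preys)
          mu[preys %in% true_set] <- config$signal_mean
          cnt <- rnb(config$n_preys, mu, config$dispersion)
          # contaminants follow the same sticky process in every run,
          # bait-independent: present with prob f_c at contaminant_mean
          hit <- preys %in% contam & !(preys %in% true_set) &
            rbinom(config$n_preys, 1, config$contaminant_frequency) == 1
          cnt[hit] <- pmax(rnb(sum(hit), config$contaminant_mean,
                               config$dispersion), 1L)
          self <- rnb(1, config$bait_self_mean[[as.character(tt)]],
                      config$dispersion)
          rows[[rid]] <- tibble(
            run_id = rid,
            prey_id = c(preys, b),
            count = as.integer(c(cnt, max(self, 1L)))
          )
        }
      }
      if (config$assay == "APMS") break
    }
    t0 <- config$labeling_times_h[1]
    for (r in seq_len(config$n_control_runs)) {
      rid <- sprintf("GFP_rep%d", r)
      run_meta[[rid]] <- tibble(
        run_id = rid, bait_id = "GFP", assay = config$assay,
        labeling_time_h = if (config$assay == "APMS") 0 else t0,
        cell_line = config$cell_line, replicate = r, is_control = TRUE
      )
      cnt <- rnb(config$n_preys, config$background_mean, config$dispersion)
      hit <- preys %in% contam & rbinom(config$n_preys, 1,
                                        config$contaminant_frequency) == 1
      cnt[hit] <- pmax(rnb(sum(hit), config$contaminant_mean,
                           config$dispersion), 1L)
      rows[[rid]] <- tibble(run_id = rid, prey_id = preys,
                            count = as.integer(cnt))
    }
    counts <- bind_rows(rows) %>% filter(.data$count > 0)
    runs <- run_table(counts, bind_rows(run_meta))
    out <- list(
      runs = runs,
      control_library = build_control_library(runs),
      truth = list(true_pairs = true_pairs,
                   contaminant_preys = sort(contam))
    )
    class(out) <- "ps_sim"
    out
  })
}

#' Simulate per-bait ChIP-seq peak sets over a toy genome
#'
#' Places non-overlapping peaks on a random genome, a configurable fraction of
#' which sit at coordinates shared by every bait; each peak gets one planted
#' NFI-style motif `TTGGC-N(k)-GCCAA` with spacer length drawn from
#' `motif_spacer_distribution`, and a uniform peak score.
#'
#' @param n_baits Number of peak sets.
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @param n_peaks Peaks per bait.
#' @param frac_shared Fraction of peaks at identical coordinates in all sets.
#' @param motif_spacer_distribution Named probability vector over spacer
#'   lengths; the canonical spacer is 5 nt, with rarer shorter/longer
#'   variants.
#' @param seed Integer seed.
#' @param peak_width Width of every peak in bases.
#' @return A list of class `ps_sim_peaks`: `peaks` (named list of peak
#'   tibbles), `genome` (named character vector of sequences), `truth` with
#'   `planted_motif_sites` (chrom, pos, spacer_len, strand) and
#'   `shared_peaks`.
#' @export
simulate_peaks <- function(n_baits = 4,
                           genome_lengths = c(chr1 = 200000L, chr2 = 200000L),
                           n_peaks = 100,
                           frac_shared = 0.5,
                           motif_spacer_distribution =
                             c("3" = 0.05, "4" = 0.1, "5" = 0.7,
                               "6" = 0.1, "7" = 0.05),
                           seed = 1L,
                           peak_width = 200L) {
  if (frac_shared < 0 || frac_shared > 1) abort("`frac_shared` must be in [0,1]")
  with_seed(seed, {
    n_shared <- round(frac_shared * n_peaks)
    n_unique <- n_peaks - n_shared
    n_distinct_peaks <- n_shared + n_baits * n_unique
    slots_per_chrom <- floor(genome_lengths / peak_width)
    if (sum(slots_per_chrom) < n_distinct_peaks) {
      abort("genome too short for the requested number of peaks")
    }
    genome <- vapply(genome_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))

    slot_chrom <- rep(names(genome_lengths), slots_per_chrom)
    slot_start <- unlist(lapply(slots_per_chrom,
                                function(k) (seq_len(k) - 1L) * peak_width),
                         use.names = FALSE)
    pick <- sample(length(slot_chrom), n_distinct_peaks)
    spacers <- as.integer(sample(names(motif_spacer_distribution),
                                 n_distinct_peaks, replace = TRUE,
                                 prob = motif_spacer_distribution))
    all_peaks <- tibble(
      chrom = slot_chrom[pick],
      start = as.integer(slot_start[pick]),
      end = as.integer(slot_start[pick] + peak_width),
      name = sprintf("peak%04d", seq_len(n_distinct_peaks)),
      score = round(runif(n_distinct_peaks, 1, 1000), 2),
      spacer_len = spacers
    )
    # plant one motif at the centre of each distinct peak
    motif_pos <- integer(n_distinct_peaks)
    for (i in seq_len(n_distinct_peaks)) {
      k <- all_peaks$spacer_len[i]
      len <- 10L + k
      pos <- all_peaks$start[i] + (peak_width - len) %/% 2L
      spacer <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                      collapse = "")
      motif <- paste0("TTGGC", spacer, "GCCAA")
      chrom <- all_peaks$chrom[i]
      substr(genome[[chrom]], pos + 1L, pos + len) <- motif
      motif_pos[i] <- pos
    }
    planted <- tibble(
      chrom = all_peaks$chrom, pos = motif_pos,
      spacer_len = all_peaks$spacer_len, strand = "+"
    )
    shared_idx <- seq_len(n_shared)
    peaksets <- setNames(lapply(seq_len(n_baits), function(b) {
      own <- n_shared + (b - 1L) * n_unique + seq_len(n_unique)
      all_peaks[c(shared_idx, if (n_unique > 0) own), ] %>%
        select(-"spacer_len") %>%
        arrange(.data$chrom, .data$start)
    }), sprintf("BAIT%02d", seq_len(n_baits)))
    out <- list(
      peaks = peaksets, genome = genome,
      truth = list(planted_motif_sites = planted,
                   shared_peaks = all_peaks$name[shared_idx])
    )
    class(out) <- "ps_sim_peaks"
    out
  })
}

#' Simulate a full-length vs short-isoform bait pair
#'
#' Two baits (`ISO_FL`, `ISO_SHORT`) over a common prey space at equal mean
#' `signal_mean`, except `n_diff_up` preys whose mean is multiplied by
#' `2^effect_log2fc` in the short isoform and `n_diff_down` preys divided by
#' it — the planted signal the isoform volcano analysis should recover.
#'
#' @param config A [sim_config()]; `n_preys`, `n_replicates`, `signal_mean`,
#'   `dispersion`, `cell_line` are used.
#' @param n_diff_up,n_diff_down Number of planted differential preys.
#' @param effect_log2fc Planted effect size in log2 units.
#' @param seed Integer seed.
#' @return A list of class `ps_sim_iso`: `runs` and `truth` with `up_preys`
#'   and `down_preys`.
#' @export
simulate_isoform_pair <- function(config = sim_config(),
                                  n_diff_up = 30,
                                  n_diff_down = 30,
                                  effect_log2fc = 3,
                                  seed = 1L) {
  if (n_diff_up + n_diff_down > config$n_preys) {
    abort("more differential preys than preys")
  }
  with_seed(seed, {
    preys <- sprintf("PREY%04d", seq_len(config$n_preys))
    diff <- sample(preys, n_diff_up + n_diff_down)
    up <- sort(diff[seq_len(n_diff_up)])
    down <- sort(setdiff(diff, up))
    fc <- 2^effect_log2fc
    mu_fl <- rep(config$signal_mean, config$n_preys)
    mu_short <- mu_fl
    mu_short[preys %in% up] <- config$signal_mean * fc
    mu_short[preys %in% down] <- config$signal_mean / fc
    rows <- list()
    meta <- list()
    for (b in c("ISO_FL", "ISO_SHORT")) {
      mu <- if (b == "ISO_FL") mu_fl else mu_short
      for (r in seq_len(config$n_replicates)) {
        rid <- sprintf("%s_rep%d", b, r)
        meta[[rid]] <- tibble(
          run_id = rid, bait_id = b, assay = "BIOID", labeling_time_h = 16,
          cell_line = config$cell_line, replicate = r, is_control = FALSE
        )
        rows[[rid]] <- tibble(
          run_id = rid, prey_id = preys,
          count = as.integer(rnb(config$n_preys, mu, config$dispersion))
        )
      }
    }
    runs <- run_table(bind_rows(rows) %>% filter(.data$count > 0),
                      bind_rows(meta))
    out <- list(runs = runs, truth = list(up_preys = up, down_preys = down))
    class(out) <- "ps_sim_iso"
    out
  })
}
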