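#' Read a spectral-count run table
#'
#' Two dialects are supported. `"long_tsv"` is the package's native format:
#' a header-ed TSV with one row per (run, prey) count and the full run
#' metadata on every row. `"saint_triplet"` is the three-file layout consumed
#' by SAINT-style scorers: a directory containing `interaction.txt`
#' (run, bait, prey, count; no header), `bait.txt` (run, bait, T/C) and
#' `prey.txt` (prey, one line each); the triplet carries no assay, labeling
#' time or cell line, so those default to `BIOID`, 0 h and `NA`, and
#' replicates are numbered by order of appearance within each bait.
#'
#' @param path File (long TSV) or directory (SAINT triplet).
#' @param dialect `"long_tsv"` or `"saint_triplet"`.
#' @return A validated `ps_runs` tibble (see [run_table()]).
#' @export
read_run_table <- function(path, dialect = c("long_tsv", "saint_triplet")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("run_id", "bait_id", "assay", "labeling_time_h", "cell_line",
             "replicate", "is_control", "prey_id", "count")
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("run table is missing columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    runs <- df %>%
      select("run_id", "bait_id", "assay", "labeling_time_h", "cell_line",
             "replicate", "is_control") %>%
      distinct()
    if (anyDuplicated(runs$run_id)) {
      dup <- unique(runs$run_id[duplicated(runs$run_id)])
      abort(paste0("duplicate run_id with conflicting metadata: ",
                   paste(dup, collapse = ", ")))
    }
    counts <- df %>% select("run_id", "prey_id", "count")
    return(run_table(counts, runs))
  }
  inter_path <- file.path(path, "interaction.txt")
  bait_path <- file.path(path, "bait.txt")
  for (p in c(inter_path, bait_path)) {
    if (!file.exists(p)) abort(paste0("missing SAINT triplet file: ", p))
  }
  inter <- readr::read_tsv(inter_path,
                           col_names = c("run_id", "bait_id", "prey_id", "count"),
                           col_types = "ccci", progress = FALSE)
  baits <- readr::read_tsv(bait_path,
                           col_names = c("run_id", "bait_id", "tc"),
                           col_types = "ccc", progress = FALSE)
  runs <- baits %>%
    mutate(
      assay = "BIOID", labeling_time_h = 0, cell_line = NA_character_,
      is_control = .data$tc == "C"
    ) %>%
    group_by(.data$bait_id) %>%
    mutate(replicate = row_number()) %>%
    ungroup() %>%
    select("run_id", "bait_id", "assay", "labeling_time_h", "cell_line",
           "replicate", "is_control")
  run_table(inter %>% select("run_id", "prey_id", "count"), runs)
}

#' Write a run table
#'
#' `long_tsv` emits the native single-file format; `saint_triplet` writes
#' `interaction.txt`, `bait.txt` and `prey.txt` into the directory `path`.
#' All writers emit tab-separated text with `\n` line endings and no row
#' index, so canonical data round-trips byte-identically.
#'
#' @param x A `ps_runs` tibble.
#' @param path Output file (long TSV) or directory (SAINT triplet).
#' @param dialect `"long_tsv"` or `"saint_triplet"`.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(x, path, dialect = c("long_tsv", "saint_triplet")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_tsv") {
    readr::write_tsv(as_tibble(x), path, progress = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- run_metadata(x)
  readr::write_tsv(
    x %>% select("run_id", "bait_id", "prey_id", "count") %>% as_tibble(),
    file.path(path, "interaction.txt"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(
    meta %>%
      mutate(tc = if_else(.data$is_control, "C", "T")) %>%
      select("run_id", "bait_id", "tc"),
    file.path(path, "bait.txt"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(
    tibble(prey_id = sort(unique(x$prey_id))),
    file.path(path, "prey.txt"), col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED coordinates are 0-based half-open and are kept that way internally.
#' Column 4 is the peak name and column 5 the score when present.
#'
#' @param path Path to a BED3/BED5 file (no header).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`
#'   (`name` `NA` and `score` 0 when absent from the file).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    abort(paste0("BED line with fewer than 3 columns: line ",
                 which(ncol < 3)[1]))
  }
  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  start_chr <- get_col(2)
  end_chr <- get_col(3)
  if (any(!grepl("^-?[0-9]+$", start_chr)) || any(!grepl("^-?[0-9]+$", end_chr))) {
    abort("non-integer coordinate in BED file")
  }
  out <- tibble(
    chrom = get_col(1),
    start = as.integer(start_chr),
    end = as.integer(end_chr),
    name = get_col(4),
    score = suppressWarnings(as.double(get_col(5)))
  )
  out$score[is.na(out$score)] <- 0
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad) > 0) {
    abort(paste0("invalid interval (need 0 <= start < end) at line ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out
}

#' @rdname read_bed
#' @param x A tibble of intervals (`chrom`, `start`, `end`, optionally
#'   `name`, `score`).
#' @export
write_bed <- function(x, path) {
  x <- as_tibble(x)
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort("intervals need `chrom`, `start`, `end`")
  }
  name <- if ("name" %in% names(x)) x$name else rep(NA_character_, nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  name[is.na(name)] <- "."
  lines <- paste(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                 format(x$end, scientific = FALSE, trim = TRUE),
                 name, format(score, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @details Intervals must not overlap within a chromosome (the format is a
#'   step function); overlap is a hard error. Uncovered gaps mean value 0.
#' @return A tibble `chrom`, `start`, `end`, `value`, sorted by coordinate.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    abort("bedGraph line with fewer than 4 columns")
  }
  m <- vapply(fields, function(f) f[1:4], character(4))
  if (any(!grepl("^-?[0-9]+$", m[2, ])) || any(!grepl("^-?[0-9]+$", m[3, ]))) {
    abort("non-integer coordinate in bedGraph")
  }
  out <- tibble(
    chrom = m[1, ], start = as.integer(m[2, ]), end = as.integer(m[3, ]),
    value = as.double(m[4, ])
  ) %>% arrange(.data$chrom, .data$start)
  if (any(out$start < 0 | out$start >= out$end)) {
    abort("invalid interval (need 0 <= start < end) in bedGraph")
  }
  overlap <- out %>%
    group_by(.data$chrom) %>%
    summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]),
              .groups = "drop")
  if (any(overlap$bad, na.rm = TRUE)) {
    abort("overlapping intervals within a chromosome in bedGraph")
  }
  out
}

#' @rdname read_bedgraph
#' @param x A coverage tibble (`chrom`, `start`, `end`, `value`).
#' @export
write_bedgraph <- function(x, path) {
  lines <- paste(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                 format(x$end, scientific = FALSE, trim = TRUE),
                 format(x$value, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a reference interaction list
#'
#' Two-column TSV of known bait-gene / prey-gene pairs (IntAct-style export).
#' Gene symbols are upper-cased so human (NFIA) and mouse (Nfia) casings join;
#' duplicate rows collapse. Pairs are stored directed (bait, prey) but the
#' known/novel lookup in [summarize_known_novel()] checks both directions,
#' since database pairs are undirected while bait/prey roles are experimental.
#'
#' @param path TSV with columns bait gene, prey gene (header optional,
#'   detected by the literal header `bait_gene\tprey_gene`).
#' @return A tibble `bait_gene`, `prey_gene`, unique rows, upper-cased.
#' @export
read_reference_interactions <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && identical(lines[1], "bait_gene\tprey_gene")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    return(tibble(bait_gene = character(), prey_gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    abort("reference interaction line with fewer than 2 columns")
  }
  tibble(
    bait_gene = toupper(vapply(fields, `[`, character(1), 1)),
    prey_gene = toupper(vapply(fields, `[`, character(1), 2))
  ) %>% distinct()
}

#' Read gene sets in GMT format
#'
#' GMT: one term per line — term, description, then member genes, all
#' tab-separated. Genes are upper-cased for joining.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble `term`, `description`, `gene` (unique per term).
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(term = character(), description = character(),
                  gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort("GMT line needs at least term, description and one gene")
  }
  purrr::map_dfr(fields, function(f) {
    tibble(term = f[1], description = f[2],
           gene = unique(toupper(f[-(1:2)])))
  })
}

#' @rdname read_gene_sets
#' @param x A long gene-set tibble (`term`, `description`, `gene`).
#' @export
write_gene_sets <- function(x, path) {
  lines <- x %>%
    group_by(.data$term) %>%
    summarise(line = paste(c(.data$term[1], .data$description[1],
                             .data$gene), collapse = "\t"),
              .groups = "drop") %>%
    pull("line")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a gene model table
#'
#' Plain TSV of TSS records used for nearest-TSS peak annotation: columns
#' `gene_id`, `chrom`, `tss` (0-based), `strand` (`+`/`-`), with header.
#'
#' @param path Path to the TSV.
#' @return A tibble with the four columns, `gene_id` unique.
#' @export
read_gene_model <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(df))) {
    abort(paste0("gene model needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) abort("duplicate gene_id in gene model")
  if (any(df$tss < 0)) abort("tss must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be + or -")
  as_tibble(df[req])
}
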