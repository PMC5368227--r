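`%||%` <- function(a, b) if (is.null(a)) b else a

# write a file atomically: build in a sibling temp file, then rename
.atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.config_to_scoring <- function(cfg_list) {
  scoring_config(
    three_prime_len = cfg_list$three_prime_len %||% 5L,
    w_non3p_mm = cfg_list$w_non3p_mm %||% 0.40,
    w_3p_mm = cfg_list$w_3p_mm %||% 1.00,
    w_non3p_gap = cfg_list$w_non3p_gap %||% 1.00,
    w_3p_gap = cfg_list$w_3p_gap %||% 3.00,
    terminal_penalty = cfg_list$terminal_penalty %||% 3.00,
    hit_threshold = cfg_list$threshold %||% 1.0,
    max_gaps = cfg_list$max_gaps %||% 2L,
    truncated_policy = cfg_list$truncated_policy %||% "exclude"
  )
}

.taxa_from_config <- function(lst) {
  dplyr::bind_rows(lapply(lst, function(tx) {
    # YAML 1.1 parses a bare `n` key as logical, hence the n_records alias
    n <- tx$n_records %||% tx$n
    if (is.null(n)) stop("each taxon needs n_records", call. = FALSE)
    taxa_spec(
      taxon = tx$taxon,
      n = n,
      defect = tx$defect %||% "none",
      defect_frac = tx$defect_frac %||% 0,
      defect_primer = tx$defect_primer %||% NA_character_,
      deletion_len = tx$deletion_len %||% 0L
    )
  }))
}

#' Run a full primer-evaluation workflow from a config
#'
#' End-to-end driver: loads primers and a reference set (a real
#' SILVA-style FASTA or a synthetic specification), scores every primer
#' against every record, builds per-taxon coverage tables for each primer
#' pair, rank and method, predicts amplicons and their length distribution,
#' and writes the report bundle (`hits.tsv`, `coverage.tsv`,
#' `amplicon_lengths.tsv`, `summary.txt`, `report.json`) to `out_dir`.
#' Percentages are formatted to 2 decimals in the TSVs and kept at full
#' precision in the JSON, which also embeds run metadata (config hash, seed,
#' package version, record counts). All files are written atomically and the
#' output is byte-identical for a fixed config and seed.
#'
#' @param config Path to a YAML config, or an equivalent nested list. Keys:
#'   `primers` (`"default"` or a file path), `pairs` (list of
#'   `[forward, reverse]` name pairs; default: all pairs of the primer
#'   table), `reference` (either `fasta:`/`taxonomy:` paths or a
#'   `synthetic:` block with `taxa:` and `seed:`), `ranks`, `method`
#'   (`"weighted"`, `"tp"` or `"both"`), `threshold`, `three_prime_len`,
#'   `max_gaps`.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional integer overriding the config's synthetic seed.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with the result tables (`hits`, `coverage`,
#'   `amplicons`, `lengths`), the `records`, optional synthetic `truth`, and
#'   the written `paths`.
#' @export
run_evaluation <- function(config, out_dir, seed = NULL, verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  primer_src <- config$primers %||% "default"
  primers <- if (identical(primer_src, "default")) default_primers() else
    read_primers(primer_src)
  if (nrow(primers) == 0L) stop("no primers defined", call. = FALSE)

  pairs <- if (is.null(config$pairs)) {
    pp <- primer_pairs(primers)
    lapply(seq_len(nrow(pp)), function(i) c(pp$forward[i], pp$reverse[i]))
  } else {
    lapply(config$pairs, unlist)
  }
  if (length(pairs) == 0L) stop("no primers defined", call. = FALSE)
  used_names <- unique(unlist(pairs))
  missing <- setdiff(used_names, primers$name)
  if (length(missing)) {
    stop("pair references unknown primer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  used_primers <- primers[match(used_names, primers$name), , drop = FALSE]

  cfg <- .config_to_scoring(config)
  ranks <- unlist(config$ranks %||% c("domain", "phylum"))
  methods <- switch(config$method %||% "both",
                    both = c("weighted", "tp"),
                    weighted = "weighted",
                    tp = "tp",
                    stop("method must be weighted, tp or both", call. = FALSE))

  truth <- NULL
  syn <- config$reference$synthetic
  if (!is.null(syn)) {
    use_seed <- seed %||% syn$seed
    if (is.null(use_seed)) stop("synthetic reference requires a seed", call. = FALSE)
    ref <- simulate_reference_set(
      taxa = .taxa_from_config(syn$taxa),
      primers = used_primers,
      seed = as.integer(use_seed),
      length_range = as.integer(unlist(syn$length_range %||% c(1200L, 1600L))),
      config = cfg,
      deletion_start = as.integer(syn$deletion_start %||% 454L)
    )
    records <- ref$records
    truth <- ref$truth
  } else if (!is.null(config$reference$fasta)) {
    tax <- if (!is.null(config$reference$taxonomy)) {
      read_taxonomy_tsv(config$reference$taxonomy)
    }
    records <- read_silva_fasta(config$reference$fasta, taxonomy = tax)
  } else {
    stop("config must name a reference: either reference$fasta or ",
         "reference$synthetic", call. = FALSE)
  }

  hits <- score_primers(records, used_primers, cfg, verbose = verbose)

  cov_rows <- list()
  for (pair in pairs) {
    for (rank in ranks) {
      for (method in methods) {
        cfg_m <- cfg
        cfg_m$method <- method
        cov_rows[[length(cov_rows) + 1L]] <-
          coverage_by_taxon(hits, records, rank, cfg_m, pair = pair)
      }
    }
  }
  coverage <- dplyr::bind_rows(cov_rows)

  amp_rows <- list()
  len_rows <- list()
  for (pair in pairs) {
    amp <- extract_amplicons(records, .get_primer(used_primers, pair[1]),
                             .get_primer(used_primers, pair[2]),
                             cfg, hits = hits)
    pair_name <- paste0(pair[1], "/", pair[2])
    if (nrow(amp) > 0L) {
      amp_rows[[pair_name]] <- dplyr::mutate(tibble::as_tibble(amp),
                                             pair = pair_name)
      len_rows[[pair_name]] <- dplyr::mutate(
        tibble::as_tibble(length_distribution(amp, group_by = "phylum")),
        pair = pair_name)
    }
  }
  amplicons <- dplyr::bind_rows(amp_rows)
  lengths <- dplyr::bind_rows(len_rows)

  paths <- c(hits = file.path(out_dir, "hits.tsv"),
             coverage = file.path(out_dir, "coverage.tsv"),
             lengths = file.path(out_dir, "amplicon_lengths.tsv"),
             summary = file.path(out_dir, "summary.txt"),
             report = file.path(out_dir, "report.json"))

  .atomic_write(paths[["hits"]], function(p) {
    utils::write.table(hits, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  cov_tsv <- coverage
  for (col in c("coverage_pct", "non_coverage_pct", "last_base_mm_pct")) {
    cov_tsv[[col]] <- sprintf("%.2f", cov_tsv[[col]])
  }
  .atomic_write(paths[["coverage"]], function(p) {
    utils::write.table(cov_tsv, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  .atomic_write(paths[["lengths"]], function(p) {
    utils::write.table(lengths, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  domain_rank <- ranks[1]
  ranking <- coverage |>
    dplyr::filter(.data$rank == domain_rank,
                  .data$method == methods[1],
                  .data$taxon != "Unclassified") |>
    dplyr::group_by(.data$primer_or_pair) |>
    dplyr::summarise(
      coverage_pct = 100 * sum(.data$n_hit) / sum(.data$n_total),
      n_total = sum(.data$n_total),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$coverage_pct))
  .atomic_write(paths[["summary"]], function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(
      "primerscout evaluation summary",
      sprintf("records: %d (skipped: %d)", nrow(records),
              attr(hits, "n_skipped") %||% 0L),
      sprintf("method: %s   threshold: %g", methods[1], cfg$hit_threshold),
      "",
      sprintf("pair ranking by %s-level coverage (%s score):",
              domain_rank, methods[1]),
      sprintf("  %-12s %7.2f%%  (n=%d)", ranking$primer_or_pair,
              ranking$coverage_pct, ranking$n_total)
    ), con)
  })

  report <- list(
    metadata = list(
      package = "primerscout",
      version = as.character(utils::packageVersion("primerscout")),
      config_hash = rlang::hash(config),
      seed = seed %||% (config$reference$synthetic$seed %||% NA),
      n_records = nrow(records),
      n_skipped = attr(hits, "n_skipped") %||% 0L,
      n_truncated = sum(hits$truncated),
      methods = methods,
      ranks = ranks,
      threshold = cfg$hit_threshold
    ),
    pair_ranking = ranking,
    coverage = coverage,
    amplicon_lengths = lengths,
    truth = truth
  )
  .atomic_write(paths[["report"]], function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  })

  invisible(list(hits = hits, coverage = coverage, amplicons = amplicons,
                 lengths = lengths, records = records, truth = truth,
                 ranking = ranking, paths = paths))
}
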