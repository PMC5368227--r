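.DEFECT_TYPES <- c("none", "non3p_mismatch", "threep_mismatch",
                   "terminal_mismatch", "double_mismatch", "site_gap",
                   "deletion")

# run code with a private, seeded RNG stream; restores the caller's stream
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# primer-space positions used when planting defects
.defect_positions <- function(L, tpl) {
  non3p_len <- L - min(tpl, L)
  list(
    non3p = max(1L, as.integer(floor(non3p_len / 2))),
    threep = L - 1L,
    terminal = L
  )
}

# closed-form weighted/tp scores of each defect type under a config
.defect_scores <- function(defect, config) {
  w <- switch(defect,
    none = 0,
    non3p_mismatch = config$w_non3p_mm,
    threep_mismatch = config$w_3p_mm,
    terminal_mismatch = config$w_3p_mm + config$terminal_penalty,
    double_mismatch = config$w_non3p_mm + config$w_3p_mm,
    site_gap = config$w_non3p_gap,
    deletion = 0,
    stop("unknown defect type: ", defect, call. = FALSE)
  )
  tp <- switch(defect,
    none = 0, deletion = 0, double_mismatch = 2,
    1
  )
  list(weighted = w, tp = tp,
       terminal = identical(defect, "terminal_mismatch"))
}

# substitution base outside the primer's set at a position (A<C<G<T order)
.mismatch_base <- function(primer_code) {
  allowed <- IUPAC_CODES[[primer_code]]
  cand <- setdiff(c("A", "C", "G", "T"), allowed)
  if (length(cand) == 0L) {
    stop("cannot plant mismatch against N: primer position matches every base",
         call. = FALSE)
  }
  cand[1]
}

#' Plant a single defect into a planted primer site
#'
#' Mutates one template base of a known primer binding site: a `mismatch`
#' substitutes the base aligned to `primer_position` with a base outside the
#' primer's IUPAC set at that position (deterministically the first such base
#' in A<C<G<T order); a `gap` deletes that template base. Works for forward
#' and reverse primers (the mutation is applied in primer space and mapped
#' through the reverse complement for reverse primers).
#'
#' @param sequence Template sequence containing the site.
#' @param primer One-row primer tibble.
#' @param site_start 1-based plus-strand start of the planted site.
#' @param type `"mismatch"` or `"gap"`.
#' @param primer_position 1-based position within the primer (5' to 3').
#' @return The mutated sequence (one base shorter for a gap).
#' @export
plant_defect <- function(sequence, primer, site_start,
                         type = c("mismatch", "gap"), primer_position) {
  type <- match.arg(type)
  primer <- .primer_row(primer)
  L <- nchar(primer$sequence)
  if (primer_position < 1L || primer_position > L) {
    stop("defect position ", primer_position, " outside primer length ", L,
         call. = FALSE)
  }
  chars <- strsplit(clean_sequence(sequence), "", fixed = TRUE)[[1]]
  site_end <- site_start + L - 1L
  if (site_start < 1L || site_end > length(chars)) {
    stop("primer site does not fit the template at position ", site_start,
         call. = FALSE)
  }
  reverse <- identical(primer$orientation, "reverse")
  plus_pos <- if (reverse) site_end - primer_position + 1L else
    site_start + primer_position - 1L
  if (type == "mismatch") {
    p_code <- substr(primer$sequence, primer_position, primer_position)
    b <- .mismatch_base(p_code)
    chars[plus_pos] <- if (reverse) chartr("ACGT", "TGCA", b) else b
  } else {
    chars <- chars[-plus_pos]
  }
  paste(chars, collapse = "")
}

#' Specify the taxa of a synthetic reference set
#'
#' Helper building the per-taxon design table consumed by
#' [simulate_reference_set()]. Each taxon gets `n` records; a fraction
#' `defect_frac` of them (the first `round(defect_frac * n)` by index under
#' deterministic planting) carries the named primer-site defect.
#'
#' @param taxon Taxon names (used as the phylum in the generated taxonomy).
#' @param n Records per taxon.
#' @param defect One of `"none"`, `"non3p_mismatch"`, `"threep_mismatch"`,
#'   `"terminal_mismatch"`, `"double_mismatch"`, `"site_gap"`, `"deletion"`.
#' @param defect_frac Fraction of the taxon's records carrying the defect.
#' @param defect_primer Name of the primer whose site is damaged (`NA`: the
#'   first primer passed to the generator). Ignored for `"deletion"`.
#' @param deletion_len Length of the internal deletion between primer sites
#'   (defect `"deletion"` only).
#' @return Tibble with one row per taxon.
#' @export
taxa_spec <- function(taxon, n, defect = "none", defect_frac = 0,
                      defect_primer = NA_character_, deletion_len = 0L) {
  defect <- match.arg(defect, .DEFECT_TYPES, several.ok = TRUE)
  tibble::tibble(
    taxon = as.character(taxon),
    n = as.integer(n),
    defect = rep_len(defect, length(taxon)),
    defect_frac = rep_len(defect_frac, length(taxon)),
    defect_primer = rep_len(as.character(defect_primer), length(taxon)),
    deletion_len = rep_len(as.integer(deletion_len), length(taxon))
  )
}

#' Generate a synthetic taxonomy-annotated 16S-like reference set
#'
#' Builds `sum(taxa$n)` records: random A/C/G/T background of 16S-like
#' length, one concrete realisation of every primer's binding site planted
#' at its E. coli coordinates, and per-taxon defects planted into a quota of
#' records. Planting is deterministic (first `round(defect_frac * n)`
#' records by index, or Bernoulli draws when `stochastic = TRUE`), so the
#' returned truth manifest gives EXACT expected coverages in closed form. A
#' drawn background is rejected and redrawn unless every planted primer's
#' best alignment scores exactly the defect's closed-form score (with the
#' expected terminal-base flag), which rules out accidental binding sites
#' that would perturb the truth.
#'
#' @param taxa Design table from [taxa_spec()].
#' @param primers Primer tibble whose sites are planted (default: the
#'   341f/785r pair). All primers need `ecoli_start`/`ecoli_end`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param length_range Background length range in bases (16S-like default).
#' @param config The [scoring_config()] under which planted defects are
#'   scored (used for the rejection check and the truth manifest).
#' @param deletion_start Plus-strand start of internal deletions, E. coli
#'   numbering (default 454, within the region where many
#'   Alphaproteobacteria carry a length polymorphism).
#' @param stochastic Use Bernoulli instead of quota planting; the manifest
#'   then records the realised defect counts.
#' @param max_tries Redraw budget per record for the rejection check.
#' @return List of class `synthetic_reference`: `records` (tibble `id`,
#'   `sequence`, `taxonomy`, `defective`), `truth` (per taxon x pair x
#'   method expected coverage, plus expected amplicon length), `taxa`,
#'   `primers`, `seed`, `config`.
#' @export
simulate_reference_set <- function(taxa,
                                   primers = .pair_341f_785r(),
                                   seed,
                                   length_range = c(1200L, 1600L),
                                   config = scoring_config(),
                                   deletion_start = 454L,
                                   stochastic = FALSE,
                                   max_tries = 50L) {
  stopifnot(is.data.frame(taxa), !missing(seed))
  if (any(is.na(primers$ecoli_start) | is.na(primers$ecoli_end))) {
    stop("all planted primers need ecoli_start/ecoli_end", call. = FALSE)
  }
  if (length_range[1] < max(primers$ecoli_end)) {
    stop("length_range must cover the most 3' planted primer site (",
         max(primers$ecoli_end), " nt)", call. = FALSE)
  }
  taxa$defect_primer <- ifelse(
    is.na(taxa$defect_primer) & taxa$defect %in% c("none", "deletion"),
    primers$name[1], taxa$defect_primer)
  taxa$defect_primer[is.na(taxa$defect_primer)] <- primers$name[1]
  bad <- !taxa$defect_primer %in% primers$name
  if (any(bad)) {
    stop("defect_primer not among planted primers: ",
         paste(unique(taxa$defect_primer[bad]), collapse = ", "), call. = FALSE)
  }

  .with_seed(seed, {
    n_defect <- if (stochastic) {
      vapply(seq_len(nrow(taxa)),
             function(i) sum(stats::rbinom(taxa$n[i], 1L, taxa$defect_frac[i])),
             integer(1))
    } else {
      as.integer(round(taxa$defect_frac * taxa$n))
    }

    rec_rows <- vector("list", nrow(taxa))
    for (ti in seq_len(nrow(taxa))) {
      tx <- taxa[ti, ]
      rec_rows[[ti]] <- .simulate_taxon(tx, n_defect[ti], primers, length_range,
                                        config, deletion_start, max_tries)
    }
    records <- dplyr::bind_rows(rec_rows)

    truth <- .synthetic_truth(taxa, n_defect, primers, config, deletion_start)
    out <- list(records = records, truth = truth, taxa = taxa,
                n_defect = n_defect, primers = primers, seed = seed,
                config = config)
    class(out) <- "synthetic_reference"
    out
  })
}

.pair_341f_785r <- function() {
  p <- default_primers()
  p[p$name %in% c("341f", "785r"), , drop = FALSE]
}

.simulate_taxon <- function(tx, k_defect, primers, length_range, config,
                            deletion_start, max_tries) {
  taxonomy <- if (grepl(";", tx$taxon, fixed = TRUE)) tx$taxon else
    paste("Bacteria", tx$taxon, paste0("Class_", tx$taxon),
          paste0("Order_", tx$taxon), paste0("Family_", tx$taxon),
          paste0("Genus_", tx$taxon), sep = ";")
  slug <- gsub("[^A-Za-z0-9]", "", tx$taxon)
  rows <- vector("list", tx$n)
  for (i in seq_len(tx$n)) {
    defective <- i <= k_defect && tx$defect != "none"
    rows[[i]] <- tibble::tibble(
      id = sprintf("%s_%04d", slug, i),
      sequence = .simulate_record(tx, defective, primers, length_range,
                                  config, deletion_start, max_tries),
      taxonomy = taxonomy,
      defective = defective
    )
  }
  dplyr::bind_rows(rows)
}

.MISMATCH_DEFECTS <- c("non3p_mismatch", "threep_mismatch",
                       "terminal_mismatch", "double_mismatch", "site_gap")

.simulate_record <- function(tx, defective, primers, length_range, config,
                             deletion_start, max_tries, repair_max = 400L) {
  defect <- if (defective) tx$defect else "none"
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    len <- sample(length_range[1]:length_range[2], 1L)
    chars <- sample(bases, len, replace = TRUE)
    # plant one concrete realisation of every primer site
    for (k in seq_len(nrow(primers))) {
      prm <- primers[k, ]
      codes <- strsplit(prm$sequence, "", fixed = TRUE)[[1]]
      realization <- vapply(codes,
                            function(cc) {
                              b <- IUPAC_CODES[[cc]]
                              if (length(b) == 1L) b else sample(b, 1L)
                            }, character(1), USE.NAMES = FALSE)
      site <- if (identical(prm$orientation, "reverse")) {
        rev(chartr("ACGT", "TGCA", realization))
      } else {
        realization
      }
      chars[prm$ecoli_start:prm$ecoli_end] <- site
    }
    seq <- paste(chars, collapse = "")

    removed <- integer(0)  # plus-strand positions deleted from the template
    if (defect %in% .MISMATCH_DEFECTS) {
      prm <- .get_primer(primers, tx$defect_primer)
      L <- nchar(prm$sequence)
      pos <- .defect_positions(L, config$three_prime_len)
      reverse <- identical(prm$orientation, "reverse")
      plus_of <- function(p) if (reverse) prm$ecoli_end - p + 1L else
        prm$ecoli_start + p - 1L
      seq <- switch(defect,
        non3p_mismatch = plant_defect(seq, prm, prm$ecoli_start, "mismatch", pos$non3p),
        threep_mismatch = plant_defect(seq, prm, prm$ecoli_start, "mismatch", pos$threep),
        terminal_mismatch = plant_defect(seq, prm, prm$ecoli_start, "mismatch", pos$terminal),
        double_mismatch = plant_defect(
          plant_defect(seq, prm, prm$ecoli_start, "mismatch", pos$non3p),
          prm, prm$ecoli_start, "mismatch", pos$threep),
        site_gap = plant_defect(seq, prm, prm$ecoli_start, "gap", pos$non3p)
      )
      if (defect == "site_gap") removed <- plus_of(pos$non3p)
    } else if (defect == "deletion") {
      del <- deletion_start:(deletion_start + tx$deletion_len - 1L)
      for (k in seq_len(nrow(primers))) {
        if (any(del >= primers$ecoli_start[k] & del <= primers$ecoli_end[k])) {
          stop("internal deletion overlaps the planted site of primer ",
               primers$name[k], call. = FALSE)
        }
      }
      chars2 <- strsplit(seq, "", fixed = TRUE)[[1]]
      seq <- paste(chars2[-del], collapse = "")
      removed <- del
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]

    # effective site coordinates after any template deletions, the expected
    # closed-form score of each planted primer, and the protected positions
    n_prm <- nrow(primers)
    eff <- vector("list", n_prm)
    protected <- integer(0)
    for (k in seq_len(n_prm)) {
      prm <- primers[k, ]
      damaged <- defect %in% .MISMATCH_DEFECTS && prm$name == tx$defect_primer
      shift <- sum(removed < prm$ecoli_start)
      prm_eff <- prm
      prm_eff$ecoli_start <- prm$ecoli_start - shift
      prm_eff$ecoli_end <- prm$ecoli_end - shift -
        sum(removed >= prm$ecoli_start & removed <= prm$ecoli_end)
      eff[[k]] <- list(
        prm = prm_eff,
        expected = if (damaged) .defect_scores(defect, config) else
          list(weighted = 0, tp = 0, terminal = FALSE)
      )
      protected <- c(protected, prm_eff$ecoli_start:prm_eff$ecoli_end)
    }

    # bulk pre-pass: re-randomise every background window whose ungapped
    # score comes near the planted score, so the exact check below only has
    # to deal with rare gapped stragglers
    for (pass in 1:30) {
      changed <- FALSE
      t_plus <- match(chars, names(IUPAC_CODES))
      Tn <- length(t_plus)
      for (k in seq_len(n_prm)) {
        prm_eff <- eff[[k]]$prm
        p_codes <- .encode_seq(prm_eff$sequence)
        L <- length(p_codes)
        rev_p <- identical(prm_eff$orientation, "reverse")
        t_work <- if (rev_p) rev(.IUPAC_COMP_IDX[t_plus]) else t_plus
        sc <- .ungapped_scan(p_codes, t_work, config)
        if (length(sc) == 0L) next
        off <- which(sc < eff[[k]]$expected$weighted + 0.8 - 1e-9)
        if (length(off) == 0L) next
        pos <- unique(unlist(lapply(off, function(o) o:(o + L - 1L))))
        if (rev_p) pos <- Tn - pos + 1L
        mutable <- setdiff(pos, protected)
        if (length(mutable) > 0L) {
          chars[mutable] <- sample(bases, length(mutable), replace = TRUE)
          changed <- TRUE
        }
      }
      if (!changed) break
    }

    # exact repair loop: whenever some background window out-scores (or ties
    # in the wrong place with) the planted site, re-randomise its unprotected
    # bases and re-check, so the planted defect is provably the best site
    redraw <- FALSE
    for (it in seq_len(repair_max)) {
      ok <- TRUE
      for (k in seq_len(n_prm)) {
        prm_eff <- eff[[k]]$prm
        exp <- eff[[k]]$expected
        hit <- .align_encoded(prm_eff, .encode_seq(paste(chars, collapse = "")),
                              config, "chk")
        good <- !hit$truncated &&
          abs(hit$weighted_score - exp$weighted) < 1e-9 &&
          identical(hit$last_base_mismatch %in% TRUE, exp$terminal) &&
          hit$start == prm_eff$ecoli_start
        if (good) next
        ok <- FALSE
        if (hit$truncated) {
          redraw <- TRUE
          break
        }
        mutable <- setdiff(hit$start:hit$end, protected)
        if (length(mutable) == 0L) {
          redraw <- TRUE
          break
        }
        chars[mutable] <- sample(bases, length(mutable), replace = TRUE)
        break
      }
      if (ok) return(paste(chars, collapse = ""))
      if (redraw) break
    }
  }
  stop("failed to build a background without competing binding sites in ",
       max_tries, " attempts for taxon ", tx$taxon, call. = FALSE)
}

# per-taxon x pair x method expected coverage, in closed form
.synthetic_truth <- function(taxa, n_defect, primers, config, deletion_start) {
  pairs <- if ("pair" %in% names(primers)) primer_pairs(primers) else {
    tibble::tibble(
      pair = paste0(primers$name[primers$orientation == "forward"][1], "/",
                    primers$name[primers$orientation == "reverse"][1]),
      forward = primers$name[primers$orientation == "forward"][1],
      reverse = primers$name[primers$orientation == "reverse"][1]
    )
  }
  rows <- list()
  for (ti in seq_len(nrow(taxa))) {
    tx <- taxa[ti, ]
    k <- n_defect[ti]
    sc <- .defect_scores(tx$defect, config)
    for (pi in seq_len(nrow(pairs))) {
      pr <- pairs[pi, ]
      fwd <- .get_primer(primers, pr$forward)
      amp_len <- .get_primer(primers, pr$reverse)$ecoli_end - fwd$ecoli_start + 1L
      affected <- tx$defect_primer %in% c(pr$forward, pr$reverse) &&
        tx$defect %in% c("non3p_mismatch", "threep_mismatch",
                         "terminal_mismatch", "double_mismatch", "site_gap")
      del_inside <- tx$defect == "deletion" &&
        deletion_start > fwd$ecoli_end &&
        deletion_start + tx$deletion_len <= .get_primer(primers, pr$reverse)$ecoli_start
      for (method in c("weighted", "tp")) {
        defect_score <- if (affected) sc[[method]] else 0
        miss <- defect_score > config$hit_threshold
        cov <- 100 * (1 - (if (miss) k / tx$n else 0))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          taxon = tx$taxon,
          pair = pr$pair,
          method = method,
          n_records = tx$n,
          n_defective = k,
          defect = tx$defect,
          defect_primer = tx$defect_primer,
          defect_score = defect_score,
          expected_coverage_pct = cov,
          expected_non_coverage_pct = 100 - cov,
          expected_amplicon_length = amp_len -
            (if (del_inside) tx$deletion_len else 0L),
          expected_last_base_mm_pct = if (sc$terminal &&
                                          tx$defect_primer %in%
                                            c(pr$forward, pr$reverse)) {
            100 * k / tx$n
          } else {
            0
          }
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic reference set to disk
#'
#' Emits the three generator outputs: a SILVA-style FASTA, a two-column
#' taxonomy TSV, and the ground-truth manifest as JSON.
#'
#' @param x A `synthetic_reference` from [simulate_reference_set()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_reference_set <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "reference.fasta"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_reference_fasta(x$records, paths[["fasta"]])
  write_taxonomy_tsv(x$records, paths[["taxonomy"]])
  jsonlite::write_json(
    list(seed = x$seed,
         n_records = nrow(x$records),
         taxa = x$taxa,
         n_defect = x$n_defect,
         truth = x$truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
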