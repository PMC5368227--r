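# Brute-force binding-site oracle: enumerates every ungapped offset and
# every explicit placement of at most max_gaps indels (deletion = primer base
# unaligned, insertion = extra template base between two primer bases), and
# returns the minimum weighted score. Shares only the cost model with the
# package; the search is an independent explicit enumeration.

oracle_gap_placements <- function(L, G) {
  # deletions: subsets of primer positions 1..L-1 (terminal base always paired)
  del_sets <- list(integer(0))
  if (G >= 1 && L >= 2) {
    for (a in 1:(L - 1)) del_sets[[length(del_sets) + 1L]] <- a
  }
  if (G >= 2 && L >= 3) {
    cmb <- utils::combn(L - 1, 2)
    for (k in seq_len(ncol(cmb))) del_sets[[length(del_sets) + 1L]] <- cmb[, k]
  }
  # insertions: multisets of interior slots 1..L-1 (slot a = between a, a+1)
  ins_sets <- list(integer(0))
  if (G >= 1 && L >= 2) {
    for (a in 1:(L - 1)) ins_sets[[length(ins_sets) + 1L]] <- a
  }
  if (G >= 2 && L >= 2) {
    for (a in 1:(L - 1)) for (b in a:(L - 1)) {
      ins_sets[[length(ins_sets) + 1L]] <- c(a, b)
    }
  }
  out <- list()
  for (d in del_sets) for (ins in ins_sets) {
    if (length(d) + length(ins) <= G) out[[length(out) + 1L]] <- list(del = d, ins = ins)
  }
  out
}

oracle_best_score <- function(primer, template, config) {
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  t <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  L <- length(p)
  Tn <- length(t)
  tpl <- min(config$three_prime_len, L)
  is3p <- seq_len(L) > L - tpl
  mmw <- ifelse(is3p, config$w_3p_mm, config$w_non3p_mm)
  gapw <- ifelse(is3p, config$w_3p_gap, config$w_non3p_gap)
  placements <- oracle_gap_placements(L, config$max_gaps)
  best <- Inf
  for (pl in placements) {
    del <- pl$del
    ins_counts <- tabulate(pl$ins, nbins = L)
    win_len <- L - length(del) + length(pl$ins)
    if (win_len > Tn || win_len < 1L) next
    for (s in 1:(Tn - win_len + 1L)) {
      cost <- 0
      tp <- s
      for (i in seq_len(L)) {
        if (i %in% del) {
          cost <- cost + gapw[i]
        } else {
          if (!iupac_match(p[i], t[tp])) {
            cost <- cost + mmw[i] +
              if (i == L) config$terminal_penalty else 0
          }
          tp <- tp + 1L
        }
        if (i < L && ins_counts[i] > 0L) {
          cost <- cost + ins_counts[i] * gapw[i + 1L]  # classified by next base
          tp <- tp + ins_counts[i]
        }
      }
      if (cost < best) best <- cost
    }
  }
  best
}

# random IUPAC primer: mostly concrete bases with some ambiguity codes
random_primer <- function(len, p_ambig = 0.2) {
  concrete <- c("A", "C", "G", "T")
  ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  paste(ifelse(stats::runif(len) < p_ambig,
               sample(ambig, len, replace = TRUE),
               sample(concrete, len, replace = TRUE)),
        collapse = "")
}

random_template <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
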