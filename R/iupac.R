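#' IUPAC nucleotide codes
#'
#' The 15 IUPAC nucleotide ambiguity codes and the concrete bases each one
#' denotes. `N` denotes all four bases; `A`, `C`, `G`, `T` denote themselves.
#'
#' @format A named list: one character vector of concrete bases per code.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# complement partner for each code, same order as IUPAC_CODES
.IUPAC_FROM <- paste(names(IUPAC_CODES), collapse = "")
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

# complement index: position k of IUPAC_CODES -> index of its complement code
.IUPAC_COMP_IDX <- match(
  strsplit(.IUPAC_TO, "", fixed = TRUE)[[1]],
  names(IUPAC_CODES)
)

# match_matrix[p, t] == TRUE iff bases(t) is a subset of bases(p):
# a template position matches a primer position only when every base the
# template code could be is acceptable to the primer code.
.iupac_match_matrix <- local({
  n <- length(IUPAC_CODES)
  m <- matrix(FALSE, n, n, dimnames = list(names(IUPAC_CODES), names(IUPAC_CODES)))
  for (p in seq_len(n)) {
    for (t in seq_len(n)) {
      m[p, t] <- all(IUPAC_CODES[[t]] %in% IUPAC_CODES[[p]])
    }
  }
  m
})

#' Expand an IUPAC code to its concrete bases
#'
#' @param code A single IUPAC nucleotide character (case-insensitive;
#'   `U` is treated as `T`).
#' @return Character vector of concrete bases in `{A, C, G, T}`.
#' @examples
#' iupac_expand("N")
#' iupac_expand("W")
#' @export
iupac_expand <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  if (code == "U") code <- "T"
  if (!code %in% names(IUPAC_CODES)) {
    stop("invalid IUPAC nucleotide code '", code, "' at position 1", call. = FALSE)
  }
  IUPAC_CODES[[code]]
}

#' Does a template base satisfy a primer base?
#'
#' A template position matches a primer position iff the template code's base
#' set is contained in the primer code's base set. Consequently a concrete
#' template base matches iff the primer code includes it, and an ambiguous
#' template base (e.g. `N`) never matches a narrower primer code.
#'
#' @param primer_base,template_base Single IUPAC characters.
#' @return Logical scalar.
#' @examples
#' iupac_match("W", "A")  # TRUE:  A is in {A, T}
#' iupac_match("C", "T")  # FALSE: disjoint
#' iupac_match("R", "N")  # FALSE: {A,C,G,T} is not within {A,G}
#' @export
iupac_match <- function(primer_base, template_base) {
  p <- .iupac_code_index(primer_base)
  t <- .iupac_code_index(template_base)
  .iupac_match_matrix[p, t]
}

.iupac_code_index <- function(ch) {
  ch <- toupper(ch)
  if (ch == "U") ch <- "T"
  i <- match(ch, names(IUPAC_CODES))
  if (is.na(i)) {
    stop("invalid IUPAC nucleotide code '", ch, "' at position 1", call. = FALSE)
  }
  i
}

#' Normalise a nucleotide sequence
#'
#' Uppercases, converts RNA `U` to `T`, and validates the alphabet. Errors
#' name the first offending character and its position.
#'
#' @param seq Character scalar.
#' @return Uppercase IUPAC DNA string.
#' @export
clean_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", s)
  if (bad > 0L) {
    stop("invalid IUPAC nucleotide code '", substr(s, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  s
}

# encode a clean sequence as integer indices into IUPAC_CODES
.encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], names(IUPAC_CODES))
}

.decode_seq <- function(codes) {
  paste(names(IUPAC_CODES)[codes], collapse = "")
}

#' Degenerate-aware reverse complement
#'
#' Complements every IUPAC code (`R`/`Y`, `K`/`M`, `B`/`V`, `D`/`H` swap;
#' `S`, `W`, `N` are self-complementary) and reverses the string. Applying
#' the function twice returns the input.
#'
#' @param seq IUPAC DNA string (case-insensitive; `U` treated as `T`).
#' @return Reverse-complemented uppercase string.
#' @examples
#' reverse_complement("CCTACGGGNGGCWGCAG")
#' @export
reverse_complement <- function(seq) {
  s <- clean_sequence(seq)
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}
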