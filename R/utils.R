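## Shared low-level helpers: seeded streams, random sequences, point mutation,
## reverse complement. All user-visible coordinates in this package are
## 1-based and inclusive.

#' Derive a child seed from a master seed and a record index
#'
#' All generators draw one master seed from their config; records that may be
#' regenerated (decoys, loci) each get their own child stream so that
#' regeneration of record i never perturbs record j. The derivation is
#' `(master * 48271 + index * 16807) mod (2^31 - 1)`, kept below 2^31 so it is
#' a valid R integer seed.
#'
#' @param master integer master seed.
#' @param index  record index (1-based).
#' @return an integer seed.
#' @export
child_seed <- function(master, index) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(index) * 16807) %% m)
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Random protein sequence over the 20-letter alphabet
#' @param n length in residues.
#' @param exclude residues to leave out of the sampling alphabet.
#' @return a single string.
#' @export
random_protein <- function(n, exclude = character()) {
  ab <- setdiff(AA_ALPHABET, exclude)
  paste(sample(ab, n, replace = TRUE), collapse = "")
}

#' Random DNA sequence
#' @param n length in nucleotides.
#' @return a single string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Split a sequence string into a character vector of single letters
#' @keywords internal
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' @keywords internal
chars_seq <- function(chars) paste(chars, collapse = "")

#' Point-mutate a sequence at a fixed per-site rate
#'
#' Substitution-only (no indels); mutated sites receive a uniformly chosen
#' different letter. Positions in `protect` never change; positions in
#' `forbid` (a named list mapping position to disallowed letters) may change
#' but never to the listed letters -- used to keep planted class labels exact.
#'
#' @param seq sequence string.
#' @param rate per-site substitution probability in [0, 1).
#' @param alphabet letters to mutate into.
#' @param protect integer positions that must not mutate.
#' @param forbid named list: `forbid[["17"]] = "E"` bans E at position 17.
#' @return mutated sequence string.
#' @export
mutate_seq <- function(seq, rate, alphabet = AA_ALPHABET,
                       protect = integer(), forbid = list()) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(seq)
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    banned <- c(ch[i], forbid[[as.character(i)]])
    ch[i] <- sample(setdiff(alphabet, banned), 1L)
  }
  chars_seq(ch)
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()].
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All k-mers over the DNA alphabet in lexicographic order
#' @param k word length.
#' @return character vector of length 4^k.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 10)
  do.call(paste0, rev(expand.grid(rep(list(DNA_ALPHABET), k),
                                  stringsAsFactors = FALSE)))
}
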