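## TAM (transposon-associated motif) depletion analysis. A 6N randomised
## library flanking the target site is sequenced before (input) and after
## (output) nuclease selection; TAMs supporting cleavage are depleted from
## the output. Scores are log2(input frequency / output frequency), so
## depleted TAMs score positive and the selection threshold (default 5 bits,
## i.e. >= 32-fold) applies directly.

#' Extract and count TAMs from amplicon reads
#'
#' For each read the constant target-site anchor is located (exact match;
#' the reverse complement of the read is searched when the forward strand
#' lacks the anchor and `search_rc` is enabled) and the `tam_length`
#' nucleotides immediately 5' of the anchor on the anchor's strand are taken
#' as the TAM. Reads lacking the anchor, lacking full TAM context, or with
#' ambiguous bases in the TAM are discarded and tallied.
#'
#' @param reads character vector of read sequences (e.g. from
#'   [read_fastq()]).
#' @param anchor constant anchor sequence, >= 10 nt.
#' @param tam_length TAM length, default 6.
#' @param search_rc also search the reverse complement, default TRUE.
#' @return an object of class `tam_counts`: `counts` (named integer vector
#'   over all 4^`tam_length` TAMs, zero-filled), `total_extracted`,
#'   `n_discarded`, `tam_length`.
#' @export
extract_tams <- function(reads, anchor, tam_length = 6L, search_rc = TRUE) {
  anchor <- toupper(anchor)
  if (nchar(anchor) < 10L) stop("anchor must be at least 10 nt")
  tams <- all_kmers(tam_length)
  n <- length(reads)
  if (n == 0L) {
    counts <- setNames(integer(length(tams)), tams)
    return(structure(list(counts = counts, total_extracted = 0L,
                          n_discarded = 0L, tam_length = tam_length),
                     class = "tam_counts"))
  }
  reads <- toupper(reads)
  oriented <- reads
  pos <- regexpr(anchor, oriented, fixed = TRUE)
  if (search_rc && any(pos == -1L)) {
    miss <- which(pos == -1L)
    oriented[miss] <- revcomp(oriented[miss])
    pos[miss] <- regexpr(anchor, oriented[miss], fixed = TRUE)
  }
  found <- pos != -1L

  ## ambiguous amplicon design guard: a second anchor occurrence
  if (any(found)) {
    after <- substring(oriented[found], as.integer(pos[found]) + 1L)
    multi <- regexpr(anchor, after, fixed = TRUE) != -1L
    if (mean(multi) > 0.01)
      stop("anchor occurs more than once in >1% of reads; ",
           "ambiguous amplicon design")
  }

  tam <- rep(NA_character_, n)
  ok <- found & as.integer(pos) - tam_length >= 1L
  tam[ok] <- substring(oriented[ok], as.integer(pos[ok]) - tam_length,
                       as.integer(pos[ok]) - 1L)
  ok <- ok & !is.na(tam) & !grepl("[^ACGT]", tam)
  counts <- table(factor(tam[ok], levels = tams))
  counts <- setNames(as.integer(counts), tams)
  structure(list(counts = counts, total_extracted = sum(counts),
                 n_discarded = n - sum(ok), tam_length = tam_length),
            class = "tam_counts")
}

#' Construct a TAM count table from a named count vector
#'
#' For workflows that already hold per-TAM counts (e.g. simulation truth
#' records); [extract_tams()] builds the same object from reads.
#'
#' @param counts named integer vector; names must be exactly the 4^L DNA
#'   words of one length L (any order).
#' @param n_discarded reads discarded upstream, default 0.
#' @return a `tam_counts` object.
#' @export
tam_counts <- function(counts, n_discarded = 0L) {
  L <- unique(nchar(names(counts)))
  if (length(L) != 1L || !setequal(names(counts), all_kmers(L)))
    stop("counts must be named by all DNA words of one length")
  counts <- counts[all_kmers(L)]
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 total_extracted = sum(counts),
                 n_discarded = as.integer(n_discarded),
                 tam_length = L),
            class = "tam_counts")
}

#' @export
print.tam_counts <- function(x, ...) {
  cat("TAM counts:", x$total_extracted, "extracted,", x$n_discarded,
      "discarded,", length(x$counts), "TAMs\n")
  invisible(x)
}

#' Score per-TAM depletion between input and output samples
#'
#' Frequencies are pseudocounted and depth-normalised per sample:
#' `f(t) = (count(t) + pc) / (total + 4^L * pc)`; the depletion score is
#' `log2(f_input(t) / f_output(t))`, positive for depleted TAMs. TAMs
#' scoring at or above `threshold` form the retained set.
#'
#' @param input,output `tam_counts` objects of equal TAM length.
#' @param pseudocount added to each count before normalisation, default 1.
#' @param threshold retention threshold in bits, default 5.
#' @return an object of class `tam_depletion`: `table` (data.frame: tam,
#'   count_in, count_out, freq_in, freq_out, log2fc, retained),
#'   `retained_set`, `threshold`.
#' @export
depletion_scores <- function(input, output, pseudocount = 1, threshold = 5) {
  stopifnot(inherits(input, "tam_counts"), inherits(output, "tam_counts"),
            input$tam_length == output$tam_length)
  if (input$total_extracted == 0L || output$total_extracted == 0L)
    stop("cannot score depletion from a sample with zero extracted TAMs")
  k <- length(input$counts)
  f_in <- (input$counts + pseudocount) /
    (input$total_extracted + k * pseudocount)
  f_out <- (output$counts + pseudocount) /
    (output$total_extracted + k * pseudocount)
  score <- log2(f_in / f_out)
  tab <- data.frame(tam = names(input$counts),
                    count_in = as.integer(input$counts),
                    count_out = as.integer(output$counts),
                    freq_in = as.numeric(f_in), freq_out = as.numeric(f_out),
                    log2fc = as.numeric(score),
                    retained = as.numeric(score) >= threshold)
  structure(list(table = tab, retained_set = tab$tam[tab$retained],
                 threshold = threshold),
            class = "tam_depletion")
}

#' @export
print.tam_depletion <- function(x, ...) {
  cat("TAM depletion:", length(x$retained_set), "of", nrow(x$table),
      "TAMs at log2FC >=", x$threshold, "\n")
  invisible(x)
}

#' Build a sequence-logo matrix from a retained TAM set
#'
#' Unweighted per-position base frequencies over the retained TAMs, with
#' per-position information `I_j = 2 - H_j` bits (`H_j` the Shannon entropy
#' in bits) and letter heights `f_bj * I_j` -- the content of a standard
#' sequence logo.
#'
#' @param retained_set character vector of equal-length TAM strings.
#' @return list of class `logo_matrix`: `freq` (4 x L), `information`
#'   (length L, in [0, 2]), `letter_heights` (4 x L).
#' @export
build_logo <- function(retained_set) {
  if (length(retained_set) == 0L)
    stop("retained set is empty; lower the depletion threshold ",
         "or check the input samples")
  L <- unique(nchar(retained_set))
  stopifnot(length(L) == 1L)
  mat <- do.call(rbind, strsplit(retained_set, "", fixed = TRUE))
  freq <- vapply(seq_len(L), function(j) {
    as.numeric(table(factor(mat[, j], levels = DNA_ALPHABET))) /
      nrow(mat)
  }, numeric(4))
  freq <- matrix(freq, nrow = 4, dimnames = list(DNA_ALPHABET, NULL))
  h <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  information <- 2 - h
  structure(list(freq = freq, information = information,
                 letter_heights = sweep(freq, 2, information, `*`)),
            class = "logo_matrix")
}

#' Normalised colony-forming units for plasmid-interference assays
#'
#' `norm_cfu = cfu_double / cfu_single` (double-antibiotic plate over
#' single-antibiotic control). When no colony grows on the double plate the
#' result is reported as the detection limit `1 / cfu_single` and flagged.
#'
#' @param cfu_double colony count on the double-antibiotic plate.
#' @param cfu_single colony count on the single-antibiotic control (> 0).
#' @return list of class `interference_result`: `cfu_double`, `cfu_single`,
#'   `norm_cfu`, `is_detection_limit`.
#' @export
norm_cfu <- function(cfu_double, cfu_single) {
  if (cfu_single <= 0) stop("single-antibiotic control CFU must be positive")
  if (cfu_double < 0) stop("CFU counts cannot be negative")
  limit <- cfu_double == 0
  structure(list(cfu_double = cfu_double, cfu_single = cfu_single,
                 norm_cfu = if (limit) 1 / cfu_single
                 else cfu_double / cfu_single,
                 is_detection_limit = limit),
            class = "interference_result")
}
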