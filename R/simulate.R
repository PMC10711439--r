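## Synthetic-data generators. Every input the pipeline consumes can be
## produced here with a machine-readable truth record, so each downstream
## stage can be scored without re-deriving ground truth. All generators are
## deterministic for a fixed (config, seed): one master seed per call, with
## per-record child streams (child_seed) wherever a record may be
## regenerated, so regeneration of record i never perturbs record j.

#' Configuration for the protein-family generator
#'
#' @param n_positives,n_decoys record counts.
#' @param ruvc1_class `"DPG"` or `"DPhiG"` for the planted RuvC1 motif.
#' @param e_placement `"E_alt"` (glutamate 7 residues before the first ZF
#'   cysteine) or `"E_can"` (canonical window placement).
#' @param spacer_range residues strictly between the RuvC1 glycine and the
#'   glutamate; default 120--160.
#' @param zf_spacers list of two integer pairs: the inter-CxxC spacer
#'   (default 12--18) and the C4-to-D spacer (default 4--8).
#' @param mutation_rate per-site substitution rate in [0, 1) applied to
#'   non-motif residues of positives (planted anchors are protected so class
#'   labels stay exact).
#' @param decoy_length length of decoy proteins (default 400 aa).
#' @param seed master seed.
#' @return a validated config list of class `protein_family_config`.
#' @export
protein_family_config <- function(n_positives, n_decoys,
                                  ruvc1_class = c("DPG", "DPhiG"),
                                  e_placement = c("E_alt", "E_can"),
                                  spacer_range = c(120L, 160L),
                                  zf_spacers = list(c(12L, 18L), c(4L, 8L)),
                                  mutation_rate = 0,
                                  decoy_length = 400L,
                                  seed = 1L) {
  ruvc1_class <- match.arg(ruvc1_class)
  e_placement <- match.arg(e_placement)
  stopifnot(n_positives >= 0, n_decoys >= 0,
            spacer_range[1] >= 1, spacer_range[2] <= 500,
            spacer_range[1] <= spacer_range[2],
            mutation_rate >= 0, mutation_rate < 1,
            decoy_length >= 50)
  structure(list(n_positives = as.integer(n_positives),
                 n_decoys = as.integer(n_decoys),
                 ruvc1_class = ruvc1_class, e_placement = e_placement,
                 spacer_range = as.integer(spacer_range),
                 zf_spacers = lapply(zf_spacers, as.integer),
                 mutation_rate = mutation_rate,
                 decoy_length = as.integer(decoy_length),
                 seed = as.integer(seed)),
            class = "protein_family_config")
}

## Build one positive with a planted fingerprint; returns seq + truth coords.
plant_fingerprint <- function(cfg) {
  s1 <- cfg$zf_spacers[[1]]; s2 <- cfg$zf_spacers[[2]]
  mid <- if (cfg$ruvc1_class == "DPG") "P" else sample(PHI_SET, 1L)
  npre <- sample(20:60, 1L)
  spacer <- sample(cfg$spacer_range[1]:cfg$spacer_range[2], 1L)
  zsp1 <- sample(s1[1]:s1[2], 1L)
  zsp2 <- sample(s2[1]:s2[2], 1L)
  ecan_k <- 50L  # distance E -> first ZF cysteine in canonical placement

  zf_block <- paste0("C", random_protein(2), "C", random_protein(zsp1),
                     "C", random_protein(2), "C", random_protein(zsp2), "D")
  if (cfg$e_placement == "E_alt") {
    body <- paste0("D", mid, "G", random_protein(spacer, exclude = "E"),
                   "E", random_protein(6), zf_block)
    e_off <- npre + 3L + spacer + 1L            # index of the glutamate
    c1_off <- e_off + 7L
  } else {
    ## E then ecan_k - 1 residues then the ZF C1; the slot 7 residues before
    ## C1 falls inside that stretch and must never hold an E.
    gap <- random_protein(ecan_k - 1L, exclude = "E")
    body <- paste0("D", mid, "G", random_protein(spacer, exclude = "E"),
                   "E", gap, zf_block)
    e_off <- npre + 3L + spacer + 1L
    c1_off <- e_off + ecan_k
  }
  npost <- sample(20:60, 1L)
  seq <- paste0(random_protein(npre), body, random_protein(npost))
  d_index <- npre + 1L
  list(seq = seq, d_index = d_index, e_index = e_off, zf_c1 = c1_off)
}

expected_category <- function(cfg) {
  if (cfg$e_placement == "E_can") return("CANONICAL")
  if (cfg$ruvc1_class == "DPG") "FANZOR_LIKE" else "E_ALT_DPHIG"
}

#' Generate a labelled protein family with planted fingerprints
#'
#' Positives carry exactly one planted fingerprint of the requested class and
#' are verified against [classify_fingerprint()] at generation time; decoys
#' are verified to classify as `INCOMPLETE`. Records failing the self-check
#' are regenerated (at most 100 attempts each, on their own child stream).
#' Mutations applied to positives protect the planted anchor residues
#' (D, P/phi, G, E, the four cysteines, the terminal D) and, for canonical
#' placements, ban E from the alternative-glutamate slot, so the truth label
#' stays exact at any mutation rate.
#'
#' @param config a [protein_family_config()].
#' @return a data.frame with columns `id`, `seq`, `class` (the expected
#'   fingerprint category; `INCOMPLETE` for decoys), `is_positive`, and
#'   planted coordinates `d_index`, `e_index`, `zf_c1` (NA for decoys).
#' @export
gen_protein_family <- function(config) {
  stopifnot(inherits(config, "protein_family_config"))
  want <- expected_category(config)
  spr <- config$spacer_range
  recs <- vector("list", config$n_positives + config$n_decoys)

  for (i in seq_len(config$n_positives)) {
    set.seed(child_seed(config$seed, i))
    for (attempt in 1:100) {
      p <- plant_fingerprint(config)
      fc <- classify_fingerprint(p$seq, spacer_range = spr,
                                 spacer1 = config$zf_spacers[[1]],
                                 spacer2 = config$zf_spacers[[2]])
      if (fc$category == want) break
      p <- NULL
    }
    if (is.null(p))
      stop("failed to plant a clean positive after 100 attempts")
    if (config$mutation_rate > 0) {
      ch <- seq_chars(p$seq)
      zf <- c(p$zf_c1, p$zf_c1 + 3L)
      ## locate the second CxxC block and terminal D from the planted layout
      fcp <- classify_fingerprint(p$seq, spacer_range = spr)
      protect <- c(p$d_index, p$d_index + 1L, p$d_index + 2L, p$e_index,
                   fcp$zf$c1, fcp$zf$c2, fcp$zf$c3, fcp$zf$c4, fcp$zf$d_end)
      forbid <- list()
      if (config$e_placement == "E_can")
        forbid[[as.character(p$zf_c1 - 7L)]] <- "E"
      p$seq <- mutate_seq(p$seq, config$mutation_rate,
                          protect = protect, forbid = forbid)
    }
    recs[[i]] <- data.frame(id = sprintf("pos_%04d", i), seq = p$seq,
                            class = want, is_positive = TRUE,
                            d_index = p$d_index, e_index = p$e_index,
                            zf_c1 = p$zf_c1)
  }

  for (j in seq_len(config$n_decoys)) {
    set.seed(child_seed(config$seed, config$n_positives + j))
    seq <- NULL
    for (attempt in 1:100) {
      cand <- random_protein(config$decoy_length)
      fc <- classify_fingerprint(cand, spacer_range = spr)
      if (fc$category == "INCOMPLETE") { seq <- cand; break }
    }
    if (is.null(seq))
      stop("failed to generate a pattern-free decoy after 100 attempts")
    recs[[config$n_positives + j]] <-
      data.frame(id = sprintf("dec_%04d", j), seq = seq,
                 class = "INCOMPLETE", is_positive = FALSE,
                 d_index = NA_integer_, e_index = NA_integer_,
                 zf_c1 = NA_integer_)
  }
  do.call(rbind, recs)
}

#' Configuration for the transposon-locus generator
#'
#' IS607 simulations have no target-site duplication and GG dinucleotides at
#' both crossover boundaries; eukaryotic DNA-transposon simulations carry a
#' TSD of at least 2 nt and terminal inverted repeats.
#'
#' @param element_length element length in nt.
#' @param tsd_length TSD length in nt, 0--15 (forced to 0 for IS607/IS200).
#' @param tir_length,tir_mismatches TIR length and planted mismatch count
#'   (eukaryotic mode only).
#' @param is_family `"eukaryotic_DNA_transposon"`, `"IS607"` or `"IS200_605"`.
#' @param flank_length flanking sequence length, default 2000 nt.
#' @param seed master seed.
#' @export
transposon_sim_config <- function(element_length = 3000L, tsd_length = 4L,
                                  tir_length = 20L, tir_mismatches = 0L,
                                  is_family = c("eukaryotic_DNA_transposon",
                                                "IS607", "IS200_605"),
                                  flank_length = 2000L, seed = 1L) {
  is_family <- match.arg(is_family)
  if (is_family != "eukaryotic_DNA_transposon") tsd_length <- 0L
  stopifnot(tsd_length >= 0, tsd_length <= 15,
            element_length >= 100, flank_length >= 20,
            tir_mismatches >= 0)
  if (is_family == "eukaryotic_DNA_transposon") {
    stopifnot(tsd_length >= 2, tir_length >= 8,
              tir_mismatches <= tir_length - 4L)
  }
  structure(list(element_length = as.integer(element_length),
                 tsd_length = as.integer(tsd_length),
                 tir_length = as.integer(tir_length),
                 tir_mismatches = as.integer(tir_mismatches),
                 is_family = is_family,
                 flank_length = as.integer(flank_length),
                 seed = as.integer(seed)),
            class = "transposon_sim_config")
}

## n positions of seq mutated to a different base
mutate_positions <- function(seq, pos) {
  ch <- seq_chars(seq)
  for (i in pos) ch[i] <- sample(setdiff(DNA_ALPHABET, ch[i]), 1L)
  chars_seq(ch)
}

#' Generate a transposon insertion allele, its empty allele, and truth record
#'
#' The insertion allele is `left flank + TSD + element + TSD + right flank`
#' (eukaryotic mode), `left flank + element + right flank` with GG at both
#' element boundaries and `left flank + GG + right flank` as the empty allele
#' (IS607 mode), or a plain flank/element/flank sandwich (IS200/605 mode).
#' Loci whose planted TSD would be ambiguous (an unplanted flank-derived
#' duplication of length >= 2 at the junctions) are regenerated.
#'
#' @param config a [transposon_sim_config()].
#' @return list with `insertion`, `empty` (strings) and `truth`: element
#'   interval (1-based inclusive, within the insertion allele), `tsd`,
#'   TIR intervals within the element + planted mismatch count, family and
#'   GG boundary flags.
#' @export
gen_transposon_locus <- function(config) {
  stopifnot(inherits(config, "transposon_sim_config"))
  fam <- config$is_family
  for (attempt in 1:100) {
    set.seed(child_seed(config$seed, attempt))
    lf <- random_dna(config$flank_length)
    rf <- random_dna(config$flank_length)
    tsd <- if (config$tsd_length > 0) random_dna(config$tsd_length) else ""
    if (fam == "eukaryotic_DNA_transposon") {
      core_len <- config$element_length - 2L * config$tir_length
      stopifnot(core_len > 0)
      tir <- random_dna(config$tir_length)
      right_tir <- revcomp(tir)
      if (config$tir_mismatches > 0) {
        ## interior positions only: the repeat termini are the
        ## transposase-critical, conserved positions of real TIRs
        pos <- sample(3:(config$tir_length - 2L), config$tir_mismatches)
        right_tir <- mutate_positions(right_tir, pos)
      }
      element <- paste0(tir, random_dna(core_len), right_tir)
      insertion <- paste0(lf, tsd, element, tsd, rf)
      empty <- paste0(lf, tsd, rf)
      el_start <- config$flank_length + config$tsd_length + 1L
    } else if (fam == "IS607") {
      element <- paste0("GG", random_dna(config$element_length - 4L), "GG")
      insertion <- paste0(lf, element, rf)
      empty <- paste0(lf, "GG", rf)
      el_start <- config$flank_length + 1L
    } else {
      element <- random_dna(config$element_length)
      insertion <- paste0(lf, element, rf)
      empty <- paste0(lf, rf)
      el_start <- config$flank_length + 1L
    }
    el_end <- el_start + nchar(element) - 1L
    found <- detect_tsd(insertion, c(el_start, el_end),
                        k_min = 2L, k_max = 15L)
    ok <- if (config$tsd_length >= 2)
      identical(found, tsd) else is.null(found)
    if (ok && fam == "eukaryotic_DNA_transposon") {
      ## the planted repeat must be unambiguous: detect_tir has to recover
      ## its exact coordinates and mismatch count
      tl <- config$tir_length
      hit <- detect_tir(element)
      ok <- !is.null(hit) &&
        identical(hit$left, c(1L, tl)) &&
        identical(hit$right, c(nchar(element) - tl + 1L, nchar(element))) &&
        hit$mismatches == config$tir_mismatches
    }
    if (ok) {
      truth <- list(element_interval = c(el_start, el_end),
                    element = element,
                    tsd = if (config$tsd_length > 0) tsd else NULL,
                    tir_length = if (fam == "eukaryotic_DNA_transposon")
                      config$tir_length else NULL,
                    tir_mismatches = if (fam == "eukaryotic_DNA_transposon")
                      config$tir_mismatches else NULL,
                    is_family = fam,
                    gg_boundaries = c(LE = fam == "IS607",
                                      RE = fam == "IS607"))
      return(list(insertion = insertion, empty = empty, truth = truth))
    }
  }
  stop("could not generate an unambiguous locus in 100 attempts")
}

#' Configuration for the homolog-ladder generator
#'
#' @param n_per_rung sequences per identity rung.
#' @param identities nominal identities of the rungs to the seed ancestor;
#'   rungs are evolutionarily nested (each rung is derived from the
#'   previous one, as homolog families are in nature), so the default
#'   ladder is ancestor -> 80% -> 60% -> 40% -> 30%.
#' @param region_len length (aa) of the conserved region the profiles model.
#' @param n_seed rows in the seed alignment.
#' @param seed_divergence per-site divergence of seed rows from the
#'   ancestor.
#' @param flank random residues added on each side of the region in
#'   database sequences.
#' @param n_decoys unrelated random database sequences.
#' @param seed master seed.
#' @export
ladder_config <- function(n_per_rung = 50L,
                          identities = c(0.8, 0.6, 0.4, 0.3),
                          region_len = 60L, n_seed = 8L,
                          seed_divergence = 0.05, flank = 30L,
                          n_decoys = 50L, seed = 1L) {
  stopifnot(n_per_rung >= 1, all(diff(identities) < 0),
            all(identities > 0), all(identities < 1),
            region_len >= 20, n_seed >= 2)
  structure(list(n_per_rung = as.integer(n_per_rung),
                 identities = identities,
                 region_len = as.integer(region_len),
                 n_seed = as.integer(n_seed),
                 seed_divergence = seed_divergence,
                 flank = as.integer(flank),
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "ladder_config")
}

#' Generate a nested homolog ladder for iterative-search experiments
#'
#' Builds a seed alignment of lightly diverged copies of an ancestral
#' conserved region, plus a database of homolog lineages: within each
#' lineage the rung sequences form a Markov chain (the 60% rung is derived
#' from that lineage's 80% sequence, and so on), so distant rungs share
#' derived residues with intermediate ones -- the regime in which adding
#' intermediate hits to the alignment genuinely helps a profile reach
#' further. Database sequences embed the (diverged) region between random
#' flanks; unrelated random decoys are appended.
#'
#' @param config a [ladder_config()].
#' @return list with `seed_alignment` (named character), `database` (named
#'   character) and `truth` (data.frame: id, rung -- the nominal identity,
#'   or NA for decoys).
#' @export
gen_homolog_ladder <- function(config) {
  stopifnot(inherits(config, "ladder_config"))
  set.seed(config$seed)
  ancestor <- random_protein(config$region_len)
  seed_aln <- vapply(seq_len(config$n_seed), function(i)
    mutate_seq(ancestor, config$seed_divergence), "")
  names(seed_aln) <- sprintf("seed_%02d", seq_len(config$n_seed))

  ids <- character(); seqs <- character(); rung <- numeric()
  rel <- c(config$identities[1],
           config$identities[-1] / head(config$identities, -1))
  for (i in seq_len(config$n_per_rung)) {
    parent <- ancestor
    for (r in seq_along(config$identities)) {
      parent <- mutate_seq(parent, 1 - rel[r])
      id <- sprintf("r%02d_%03d", round(100 * config$identities[r]), i)
      ids <- c(ids, id)
      seqs <- c(seqs, paste0(random_protein(config$flank), parent,
                             random_protein(config$flank)))
      rung <- c(rung, config$identities[r])
    }
  }
  for (i in seq_len(config$n_decoys)) {
    ids <- c(ids, sprintf("decoy_%03d", i))
    seqs <- c(seqs, random_protein(config$region_len + 2L * config$flank))
    rung <- c(rung, NA_real_)
  }
  database <- setNames(seqs, ids)
  list(seed_alignment = seed_aln, database = database,
       truth = data.frame(id = ids, rung = rung))
}

#' Configuration for the TAM amplicon-read generator
#'
#' @param tam_length TAM length, default 6 nt (a 6N randomised library spans
#'   all 4096 TAMs).
#' @param depleted_set either a character vector of depleted TAMs or a
#'   predicate `function(tams) -> logical`; default: TAMs whose first three
#'   positions are GGG.
#' @param depletion_factor fold down-weighting of depleted TAMs in the
#'   output sample, default 2^6.
#' @param reads_per_sample sequencing depth per sample, default 500000.
#' @param anchor constant target-site sequence 3' of the TAM (>= 10 nt).
#' @param frac_reverse fraction of reads emitted as reverse complements.
#' @param seed master seed.
#' @export
tam_sim_config <- function(tam_length = 6L,
                           depleted_set = function(t) substr(t, 1, 3) == "GGG",
                           depletion_factor = 2^6,
                           reads_per_sample = 500000L,
                           anchor = "ACGTTGACCGTAGGTT",
                           frac_reverse = 0.5,
                           seed = 1L) {
  stopifnot(tam_length >= 1, tam_length <= 8,
            depletion_factor > 0,
            nchar(anchor) >= 10,
            reads_per_sample >= 0,
            frac_reverse >= 0, frac_reverse <= 1)
  structure(list(tam_length = as.integer(tam_length),
                 depleted_set = depleted_set,
                 depletion_factor = depletion_factor,
                 reads_per_sample = as.integer(reads_per_sample),
                 anchor = toupper(anchor),
                 frac_reverse = frac_reverse,
                 seed = as.integer(seed)),
            class = "tam_sim_config")
}

## random pads taken as substrings of a shared random pool (pads are inert)
random_pads <- function(n, len_range, pool_size = 4000L) {
  pool <- random_dna(pool_size)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- sample.int(pool_size - len_range[2], n, replace = TRUE)
  substring(pool, start, start + len - 1L)
}

#' Generate paired TAM-library amplicon read sets with planted depletion
#'
#' The input (library) sample draws reads uniformly over all 4^L TAMs; the
#' output (selected) sample down-weights the depleted set by
#' `depletion_factor` and renormalises. Each read is
#' `left pad + TAM + anchor + right pad`; a configured fraction is emitted
#' reverse-complemented. Counts are multinomial at the configured depth.
#'
#' @param config a [tam_sim_config()].
#' @param emit_reads if `FALSE`, skip read materialisation and return counts
#'   only (the truth record is identical either way).
#' @return list with `input_reads`, `output_reads` (character vectors;
#'   `NULL` when `emit_reads = FALSE`) and `truth`: named per-TAM
#'   `input_counts` and `output_counts` (the planted multinomial draws) and
#'   the `depleted` TAM set.
#' @export
gen_tam_reads <- function(config, emit_reads = TRUE) {
  stopifnot(inherits(config, "tam_sim_config"))
  set.seed(config$seed)
  tams <- all_kmers(config$tam_length)
  depl <- config$depleted_set
  depleted <- if (is.function(depl)) tams[depl(tams)] else intersect(depl, tams)

  n <- config$reads_per_sample
  p_in <- rep(1 / length(tams), length(tams))
  w <- ifelse(tams %in% depleted, 1 / config$depletion_factor, 1)
  p_out <- w / sum(w)
  counts_in <- if (n > 0) drop(rmultinom(1, n, p_in)) else rep(0L, length(tams))
  counts_out <- if (n > 0) drop(rmultinom(1, n, p_out)) else rep(0L, length(tams))
  names(counts_in) <- names(counts_out) <- tams

  materialise <- function(counts) {
    if (sum(counts) == 0) return(character())
    tam_of_read <- sample(rep.int(tams, counts))
    m <- length(tam_of_read)
    reads <- paste0(random_pads(m, c(5L, 12L)), tam_of_read, config$anchor,
                    random_pads(m, c(5L, 12L)))
    if (config$frac_reverse > 0) {
      flip <- runif(m) < config$frac_reverse
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
    }
    reads
  }
  list(input_reads = if (emit_reads) materialise(counts_in) else NULL,
       output_reads = if (emit_reads) materialise(counts_out) else NULL,
       truth = list(input_counts = counts_in, output_counts = counts_out,
                    depleted = depleted))
}

#' Configuration for the co-diverging TnpA/TnpB family generator
#'
#' @param n_elements number of transposable elements (>= 3).
#' @param divergence_range per-element expected substitutions/site drawn
#'   uniformly from this range; default 0.1--0.6.
#' @param coupling in [0, 1]; 1 means TnpA and TnpB of an element diverge on
#'   the same clock draw, 0 means independent draws.
#' @param shuffle_control also return a permuted TnpB pairing.
#' @param len_a,len_b TnpA / TnpB sequence lengths (aa).
#' @param seed master seed.
#' @export
paired_family_config <- function(n_elements = 30L,
                                 divergence_range = c(0.1, 0.6),
                                 coupling = 1, shuffle_control = FALSE,
                                 len_a = 200L, len_b = 400L, seed = 1L) {
  stopifnot(n_elements >= 3, coupling >= 0, coupling <= 1,
            divergence_range[1] > 0, divergence_range[2] < 2)
  structure(list(n_elements = as.integer(n_elements),
                 divergence_range = divergence_range,
                 coupling = coupling, shuffle_control = shuffle_control,
                 len_a = as.integer(len_a), len_b = as.integer(len_b),
                 seed = as.integer(seed)),
            class = "paired_family_config")
}

#' Generate co-diverging TnpA and TnpB alignments with a pairing table
#'
#' Each element carries a TnpA and a TnpB sequence diverged from common
#' ancestors. With coupling 1 both proteins of an element use the same clock
#' draw, so pairwise identities co-vary across elements; with coupling 0 the
#' draws are independent. Substitution-only evolution, so the sequence sets
#' are gap-free alignments.
#'
#' @param config a [paired_family_config()].
#' @return list with `msa_a`, `msa_b` (named character vectors), `pairing`
#'   (data.frame element_id, row_a, row_b), `shuffled_pairing` (present when
#'   requested; permutes the TnpB assignment only) and `truth` (the clock
#'   draws per element).
#' @export
gen_paired_families <- function(config) {
  stopifnot(inherits(config, "paired_family_config"))
  set.seed(config$seed)
  n <- config$n_elements
  anc_a <- random_protein(config$len_a)
  anc_b <- random_protein(config$len_b)
  d <- runif(n, config$divergence_range[1], config$divergence_range[2])
  d_ind <- runif(n, config$divergence_range[1], config$divergence_range[2])
  d_b <- config$coupling * d + (1 - config$coupling) * d_ind
  ids <- sprintf("el_%03d", seq_len(n))
  msa_a <- vapply(d, function(x) mutate_seq(anc_a, 1 - exp(-x)), "")
  msa_b <- vapply(d_b, function(x) mutate_seq(anc_b, 1 - exp(-x)), "")
  names(msa_a) <- paste0(ids, "_tnpA")
  names(msa_b) <- paste0(ids, "_tnpB")
  pairing <- data.frame(element_id = ids, row_a = names(msa_a),
                        row_b = names(msa_b))
  out <- list(msa_a = msa_a, msa_b = msa_b, pairing = pairing,
              truth = list(dist_a = d, dist_b = d_b))
  if (config$shuffle_control) {
    perm <- sample(n)
    out$shuffled_pairing <- data.frame(element_id = ids,
                                       row_a = names(msa_a),
                                       row_b = names(msa_b)[perm])
  }
  out
}

#' Configuration for the small-RNA read generator
#'
#' @param locus nucleotide string the reads derive from.
#' @param rerna_start,rerna_end 1-based inclusive reRNA interval within the
#'   locus.
#' @param n_reads read count (> 0).
#' @param read_length_range optional length clamp; reads outside the range
#'   are discarded.
#' @param end_noise_sd standard deviation (nt) of Gaussian jitter applied to
#'   both read endpoints.
#' @param seed master seed.
#' @export
smallrna_sim_config <- function(locus, rerna_start, rerna_end,
                                n_reads = 1000L, read_length_range = NULL,
                                end_noise_sd = 0, seed = 1L) {
  stopifnot(rerna_start >= 1, rerna_end <= nchar(locus),
            rerna_start < rerna_end, n_reads > 0, end_noise_sd >= 0)
  structure(list(locus = toupper(locus),
                 rerna_start = as.integer(rerna_start),
                 rerna_end = as.integer(rerna_end),
                 n_reads = as.integer(n_reads),
                 read_length_range = read_length_range,
                 end_noise_sd = end_noise_sd,
                 seed = as.integer(seed)),
            class = "smallrna_sim_config")
}

#' Generate merged small-RNA reads tiling a reRNA span
#'
#' Emulates merged paired-end small-RNA-seq of an expressed reRNA: each read
#' is a substring of the locus spanning the planted interval with both
#' endpoints jittered by Gaussian noise (rounded to whole nt) and clipped to
#' the locus.
#'
#' @param config a [smallrna_sim_config()].
#' @return list with `reads` (character vector) and `truth`: the planted
#'   interval, the realised per-read start/end, and the planted pileup
#'   (integer coverage over the locus).
#' @export
gen_smallrna_reads <- function(config) {
  stopifnot(inherits(config, "smallrna_sim_config"))
  set.seed(config$seed)
  n <- config$n_reads
  L <- nchar(config$locus)
  s <- config$rerna_start + round(rnorm(n, 0, config$end_noise_sd))
  e <- config$rerna_end + round(rnorm(n, 0, config$end_noise_sd))
  s <- pmax(1L, pmin(as.integer(s), L))
  e <- pmax(1L, pmin(as.integer(e), L))
  keep <- e > s
  if (!is.null(config$read_length_range)) {
    len <- e - s + 1L
    keep <- keep & len >= config$read_length_range[1] &
      len <= config$read_length_range[2]
  }
  s <- s[keep]; e <- e[keep]
  reads <- substring(config$locus, s, e)
  cov <- integer(L)
  for (i in seq_along(s)) {
    idx <- s[i]:e[i]
    cov[idx] <- cov[idx] + 1L
  }
  list(reads = reads,
       truth = list(interval = c(config$rerna_start, config$rerna_end),
                    starts = s, ends = e, pileup = cov))
}
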