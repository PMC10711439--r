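## End-to-end orchestration: simulate -> classify -> annotate -> score.
## Every stage writes declared files only; all randomness flows from the
## master seed; rerunning with the same config reproduces byte-identical
## stage outputs (the manifest additionally records wall-clock, which of
## course varies).

PIPELINE_STAGES <- c("proteins", "transposon", "tam", "pairs", "smallrna")

#' Default pipeline configuration
#'
#' Problem sizes are desk-scale so a full run completes in seconds; every
#' parameter default equals the module default it feeds.
#'
#' @param seed master seed; each stage derives its own child seed.
#' @return nested config list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = PIPELINE_STAGES,
    proteins = list(n_positives = 20L, n_decoys = 80L,
                    ruvc1_class = "DPG", e_placement = "E_alt",
                    mutation_rate = 0),
    transposon = list(element_length = 600L, tsd_length = 4L,
                      tir_length = 20L, tir_mismatches = 0L,
                      is_family = "eukaryotic_DNA_transposon",
                      flank_length = 100L),
    tam = list(tam_length = 6L, depletion_factor = 2^6,
               reads_per_sample = 500000L, threshold = 5),
    pairs = list(n_elements = 30L, coupling = 1, shuffle_control = TRUE),
    smallrna = list(locus_length = 600L, rerna_start = 101L,
                    rerna_end = 250L, n_reads = 500L, end_noise_sd = 0)
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected by [run_pipeline()]'s validation.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return nested config list.
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_pipeline_config()
  for (k in names(cfg)) {
    if (is.list(cfg[[k]]) && is.list(base[[k]]))
      base[[k]][names(cfg[[k]])] <- cfg[[k]]
    else base[[k]] <- cfg[[k]]
  }
  base
}

validate_pipeline_config <- function(config) {
  ref <- default_pipeline_config()
  problems <- character()
  unknown_top <- setdiff(names(config), names(ref))
  if (length(unknown_top))
    problems <- c(problems, paste0("unknown config key(s): ",
                                   paste(unknown_top, collapse = ", ")))
  for (stage in intersect(names(config), PIPELINE_STAGES)) {
    unknown <- setdiff(names(config[[stage]]), names(ref[[stage]]))
    if (length(unknown))
      problems <- c(problems,
                    paste0("unknown key(s) in '", stage, "': ",
                           paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$stages) &&
      !all(config$stages %in% PIPELINE_STAGES))
    problems <- c(problems,
                  paste0("unknown stage(s): ",
                         paste(setdiff(config$stages, PIPELINE_STAGES),
                               collapse = ", ")))
  if (length(problems)) stop(paste(problems, collapse = "\n"))
  invisible(TRUE)
}

#' Run the full synthetic pipeline
#'
#' Executes the selected stages in order, each against its own child seed:
#' protein-family simulation + fingerprint scan, transposon simulation +
#' locus curation, TAM simulation + depletion scoring + logo, paired-family
#' simulation + co-conservation, and small-RNA simulation + mapping +
#' boundary calling. Writes per-stage TSV/JSON outputs plus a manifest with
#' config echo, output digests and per-stage wall-clock.
#'
#' @param config nested config list (see [default_pipeline_config()]);
#'   validation errors list every violation.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("fanzortrace_run_")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character()
  timings <- list()
  results <- list()

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- fun()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    results[[name]] <<- res
  }

  if ("proteins" %in% config$stages) run_stage("proteins", function() {
    pc <- config$proteins
    fam <- gen_protein_family(protein_family_config(
      n_positives = pc$n_positives, n_decoys = pc$n_decoys,
      ruvc1_class = pc$ruvc1_class, e_placement = pc$e_placement,
      mutation_rate = pc$mutation_rate, seed = child_seed(seed, 1L)))
    scan <- scan_database(setNames(fam$seq, fam$id))
    f <- file.path(out_dir, "fingerprint_calls.tsv")
    write_tsv(scan$calls, f)
    outputs <<- c(outputs, f)
    list(fractions = scan$fractions,
         truth_fractions = prop.table(table(factor(fam$class,
           levels = FINGERPRINT_CATEGORIES))))
  })

  if ("transposon" %in% config$stages) run_stage("transposon", function() {
    tc <- config$transposon
    loc <- gen_transposon_locus(transposon_sim_config(
      element_length = tc$element_length, tsd_length = tc$tsd_length,
      tir_length = tc$tir_length, tir_mismatches = tc$tir_mismatches,
      is_family = tc$is_family, flank_length = tc$flank_length,
      seed = child_seed(seed, 2L)))
    ann <- annotate_locus(loc$insertion, loc$truth$element_interval,
                          loc$empty)
    f <- file.path(out_dir, "locus_annotation.tsv")
    write_tsv(data.frame(
      field = c("tsd", "empty_site_ok", "tir_mismatches", "gg_le", "gg_re"),
      value = c(if (is.null(ann$tsd)) "." else ann$tsd,
                as.character(ann$empty_site_ok),
                if (is.null(ann$tirs)) "." else ann$tirs$mismatches,
                ann$gg_boundaries[["LE"]], ann$gg_boundaries[["RE"]])), f)
    g <- file.path(out_dir, "locus_features.gff3")
    write_locus_gff3("synthetic_locus", loc$truth$element_interval,
                     ann$tsd, ann$tirs, g)
    outputs <<- c(outputs, f, g)
    list(annotation = ann, truth = loc$truth)
  })

  if ("tam" %in% config$stages) run_stage("tam", function() {
    mc <- config$tam
    cfg <- tam_sim_config(tam_length = mc$tam_length,
                          depletion_factor = mc$depletion_factor,
                          reads_per_sample = mc$reads_per_sample,
                          seed = child_seed(seed, 3L))
    sim <- gen_tam_reads(cfg)
    cin <- extract_tams(sim$input_reads, cfg$anchor, mc$tam_length)
    cout <- extract_tams(sim$output_reads, cfg$anchor, mc$tam_length)
    dep <- depletion_scores(cin, cout, threshold = mc$threshold)
    f <- file.path(out_dir, "tam_depletion.tsv")
    write_tsv(dep$table, f)
    outputs <<- c(outputs, f)
    out <- list(retained = dep$retained_set, truth = sim$truth$depleted)
    if (length(dep$retained_set) > 0) {
      logo <- build_logo(dep$retained_set)
      lf <- file.path(out_dir, "tam_logo.tsv")
      write_tsv(data.frame(position = seq_along(logo$information),
                           t(logo$freq),
                           information = logo$information), lf)
      outputs <<- c(outputs, lf)
      out$logo <- logo
    }
    out
  })

  if ("pairs" %in% config$stages) run_stage("pairs", function() {
    qc <- config$pairs
    fam <- gen_paired_families(paired_family_config(
      n_elements = qc$n_elements, coupling = qc$coupling,
      shuffle_control = qc$shuffle_control, seed = child_seed(seed, 4L)))
    res <- paired_identities(fam$msa_a, fam$msa_b, fam$pairing)
    f <- file.path(out_dir, "coconservation_pairs.tsv")
    write_tsv(res$pairs, f)
    outputs <<- c(outputs, f)
    out <- list(pearson_r = res$pearson_r, spearman_rho = res$spearman_rho)
    if (!is.null(fam$shuffled_pairing)) {
      shuf <- paired_identities(fam$msa_a, fam$msa_b, fam$shuffled_pairing)
      out$pearson_r_shuffled <- shuf$pearson_r
    }
    out
  })

  if ("smallrna" %in% config$stages) run_stage("smallrna", function() {
    sc <- config$smallrna
    locus <- with_seed(child_seed(seed, 5L), random_dna(sc$locus_length))
    sim <- gen_smallrna_reads(smallrna_sim_config(
      locus, sc$rerna_start, sc$rerna_end, n_reads = sc$n_reads,
      end_noise_sd = sc$end_noise_sd, seed = child_seed(seed, 6L)))
    prof <- map_reads(sim$reads, locus)
    call <- call_boundaries(prof)
    f <- file.path(out_dir, "rerna_coverage.tsv")
    write_tsv(data.frame(pos = seq_along(prof$coverage),
                         depth = prof$coverage), f)
    outputs <<- c(outputs, f)
    list(called = call$interval, truth = sim$truth$interval,
         n_mapped = prof$n_mapped)
  })

  manifest <- list(
    tool = paste0("fanzortrace ",
                  as.character(utils::packageVersion("fanzortrace"))),
    config = config,
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))),
    wall_clock_s = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results,
                 out_dir = out_dir))
}
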