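#' Build and validate a pipeline configuration
#'
#' One object drives the whole pipeline: the allele set, the simulation
#' parameters, the training/calibration knobs, the class-specific rank
#' cutoff and strong-binder bound, the master seed and the output directory.
#' Every stage derives named child seeds from the master seed, so toggling a
#' stage never changes another stage's randomness.
#'
#' @param alleles character vector of allele names.
#' @param hla_class `"I"` or `"II"`.
#' @param out_dir directory for all stage outputs.
#' @param stages stages to run, a subset of
#'   `c("simulate", "train", "calibrate", "deconv", "scan")`.
#' @param rank_cutoff retention cutoff in percent (class default when `NULL`).
#' @param strong_bound strong-binder bound in percent (class default when
#'   `NULL`); must be below `rank_cutoff`.
#' @param motif_sharpness,n_ligands_per_allele,decoy_fraction simulation
#'   parameters (see [ligandome_spec()]).
#' @param beta PSSM pseudocount weight.
#' @param background_M background sample size per length for calibration.
#' @param n_background_proteins,background_mean_length synthetic background
#'   proteome size.
#' @param n_variants number of synthetic variants for the scan stage.
#' @param peptide_tsv,proteome_fasta,variant_tsv optional external inputs;
#'   when `NULL` the simulate stage must be enabled to provide them.
#' @param predictor_json optional pre-trained predictor bundle (from
#'   [write_predictor_json()]) for runs that skip the train/calibrate stages.
#' @param seed integer master seed.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alleles, hla_class = "I", out_dir,
                            stages = c("simulate", "train", "calibrate",
                                       "deconv", "scan"),
                            rank_cutoff = NULL, strong_bound = NULL,
                            motif_sharpness = 0.8,
                            n_ligands_per_allele = 500L,
                            decoy_fraction = 0.2, beta = 50,
                            background_M = 2000L,
                            n_background_proteins = 150L,
                            background_mean_length = 350L,
                            n_variants = 5L,
                            peptide_tsv = NULL, proteome_fasta = NULL,
                            variant_tsv = NULL, predictor_json = NULL,
                            seed = 1L) {
  hla_class <- match.arg(hla_class, c("I", "II"))
  stages <- match.arg(stages, c("simulate", "train", "calibrate", "deconv",
                                "scan"), several.ok = TRUE)
  if (is.null(rank_cutoff)) rank_cutoff <- default_rank_cutoff(hla_class)
  if (is.null(strong_bound)) strong_bound <- default_strong_bound(hla_class)
  if (!(rank_cutoff > 0 && rank_cutoff < 100) ||
      !(strong_bound > 0 && strong_bound < 100)) {
    stop("rank cutoff and strong bound must lie in (0, 100)", call. = FALSE)
  }
  if (strong_bound >= rank_cutoff) {
    stop("strong bound (", strong_bound, ") must be below the rank cutoff (",
         rank_cutoff, ")", call. = FALSE)
  }
  if (is.na(suppressWarnings(as.integer(seed)))) {
    stop("seed must be an integer", call. = FALSE)
  }
  structure(list(alleles = as.character(alleles), hla_class = hla_class,
                 out_dir = out_dir, stages = stages,
                 rank_cutoff = rank_cutoff, strong_bound = strong_bound,
                 motif_sharpness = motif_sharpness,
                 n_ligands_per_allele = as.integer(n_ligands_per_allele),
                 decoy_fraction = decoy_fraction, beta = beta,
                 background_M = as.integer(background_M),
                 n_background_proteins = as.integer(n_background_proteins),
                 background_mean_length = as.integer(background_mean_length),
                 n_variants = as.integer(n_variants),
                 peptide_tsv = peptide_tsv, proteome_fasta = proteome_fasta,
                 variant_tsv = variant_tsv, predictor_json = predictor_json,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: the restored, re-validated config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the configured pipeline
#'
#' Executes the enabled stages in order (simulate, train, calibrate, deconv,
#' scan), writing each stage's outputs under `config$out_dir` and a final
#' `report.json` with the config echo, package version, seed and per-stage
#' record counts. Re-running with the same config reproduces all outputs
#' bitwise. A stage failure aborts the run with the failing stage named.
#'
#' Stage outputs: `training_ligands.tsv`, `peptides.tsv`, `truth.tsv`,
#' `background.fasta`, `variants.tsv` (simulate); `predictor.json`
#' (train/calibrate); `assignments.tsv`, `summary.tsv`, `top_epitopes.tsv`
#' (deconv); `scan_candidates.tsv`, `scan_kept.tsv` (scan).
#'
#' @param config a [pipeline_config()].
#' @return the run report, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "mhcdeconv",
                 version = as.character(utils::packageVersion("mhcdeconv")),
                 seed = config$seed, config = unclass(config),
                 stages = list())
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    counts <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <- list(status = "failed",
                                    error = conditionMessage(e))
      jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- c(list(status = "ok"), counts)
  }

  run_stage("simulate", function() {
    spec_train <- ligandome_spec(config$alleles, config$hla_class,
                                 motif_sharpness = config$motif_sharpness,
                                 n_ligands_per_allele = config$n_ligands_per_allele,
                                 decoy_fraction = 0,
                                 seed = derive_seed(config$seed, "simulate/train"))
    spec_detect <- ligandome_spec(config$alleles, config$hla_class,
                                  motif_sharpness = config$motif_sharpness,
                                  n_ligands_per_allele = config$n_ligands_per_allele,
                                  decoy_fraction = config$decoy_fraction,
                                  seed = derive_seed(config$seed, "simulate/detect"))
    # both draws share the per-allele ground-truth motifs
    motifs <- make_allele_motifs(ligandome_spec(
      config$alleles, config$hla_class,
      motif_sharpness = config$motif_sharpness,
      seed = derive_seed(config$seed, "simulate/motifs")))
    state$motifs <- motifs
    train <- sample_ligandome(spec_train, motifs)
    detect <- sample_ligandome(spec_detect, motifs)
    proteome <- sample_background_proteome(config$n_background_proteins,
                                           config$background_mean_length,
                                           seed = derive_seed(config$seed,
                                                              "simulate/background"))
    variants <- make_variant_fixture(proteome, config$n_variants,
                                     seed = derive_seed(config$seed,
                                                        "simulate/variants"),
                                     motifs = motifs)
    write_tsv(cbind(train$peptides, allele = train$truth$label),
              file.path(config$out_dir, "training_ligands.tsv"))
    write_peptide_list(detect$peptides, file.path(config$out_dir, "peptides.tsv"))
    write_tsv(detect$truth, file.path(config$out_dir, "truth.tsv"))
    write_fasta(proteome, file.path(config$out_dir, "background.fasta"))
    write_variant_table(variants, file.path(config$out_dir, "variants.tsv"))
    state$training <- cbind(train$peptides, allele = train$truth$label)
    state$peptides <- detect$peptides
    state$proteome <- proteome
    state$variants <- variants
    message("simulate: ", nrow(train$peptides), " training ligands, ",
            nrow(detect$peptides), " detected peptides, ",
            nrow(proteome), " background proteins, ",
            nrow(variants), " variants")
    list(n_training_ligands = nrow(train$peptides),
         n_detected_peptides = nrow(detect$peptides),
         n_background_proteins = nrow(proteome),
         n_variants = nrow(variants))
  })

  run_stage("train", function() {
    training <- state$training
    if (is.null(training)) {
      stop("train stage needs the simulate stage or a training ligand table")
    }
    models <- lapply(stats::setNames(config$alleles, config$alleles),
                     function(al) {
      lig <- training$sequence[training$allele == al]
      build_motif_model(lig, al, config$hla_class, beta = config$beta)
    })
    state$models <- models
    write_predictor_json(models, NULL,
                         file.path(config$out_dir, "predictor.json"))
    message("train: ", length(models), " allele model(s), beta = ",
            config$beta)
    list(n_models = length(models))
  })

  run_stage("calibrate", function() {
    proteome <- state$proteome %||% read_fasta(config$proteome_fasta)
    models <- state$models
    if (is.null(models)) {
      stop("calibrate stage needs models from the train stage")
    }
    calibrations <- lapply(models, function(m) {
      calibrate_ranks(m, proteome, M = config$background_M,
                      seed = derive_seed(config$seed, "calibrate"))
    })
    state$calibrations <- calibrations
    write_predictor_json(models, calibrations,
                         file.path(config$out_dir, "predictor.json"))
    message("calibrate: M = ", config$background_M, " per length against ",
            nrow(proteome), " background proteins")
    list(background_M = config$background_M)
  })

  load_predictor <- function() {
    if (is.null(state$models) || is.null(state$calibrations)) {
      if (is.null(config$predictor_json)) {
        stop("need train + calibrate stages or a predictor_json input")
      }
      bundle <- read_predictor_json(config$predictor_json)
      state$models <- bundle$models
      state$calibrations <- bundle$calibrations
    }
  }

  run_stage("deconv", function() {
    peptides <- state$peptides %||% read_peptide_list(config$peptide_tsv,
                                                      drop_invalid = TRUE)
    load_predictor()
    assignments <- deconvolute(peptides, state$models, state$calibrations,
                               rank_cutoff = config$rank_cutoff)
    write_tsv(assignments, file.path(config$out_dir, "assignments.tsv"))
    hist <- length_distribution(assignments)
    loads <- table(assignments$best_allele[assignments$retained])
    summary <- rbind(
      data.frame(metric = paste0("retained_length_", names(hist)),
                 value = as.integer(hist)),
      data.frame(metric = paste0("retained_allele_", names(loads)),
                 value = as.integer(loads)),
      data.frame(metric = c("n_input", "n_scored", "n_retained", "n_skipped"),
                 value = c(nrow(peptides), nrow(assignments),
                           sum(assignments$retained),
                           attr(assignments, "n_skipped"))))
    write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
    write_tsv(top_epitopes_per_allele(assignments, 3L),
              file.path(config$out_dir, "top_epitopes.tsv"))
    message("deconv: cutoff ", config$rank_cutoff, "%, ",
            sum(assignments$retained), "/", nrow(assignments),
            " retained, ", attr(assignments, "n_skipped"), " skipped")
    list(n_input = nrow(peptides), n_scored = nrow(assignments),
         n_retained = sum(assignments$retained),
         n_skipped = attr(assignments, "n_skipped"))
  })

  run_stage("scan", function() {
    proteome <- state$proteome %||% read_fasta(config$proteome_fasta)
    variants <- state$variants %||% read_variant_table(config$variant_tsv)
    load_predictor()
    bounds <- c(I = default_strong_bound("I"), II = default_strong_bound("II"))
    bounds[[config$hla_class]] <- config$strong_bound
    cand <- scan_variants(proteome, variants, state$models,
                          state$calibrations, strong_bounds = bounds)
    write_tsv(cand, file.path(config$out_dir, "scan_candidates.tsv"))
    kept <- summarize_scan(cand)
    write_tsv(kept, file.path(config$out_dir, "scan_kept.tsv"))
    message("scan: ", nrow(cand), " candidates, ", nrow(kept),
            " kept mutant epitopes (strong bound ", config$strong_bound, "%)")
    list(n_candidates = nrow(cand), n_kept = nrow(kept))
  })

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
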