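#' Pipeline run configuration
#'
#' Collects file paths and thresholds for a one-shot end-to-end run:
#' candidate derivation from peaks, route scoring, distillation, extended
#' scoring, survival evaluation and (optionally) decoy testing. Any of the
#' peak/TSS inputs may be omitted when a ready-made candidate file `ptg`
#' is given; the survival stage is skipped (with a warning) when
#' `clinical` is absent and `require_clinical = FALSE`.
#'
#' @param pathway Path to a pathway JSON (or SIF).
#' @param expr Path to the gene-by-subject log2-ratio TSV (first column
#'   `gene`).
#' @param clinical Optional clinical TSV (`subject_id`, `time_days`,
#'   `event`, optional `stage`).
#' @param peaks_conservative,peaks_optimal,tss Optional peak/TSS files for
#'   the candidate stage.
#' @param ptg Optional candidate gene-set file (one symbol per line).
#' @param indirect Optional file of indirect targets to augment with.
#' @param out_dir Output directory.
#' @param window,peak_mode,idr_mode Candidate-mapping parameters.
#' @param t_pr,t_pm,t_cu,t_cd,t_gu,t_gd Scoring / distillation thresholds.
#' @param sweep_grid,min_group Threshold-sweep parameters.
#' @param k_decoys,alpha,corr_cut Decoy-test parameters (`k_decoys = 0`
#'   disables the stage).
#' @param seed Integer seed (decoy construction is the only randomness).
#' @param require_clinical Error (rather than skip) when `clinical` is
#'   missing.
#' @return A `pd_run_config` list.
#' @export
run_config <- function(pathway, expr, clinical = NULL,
                       peaks_conservative = NULL, peaks_optimal = NULL,
                       tss = NULL, ptg = NULL, indirect = NULL,
                       out_dir = "pathdistill_run",
                       window = 2000, peak_mode = "upstream",
                       idr_mode = "intersect",
                       t_pr = 0.05, t_pm = 0.05, t_cu = 0.5, t_cd = -0.5,
                       t_gu = 0.3, t_gd = -0.3,
                       sweep_grid = seq(-1, 1, by = 0.1), min_group = 10,
                       k_decoys = 10, alpha = 0.05, corr_cut = 0.3,
                       seed = 1, require_clinical = FALSE) {
  cfg <- as.list(environment())
  for (nm in c("t_cu", "t_cd", "t_gu", "t_gd")) {
    check_threshold(cfg[[nm]], nm)
  }
  check_threshold(t_pr, "t_pr", lo = 0, hi = 1, open_lo = TRUE)
  check_threshold(t_pm, "t_pm", lo = 0, hi = 1, open_lo = TRUE)
  if (is.null(ptg) && (is.null(peaks_conservative) || is.null(tss))) {
    pd_abort("need either `ptg` or peak + TSS inputs", "pd_config_error")
  }
  structure(cfg, class = "pd_run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `pd_run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    pd_abort("YAML configs need the yaml package", "pd_io_error")
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Stages: candidate targets -> base route scoring -> distillation ->
#' extended scoring -> survival stratification and threshold sweep ->
#' decoy significance. Every stage's table is written under
#' `config$out_dir` and summarized in `manifest.json` (config, seed,
#' per-stage record counts and output checksums); outputs are a function
#' of inputs, config and seed only.
#'
#' @param config A `pd_run_config`.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pd_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()
  note <- function(stage, n) {
    inform(sprintf("[%s] %d records", stage, n))
    stages[[stage]] <<- n
  }

  # stage 1: candidate target genes
  if (!is.null(config$ptg)) {
    ptg <- read_gene_set(config$ptg)
  } else {
    cons <- read_peaks(config$peaks_conservative, idr_class = "conservative")
    tsst <- read_tss(config$tss)
    cons_set <- map_peaks_to_genes(cons, tsst, window = config$window,
                                   mode = config$peak_mode)
    if (!is.null(config$peaks_optimal)) {
      opt <- read_peaks(config$peaks_optimal, idr_class = "optimal")
      opt_set <- map_peaks_to_genes(opt, tsst, window = config$window,
                                    mode = config$peak_mode)
      ptg <- combine_idr_sets(cons_set, opt_set, mode = config$idr_mode)
    } else {
      ptg <- cons_set
    }
    indirect <- if (!is.null(config$indirect)) {
      readLines(config$indirect, warn = FALSE)
    } else character()
    ptg <- augment_with_indirect(ptg, indirect)
  }
  write_gene_set(ptg, out("ptg.txt"))
  note("targets", length(ptg$genes))

  # stage 2: pathway and routes
  pw <- read_pathway(config$pathway)
  if (nrow(pw$routes) == 0) pw <- enumerate_routes(pw)
  note("pathway", length(unique(pw$routes$route_id)))

  # stage 3-6: scoring and distillation
  expr <- readr::read_tsv(config$expr, show_col_types = FALSE)
  dist <- distill(pw, expr, ptg,
                  t_pr = config$t_pr, t_pm = config$t_pm,
                  t_cu = config$t_cu, t_cd = config$t_cd,
                  t_gu = config$t_gu, t_gd = config$t_gd)
  readr::write_tsv(as_tibble(dist$scores), out("scores.tsv"))
  readr::write_tsv(subject_scores(dist$scores), out("scores_subject.tsv"))
  readr::write_tsv(as_tibble(dist$selection), out("selection.tsv"))
  readr::write_tsv(as_tibble(dist$targets), out("targets.tsv"))
  write_pathway(dist$extended, out("extended_pathway.json"))
  jsonlite::write_json(as.list(dist$quality[1, ]), out("quality.json"),
                       auto_unbox = TRUE, digits = NA)
  note("distill", nrow(dist$targets))
  note("score", length(unique(dist$scores$subject_id)))

  # stage 5: survival evaluation
  if (!is.null(config$clinical)) {
    clinical <- as_clinical(readr::read_tsv(config$clinical,
                                            show_col_types = FALSE))
    groups <- stratify(dist$scores, score = "M", beta = 0)
    lr <- logrank_test(clinical, groups)
    jsonlite::write_json(
      list(statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
           n = lr$n),
      out("logrank.json"), auto_unbox = TRUE, digits = NA)
    sweep <- threshold_sweep(dist$scores, clinical,
                             grid = config$sweep_grid,
                             min_group = config$min_group)
    readr::write_tsv(sweep, out("sweep.tsv"))
    note("survival", sum(!sweep$skipped))
  } else if (isTRUE(config$require_clinical)) {
    pd_abort("clinical table required but not provided", "pd_config_error")
  } else {
    warn("no clinical table; survival stage skipped")
    stages[["survival"]] <- 0L
  }

  # stage 6: decoy significance
  if (config$k_decoys > 0) {
    report <- decoy_analysis(expr, dist$extended, k = config$k_decoys,
                             seed = config$seed, t_pr = config$t_pr,
                             t_pm = config$t_pm, alpha = config$alpha,
                             corr_cut = config$corr_cut)
    readr::write_tsv(as_tibble(report), out("decoys.tsv"))
    note("decoy", nrow(report))
  } else {
    stages[["decoy"]] <- 0L
  }

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "pathdistill",
    version = as.character(utils::packageVersion("pathdistill")),
    seed = config$seed,
    config = config[!map_lgl(config, is.null)],
    stages = stages,
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [simulate_cohort()] result as the pipeline's input
#' files: `expr.tsv`, `clinical.tsv`, `pathway.json`, `ptg.txt`,
#' `truth.json` (planted targets and subject states) and a `manifest.json`
#' recording the config and seed.
#'
#' @param cohort A `pd_synthetic_cohort`.
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expr = file.path(dir, "expr.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    pathway = file.path(dir, "pathway.json"),
    ptg = file.path(dir, "ptg.txt"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json"))
  readr::write_tsv(cohort$expr, paths$expr)
  readr::write_tsv(cohort$clinical, paths$clinical)
  write_pathway(cohort$pathway, paths$pathway)
  write_gene_set(cohort$ptg, paths$ptg)
  jsonlite::write_json(list(planted_up = cohort$planted_up,
                            planted_down = cohort$planted_down,
                            states = cohort$truth),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config = unclass(cohort$config),
                            seed = cohort$config$seed),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
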