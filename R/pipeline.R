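# Orchestration: a config-driven end-to-end run from synthetic or on-disk
# inputs to per-stage tables and a JSON report, plus the command-line entry
# point.  Every output directory carries a manifest (package version, seed,
# config hash); timing goes to stderr so that reports are byte-identical
# across reruns with the same seed.

.PIPELINE_STAGES <- c("spectra", "signatures", "apobec", "cin", "burden",
                      "clonality", "tcr", "compare")

.default_params <- function() {
  list(bin_size = 1e6, region_mb = 34, kd_threshold_nM = 500,
       k_range = 1:4, n_restarts = 30L, cin_mode = "absolute",
       context_freqs = default_context_freqs())
}

#' Load a cohort bundle from a directory written by [write_cohort()]
#' @param dir input directory.
#' @return a bundle list (same shape as [simulate_cohort()] output, minus
#'   config).
#' @export
read_cohort <- function(dir) {
  list(
    meta = read_sample_meta(file.path(dir, "samples.tsv")),
    mutations = read_mutations(file.path(dir, "mutations.maf.tsv")),
    segments = read_segments(file.path(dir, "tumor_segments.seg")),
    control_segments = read_segments(file.path(dir, "control_segments.seg")),
    neoantigens = read_neoantigens(file.path(dir, "neoantigens.tsv")),
    clonotypes = read_clonotypes(file.path(dir, "clonotypes.airr.tsv")),
    clusters = read_clusters(file.path(dir, "clusters.tsv"))
  )
}

.stage_spectra <- function(bundle, params) {
  tumor <- bundle$meta$sample_id[bundle$meta$group != "control"]
  spec <- build_spectrum(bundle$mutations, samples = tumor)
  df <- data.frame(sample_id = rownames(spec), spec, check.names = FALSE,
                   stringsAsFactors = FALSE)
  list(tables = list(spectrum = df),
       summary = list(n_samples = nrow(spec), n_snv = sum(spec)),
       spectrum = spec)
}

.stage_signatures <- function(bundle, params, spectrum, seed) {
  fit <- extract_signatures(spectrum, k_range = params$k_range,
                            n_restarts = params$n_restarts, seed = seed)
  catalog <- default_signature_catalog()
  matches <- do.call(rbind, lapply(fit$signatures$names, function(nm) {
    m <- match_to_catalog(fit$signatures$probs[nm, ], catalog)
    data.frame(component = nm, best_match = m$name, cosine = m$cosine,
               tie = m$tie, stringsAsFactors = FALSE)
  }))
  refit <- refit_exposures(spectrum,
                           signature_catalog(matches$best_match,
                                             catalog$probs[matches$best_match, ,
                                                           drop = FALSE]))
  sig_df <- data.frame(channel = .CHANNELS, t(fit$signatures$probs),
                       check.names = FALSE, stringsAsFactors = FALSE)
  expo_df <- data.frame(sample_id = rownames(refit$contributions),
                        refit$contributions, check.names = FALSE,
                        stringsAsFactors = FALSE)
  list(tables = list(signatures = sig_df, signature_matches = matches,
                     exposures = expo_df),
       summary = list(selected_k = fit$selected_k, stable = fit$stable,
                      matches = matches))
}

.stage_apobec <- function(bundle, params) {
  res <- apobec_enrichment(bundle$mutations,
                           context_freqs = params$context_freqs)
  genes <- tryCatch(apobec_group_genes(bundle$mutations, res),
                    relapsekit_error = function(e) NULL)
  tables <- list(apobec = res)
  if (!is.null(genes)) tables$apobec_genes <- genes
  list(tables = tables,
       summary = list(n_high = sum(res$label %in% "APOBEC_high"),
                      n_low = sum(res$label %in% "APOBEC_low")))
}

.stage_cin <- function(bundle, params) {
  zs <- segment_zscores(bundle$segments, bundle$control_segments,
                        bin_size = params$bin_size)
  ctrl_zs <- segment_zscores(bundle$control_segments, bundle$control_segments,
                             bin_size = params$bin_size)
  mode <- params$cin_mode
  scores <- cin_score(zs, mode = mode)
  ctrl_scores <- cin_score(ctrl_zs, mode = mode)
  thr <- cin_threshold(ctrl_scores$cin_score, scores$cin_score)
  scores$threshold <- thr$threshold
  scores$elevated <- thr$elevated
  list(tables = list(cin = scores, cin_controls = ctrl_scores),
       summary = list(mode = mode, threshold = thr$threshold,
                      n_elevated = sum(thr$elevated)),
       cin = scores)
}

.stage_burden <- function(bundle, params) {
  burden <- tmb(bundle$mutations, region_mb = params$region_mb)
  kept <- filter_neoantigens(bundle$neoantigens,
                             kd_threshold_nM = params$kd_threshold_nM)
  neo_pct <- neoantigen_percentage(bundle$mutations, kept)
  burden <- merge(burden, neo_pct, by = "sample_id", sort = FALSE)
  cl_frac <- cluster_neoantigen_fraction(bundle$mutations, kept)
  list(tables = list(burden = burden, cluster_neoantigen = cl_frac),
       summary = list(mean_tmb = mean(burden$tmb_per_mb),
                      n_kept_candidates = nrow(kept)),
       burden = burden)
}

.stage_clonality <- function(bundle, params) {
  retained <- retain_clusters(bundle$clusters)
  sharing <- sharing_summary(bundle$mutations, bundle$meta)
  list(tables = list(retained_clusters = retained, sharing_summary = sharing),
       summary = list(n_clusters_in = length(unique(paste(bundle$clusters$patient_id,
                                                          bundle$clusters$cluster_id))),
                      n_clusters_retained = length(unique(paste(retained$patient_id,
                                                                retained$cluster_id)))))
}

.stage_tcr <- function(bundle, params) {
  summ <- repertoire_summary(bundle$clonotypes)
  list(tables = list(repertoire = summ),
       summary = list(mean_sdi = mean(summ$sdi, na.rm = TRUE)),
       repertoire = summ)
}

.stage_compare <- function(bundle, params, computed) {
  metrics <- list()
  if (!is.null(computed$cin)) {
    metrics$cin_score <- data.frame(sample_id = computed$cin$sample_id,
                                    value = computed$cin$cin_score)
  }
  if (!is.null(computed$burden)) {
    metrics$tmb_per_mb <- data.frame(sample_id = computed$burden$sample_id,
                                     value = computed$burden$tmb_per_mb)
    metrics$neoantigen_pct <- data.frame(sample_id = computed$burden$sample_id,
                                         value = computed$burden$neoantigen_pct)
  }
  if (!is.null(computed$repertoire)) {
    metrics$sdi <- data.frame(sample_id = computed$repertoire$sample_id,
                              value = computed$repertoire$sdi)
  }
  if (!length(metrics)) rk_validation_error("compare stage: no upstream metrics available")
  rows <- lapply(names(metrics), function(nm) {
    res <- tryCatch(
      compare_groups(metrics[[nm]], bundle$meta,
                     c("primary_with_relapse", "relapsed"), paired = TRUE),
      relapsekit_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(metric = nm, comparison = "primary_with_relapse_vs_relapsed",
               paired = TRUE, statistic = res$statistic, n = res$n_used,
               p_value = res$p_value, exact = res$exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) rk_validation_error("compare stage: no comparison could be run")
  out$fdr <- bh_fdr(out$p_value)
  list(tables = list(comparisons = out), summary = list(comparisons = out))
}

#' Run the pipeline end to end
#'
#' Stages run in dependency order; a stage failure halts the run with an
#' error naming the stage, retaining the outputs already written.
#'
#' @param config list with fields: `simulate` (a [cohort_config()]) or
#'   `input_dir` (a directory of tables, see [read_cohort()]); optional
#'   `stages` (subset of spectra, signatures, apobec, cin, burden,
#'   clonality, tcr, compare); optional `params` overriding bin_size,
#'   region_mb, kd_threshold_nM, k_range, n_restarts, cin_mode,
#'   context_freqs; `seed`; `outdir`.
#' @return path of the output directory, invisibly; tables are written as
#'   TSV plus a `report.json` aggregating per-stage summaries.
#' @export
run_pipeline <- function(config) {
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% rk_validation_error("config$outdir is required")
  stages <- config$stages %||% .PIPELINE_STAGES
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) rk_validation_error("unknown stage(s): %s", paste(bad, collapse = ", "))
  params <- utils::modifyList(.default_params(), config$params %||% list())
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    bundle <- simulate_cohort(config$simulate)
  } else if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      rk_validation_error("input_dir does not exist: %s", config$input_dir)
    }
    bundle <- read_cohort(config$input_dir)
  } else {
    rk_validation_error("config needs either $simulate or $input_dir")
  }

  report <- list()
  computed <- list()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      rk_stop("relapsekit_stage_error", "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
    for (tn in names(res$tables)) {
      .write_tsv(res$tables[[tn]], file.path(outdir, paste0(tn, ".tsv")))
    }
    report[[name]] <<- res$summary
    for (extra in setdiff(names(res), c("tables", "summary"))) {
      computed[[extra]] <<- res[[extra]]
    }
    message(sprintf("[relapsekit] stage %-10s done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    invisible(NULL)
  }

  run_stage("spectra", function() .stage_spectra(bundle, params))
  run_stage("signatures", function() {
    if (is.null(computed$spectrum)) {
      computed$spectrum <<- .stage_spectra(bundle, params)$spectrum
    }
    .stage_signatures(bundle, params, computed$spectrum, seed)
  })
  run_stage("apobec", function() .stage_apobec(bundle, params))
  run_stage("cin", function() .stage_cin(bundle, params))
  run_stage("burden", function() .stage_burden(bundle, params))
  run_stage("clonality", function() .stage_clonality(bundle, params))
  run_stage("tcr", function() .stage_tcr(bundle, params))
  run_stage("compare", function() .stage_compare(bundle, params, computed))

  cfg_norm <- config
  cfg_norm$simulate <- if (!is.null(config$simulate)) unclass(config$simulate)
  cfg_norm$simulate$catalog <- NULL
  cfg_norm$outdir <- NULL      # paths must not affect the config hash
  cfg_norm$input_dir <- NULL
  cfg_txt <- paste(deparse(cfg_norm), collapse = "\n")
  tf <- tempfile(); writeLines(cfg_txt, tf)
  manifest <- list(package = "relapsekit",
                   version = as.character(utils::packageVersion("relapsekit")),
                   seed = seed, stages = stages,
                   config_md5 = unname(tools::md5sum(tf)))
  unlink(tf)
  jsonlite::write_json(list(manifest = manifest, stages = report),
                       file.path(outdir, "report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  invisible(outdir)
}

# ---------------------------------------------------------------------------
# Command-line interface.  Subcommands: simulate, run, spectra, signatures,
# apobec, cin, burden, clonality, tcr, compare.  Exit codes: 0 success,
# 2 validation/format error, 3 stage error.

.cli_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON config file"),
    optparse::make_option("--seed", type = "integer", default = 1L,
                          help = "master seed [default %default]"),
    optparse::make_option("--outdir", type = "character", default = "relapsekit_out",
                          help = "output directory [default %default]"),
    optparse::make_option("--indir", type = "character", default = NULL,
                          help = "input directory (tables written by 'simulate')"),
    optparse::make_option("--stages", type = "character", default = NULL,
                          help = "comma-separated stage subset")
  )
}

.cli_cohort_config <- function(opts) {
  args <- list(seed = opts$seed)
  if (!is.null(opts$config)) {
    user <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    keep <- intersect(names(user), names(formals(cohort_config)))
    args <- utils::modifyList(args, user[keep])
  }
  do.call(cohort_config, args)
}

#' Command-line entry point
#'
#' `relapsekit_main(c("simulate", "--seed", "7", "--outdir", "out"))` etc.
#' Subcommands: `simulate`, `run`, or a single analysis stage (`spectra`,
#' `signatures`, `apobec`, `cin`, `burden`, `clonality`, `tcr`, `compare`)
#' applied to a directory of tables via `--indir`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return integer exit status, invisibly (0 ok, 2 validation error,
#'   3 stage error).
#' @export
relapsekit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: relapsekit <simulate|run|", paste(.PIPELINE_STAGES, collapse = "|"),
            "> [--config F] [--seed N] [--outdir D] [--indir D] [--stages a,b]")
    return(invisible(2L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = .cli_options())
  opts <- optparse::parse_args(parser, args = args[-1])
  status <- tryCatch({
    if (cmd == "simulate") {
      cfg <- .cli_cohort_config(opts)
      bundle <- simulate_cohort(cfg)
      write_cohort(bundle, opts$outdir)
      message("[relapsekit] cohort written to ", opts$outdir)
    } else if (cmd == "run") {
      stages <- if (is.null(opts$stages)) .PIPELINE_STAGES else
        strsplit(opts$stages, ",", fixed = TRUE)[[1]]
      run_pipeline(list(simulate = .cli_cohort_config(opts),
                        stages = stages, seed = opts$seed,
                        outdir = opts$outdir))
    } else if (cmd %in% .PIPELINE_STAGES) {
      if (is.null(opts$indir)) rk_validation_error("--indir is required for stage '%s'", cmd)
      stages <- if (cmd == "compare") c("cin", "burden", "tcr", "compare") else cmd
      run_pipeline(list(input_dir = opts$indir, stages = stages,
                        seed = opts$seed, outdir = opts$outdir))
    } else {
      rk_validation_error("unknown subcommand '%s'", cmd)
    }
    0L
  },
  relapsekit_stage_error = function(e) { message("error: ", conditionMessage(e)); 3L },
  relapsekit_error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(status)
}
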