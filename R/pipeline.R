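# End-to-end orchestration: simulate or ingest summary statistics,
# WLM-partition, harmonize to the raising allele, pool per-allele effects,
# fit the dose-response slope, and run the individual-level cohort stage.
# Every run writes tab-delimited stage outputs plus a JSON manifest with
# input/output digests so results are attributable to (inputs, config,
# seed).

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    sd_grams = 484,
    palindrome_freq_limit = 0.42,
    palindromic_action = "freq",
    pool_model = "random",
    weight_power = 2,
    simulate = list(
      n_snps = 14,
      n_own = 50000,
      n_offspring = 50000,
      cohort_sizes = c(alspac = 4000, bib = 1900, efsoch = 700,
                       hapo = 1800),
      beta_maternal = 0,
      proportionality_slope = 0.124,
      noise_sd = 1
    ),
    inputs = NULL  # named paths: instruments, own, offspring (optional)
  )
}

#' Validate and complete a pipeline configuration
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults: `seed`, `sd_grams`, `palindrome_freq_limit`,
#'   `palindromic_action`, `pool_model` (`"random"` or `"fixed"`),
#'   `weight_power`, the `simulate` block (`n_snps`, `n_own`,
#'   `n_offspring`, `cohort_sizes`, `beta_maternal`,
#'   `proportionality_slope`, `noise_sd`) and optionally `inputs`
#'   (paths `instruments`, `own`, `offspring`) to run on real files instead
#'   of simulated ones.
#' @return Completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("pipeline config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("config error: pipeline config must be a list or a YAML path",
         call. = FALSE)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  if (!cfg$pool_model %in% c("random", "fixed"))
    stop("config error: pool_model must be 'random' or 'fixed'",
         call. = FALSE)
  if (!cfg$palindromic_action %in% c("freq", "drop"))
    stop("config error: palindromic_action must be 'freq' or 'drop'",
         call. = FALSE)
  if (!is.null(cfg$inputs)) {
    missing <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
    if (length(missing))
      stop("pipeline pre-flight failure: input file(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.write_stage <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) ingest the instrument list and the own/offspring
#' birth-weight summary statistics — simulated from the configuration when
#' no input files are given; (2) WLM partition into maternal-adjusted fetal
#' effects; (3) harmonization of the fetal effects to the
#' adiposity-raising allele; (4) per-allele meta-analysis across the
#' instrument set with conversion to grams; (5) weighted dose-response
#' regression; (6) when simulating, the individual-level cohort stage
#' (standardize, per-SNP adjusted fits, cross-cohort fixed-effects
#' pooling). Any stage failure aborts with the stage name. Outputs are a
#' deterministic function of (inputs, config, seed).
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`wlm`, `harmonized`,
#'   `pooled_sd`, `pooled_grams`, `dose`, `cohort`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  counts <- list()
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  message("[ingest] preparing instrument and summary-statistic tables")
  if (is.null(cfg$inputs)) {
    sim <- cfg$simulate
    base_cfg <- function(n, label, seed_off)
      duo_config(n_individuals = n, n_snps = sim$n_snps,
                 beta_maternal = sim$beta_maternal,
                 proportionality_slope = sim$proportionality_slope,
                 noise_sd = sim$noise_sd, sd_grams = cfg$sd_grams,
                 cohort = label, seed = cfg$seed + seed_off)
    own_cohort <- stage("ingest", simulate_duo_cohort(
      base_cfg(sim$n_own, "gwas-own", 11L)))
    off_cohort <- stage("ingest", simulate_duo_cohort(
      base_cfg(sim$n_offspring, "gwas-offspring", 23L)))
    ss <- stage("ingest", duo_summary_stats(own_cohort, off_cohort))
    own <- ss$own; offspring <- ss$offspring
    instruments <- stage("ingest", instrument_sumstats(own_cohort$config))
  } else {
    instruments <- stage("ingest", instrument_set(
      read_sumstats(cfg$inputs$instruments)))
    own <- stage("ingest", read_sumstats(cfg$inputs$own))
    offspring <- stage("ingest", read_sumstats(cfg$inputs$offspring))
  }
  files <- c(files, .write_stage(own, out_dir, "sumstats_own"),
             .write_stage(offspring, out_dir, "sumstats_offspring"),
             .write_stage(as.data.frame(instruments), out_dir,
                          "instruments"))
  counts$instruments <- nrow(instruments)

  message("[wlm] partitioning fetal and maternal effects")
  wlm <- stage("wlm", partition_table(own, offspring))
  counts$wlm_snps <- nrow(wlm$estimates)
  counts$wlm_missing <- length(wlm$missing)
  fetal <- wlm_to_sumstats(wlm$estimates, "fetal")
  files <- c(files, .write_stage(wlm$estimates, out_dir, "wlm_estimates"),
             .write_stage(fetal, out_dir, "wlm_fetal_sumstats"))

  message("[harmonize] aligning to the adiposity-raising allele")
  joined <- stage("harmonize", join_instruments(instruments, fetal))
  harm <- stage("harmonize", harmonize_pairs(
    joined$pairs, palindrome_freq_limit = cfg$palindrome_freq_limit,
    palindromic_action = cfg$palindromic_action))
  kept <- harm[harm$resolution != "dropped", , drop = FALSE]
  counts$harmonized <- nrow(kept)
  counts$harmonization_dropped <- sum(harm$resolution == "dropped")
  counts$join_missing <- length(joined$missing)
  files <- c(files, .write_stage(harm, out_dir, "harmonized"))

  message("[pool] per-allele meta-analysis across the instrument set")
  pooler <- if (cfg$pool_model == "random") pool_random else pool_fixed
  pooled_sd <- stage("pool", pooler(kept$aligned_outcome_beta,
                                    kept$outcome_se))
  pooled_g <- sd_to_grams(pooled_sd, cfg$sd_grams)
  pool_tab <- rbind(cbind(units = "SD", as.data.frame(pooled_sd)),
                    cbind(units = "grams", as.data.frame(pooled_g)))
  files <- c(files, .write_stage(pool_tab, out_dir, "pooled_effect"))

  message("[dose] weighted dose-response regression")
  dose <- stage("dose", fit_weighted_slope(
    kept$aligned_exposure_beta, kept$aligned_outcome_beta, kept$outcome_se,
    weight_power = cfg$weight_power))
  files <- c(files, .write_stage(as.data.frame(dose), out_dir,
                                 "dose_response"))

  cohort_res <- NULL
  if (is.null(cfg$inputs) && length(cfg$simulate$cohort_sizes) >= 2) {
    message("[cohort] individual-level cohort stage")
    sizes <- cfg$simulate$cohort_sizes
    cohorts <- lapply(seq_along(sizes), function(i)
      stage("cohort", simulate_duo_cohort(
        base_cfg(sizes[[i]], names(sizes)[i] %||% paste0("cohort", i),
                 100L + i))))
    cohort_res <- stage("cohort", cohort_pipeline(cohorts))
    counts$cohorts <- length(cohorts)
    files <- c(files,
               .write_stage(cohort_res$per_cohort, out_dir,
                            "cohort_assoc"),
               .write_stage(cohort_res$pooled, out_dir, "cohort_pooled"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("duogenie")),
    seed = cfg$seed,
    config_digest = unname(.digest_object(cfg)),
    inputs = if (is.null(cfg$inputs)) "simulated"
             else lapply(cfg$inputs, function(p)
               unname(tools::md5sum(p))),
    outputs = setNames(as.list(unname(tools::md5sum(files))),
                       basename(files)),
    counts = counts,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(wlm = wlm, harmonized = harm, pooled_sd = pooled_sd,
                 pooled_grams = pooled_g, dose = dose,
                 cohort = cohort_res, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a

.digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(x, file = tmp)
  tools::md5sum(tmp)
}
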