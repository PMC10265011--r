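# Pipeline orchestration: config handling, file validation, and the four
# stage runners (simulate, fit, associate, report). A thin command-line
# wrapper over these functions ships in inst/scripts/ia-pipeline.R.

#' Read a pipeline configuration file
#'
#' JSON (.json) or YAML (.yml/.yaml; needs the yaml package) with optional
#' sections `paths`, `beliefs`, `priors`, `mcmc`, `simulation`,
#' `association`. Every section maps one-to-one onto the corresponding
#' constructor ([belief_config()], [prior_spec()], [mcmc_config()],
#' [simulation_config()]); omitted fields take the package defaults.
#'
#' @param path config file path.
#' @return An object of class `"ia_pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param x a named list with the sections above (e.g. parsed JSON).
#' @export
as_pipeline_config <- function(x) {
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    args <- args[intersect(names(args), names(formals(ctor)))]
    do.call(ctor, args)
  }
  sim_args <- x$simulation
  if (!is.null(sim_args$effects_beta))
    sim_args$effects_beta <- unlist(sim_args$effects_beta)
  if (!is.null(sim_args$effects_alpha))
    sim_args$effects_alpha <- unlist(sim_args$effects_alpha)
  beliefs <- build(belief_config, x$beliefs)
  if (!is.null(sim_args)) sim_args$beliefs <- beliefs
  structure(list(paths = x$paths,
                 beliefs = beliefs,
                 priors = build(prior_spec, x$priors),
                 mcmc = build(mcmc_config, x$mcmc),
                 simulation = build(simulation_config, sim_args),
                 association = x$association),
            class = "ia_pipeline_config")
}

#' Validate a behaviour table against a context schedule
#'
#' Checks required columns and that every (game, context_param,
#' chosen_label) lies on the corresponding option grid; errors carry row
#' numbers (so e.g. a dictator-game allocation of JPY 150 is rejected).
#'
#' @param behaviour behaviour data frame.
#' @param contexts context list.
#' @return The table, invisibly, when valid.
#' @export
validate_behaviour <- function(behaviour, contexts) {
  need <- c("participant_id", "game", "context_param", "chosen_label")
  miss <- setdiff(need, names(behaviour))
  if (length(miss))
    stop("behaviour table is missing column(s): ",
         paste(miss, collapse = ", "))
  match_choices(behaviour, contexts)  # row-numbered errors on failure
  invisible(behaviour)
}

#' Run the simulation stage
#'
#' @param config an `"ia_pipeline_config"` (or a [simulation_config()]).
#' @param out_dir output directory (default `config$paths$out_dir` or ".").
#' @return The [generate_study()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  sim <- if (inherits(config, "ia_sim_config")) config else config$simulation
  out_dir <- out_dir %||% config$paths$out_dir %||% "."
  study <- generate_study(sim, dir = out_dir)
  log_stage(out_dir, "simulate", sim, sim$seed,
            list(n = sim$n_participants))
  message(sprintf("[simulate] n = %d participants, seed = %d -> %s",
                  sim$n_participants, sim$seed, out_dir))
  invisible(study)
}

#' Run the estimation stage
#'
#' Reads the behaviour CSV, validates it against the schedule implied by the
#' configured beliefs, fits every participant and writes the estimates CSV.
#'
#' @param config an `"ia_pipeline_config"`.
#' @param behaviour_csv behaviour file (default `config$paths$behaviour`).
#' @param out_csv estimates output (default `config$paths$estimates` or
#'   "estimates.csv").
#' @return The `"ia_cohort"` estimates table, invisibly.
#' @export
run_fit <- function(config, behaviour_csv = NULL, out_csv = NULL) {
  behaviour_csv <- behaviour_csv %||% config$paths$behaviour
  out_csv <- out_csv %||% config$paths$estimates %||% "estimates.csv"
  if (is.null(behaviour_csv) || !file.exists(behaviour_csv))
    stop("behaviour CSV not found: ", behaviour_csv)
  behaviour <- utils::read.csv(behaviour_csv, stringsAsFactors = FALSE,
                               colClasses = c(chosen_label = "character"))
  contexts <- game_schedule(config$beliefs)
  validate_behaviour(behaviour, contexts)
  est <- estimate_cohort(behaviour, contexts, config$priors, config$mcmc)
  write_estimates_csv(est, out_csv)
  log_stage(dirname(out_csv), "fit", config$mcmc, config$mcmc$seed,
            list(n = nrow(est), n_nonconverged = sum(!est$converged)))
  message(sprintf("[fit] %d participants, %d non-converged, seed = %d -> %s",
                  nrow(est), sum(!est$converged), config$mcmc$seed, out_csv))
  invisible(est)
}

#' Run the association stage
#'
#' Merges estimates and genotypes and writes the ANCOVA report
#' (association.tsv) and pairwise-contrast (contrasts.tsv) tables.
#'
#' @param config an `"ia_pipeline_config"`; `config$association` may set
#'   `use_334`, `sex_interaction` and `covariates`.
#' @param estimates_csv,genotypes_csv input files (defaults from
#'   `config$paths`).
#' @param out_dir output directory.
#' @return The `"ia_association"` object, invisibly.
#' @export
run_associate <- function(config, estimates_csv = NULL, genotypes_csv = NULL,
                          out_dir = NULL) {
  estimates_csv <- estimates_csv %||% config$paths$estimates
  genotypes_csv <- genotypes_csv %||% config$paths$genotypes
  out_dir <- out_dir %||% config$paths$out_dir %||% "."
  for (f in c(estimates_csv, genotypes_csv))
    if (is.null(f) || !file.exists(f)) stop("input CSV not found: ", f)
  est <- read_estimates_csv(estimates_csv)
  gen <- utils::read.csv(genotypes_csv, stringsAsFactors = FALSE)
  opts <- config$association
  assoc <- associate_preferences(
    est, gen,
    covariates = opts$covariates %||% "age",
    use_334 = isTRUE(opts$use_334),
    sex_interaction = isTRUE(opts$sex_interaction))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(assoc$anova, file.path(out_dir, "association.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(assoc$contrasts))
    utils::write.table(assoc$contrasts, file.path(out_dir, "contrasts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage(out_dir, "associate", opts %||% list(), NA,
            list(n = assoc$n))
  message(sprintf("[associate] n = %d -> %s", assoc$n, out_dir))
  invisible(assoc)
}

#' Run the report stage
#'
#' Prints (and returns) the genotype-distribution report for any genotype
#' CSV: counts, percentages, HWE chi-squares and the 334 bp carrier split.
#'
#' @param config an `"ia_pipeline_config"` (optional if `genotypes_csv`
#'   given).
#' @param genotypes_csv genotype file (default `config$paths$genotypes`).
#' @return An `"ia_genotype_report"`, invisibly.
#' @export
run_report <- function(config = NULL, genotypes_csv = NULL) {
  genotypes_csv <- genotypes_csv %||% config$paths$genotypes
  if (is.null(genotypes_csv) || !file.exists(genotypes_csv))
    stop("genotype CSV not found: ", genotypes_csv)
  gen <- utils::read.csv(genotypes_csv, stringsAsFactors = FALSE)
  rep <- genotype_report(gen)
  print(rep)
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One structured log line per stage: timestamp, stage, md5 of the JSON-ified
# config, seed, and package/R versions. Appended to <out_dir>/pipeline.log.
log_stage <- function(out_dir, stage, config, seed, extra = list()) {
  if (is.null(out_dir) || !dir.exists(out_dir)) return(invisible(NULL))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass_all(config),
                                           auto_unbox = TRUE, digits = NA,
                                           null = "null", force = TRUE)),
             tmp)
  line <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 stage = stage,
                 config_md5 = unname(tools::md5sum(tmp)),
                 seed = seed,
                 iafit = as.character(utils::packageVersion("iafit")),
                 R = paste(R.version$major, R.version$minor, sep = ".")),
            extra)
  cat(as.character(jsonlite::toJSON(line, auto_unbox = TRUE, digits = NA)),
      "\n", sep = "", file = file.path(out_dir, "pipeline.log"),
      append = TRUE)
  invisible(NULL)
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}
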