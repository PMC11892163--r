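#' Configuration for a full bidirectional mediation analysis grid
#'
#' Declares the whole analysis: the cohort (supplied records or a generator
#' invocation), the grid of cells (sexes x exposure contrasts x causal
#' directions x substances), the adjustment covariates, and the bootstrap
#' settings. Each grid cell resolves to one [mediation_spec()].
#'
#' Exposure contrasts: `"lifetime"` compares any lifetime exposure vs none;
#' `"childhood"` compares childhood-onset exposure vs none, dropping records
#' whose exposure began later; `"repeated"` compares repeated exposure vs
#' none, dropping single-exposure records (the small-cell sensitivity
#' contrast). Directions: `"substance_mediator"` (substance use mediating
#' the path to depression) and `"depression_mediator"` (depression mediating
#' the path to substance use) — the two recursive orderings.
#'
#' @param data Optional tibble of records; when `NULL`, a synthetic cohort
#'   is generated per `simulate`.
#' @param simulate List `(n, seed)` for the generator (both sexes, default
#'   n = 5000 per sex, seed 42); ignored when `data` is given.
#' @param sexes,contrasts,directions,substances Character vectors defining
#'   the grid.
#' @param depression Name of the depression column.
#' @param covariates Adjustment covariates (default age group, education).
#' @param interaction,covariate_evaluation Passed to [mediation_spec()].
#' @param design A [survey_design()].
#' @param bootstrap A [bootstrap_config()], or `NULL` for point estimates
#'   only.
#' @param apply_exclusions Run [apply_exclusion_flow()] first (default
#'   `TRUE` when the recent-exposure flag column is present).
#' @param out_dir Directory for CSV/JSON outputs, or `NULL` to skip writing.
#' @param quiet Suppress per-cell progress messages.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(data = NULL,
                            simulate = list(n = 5000, seed = 42),
                            sexes = c("female", "male"),
                            contrasts = c("lifetime", "childhood"),
                            directions = c("substance_mediator",
                                           "depression_mediator"),
                            substances = c("hazardous_alcohol", "heavy_tobacco",
                                           "frequent_cannabis"),
                            depression = "depression",
                            covariates = c("age_group", "education"),
                            interaction = TRUE,
                            covariate_evaluation = "weighted_mean",
                            design = survey_design(),
                            bootstrap = NULL,
                            apply_exclusions = TRUE,
                            out_dir = NULL,
                            quiet = FALSE) {
  structure(
    list(data = data, simulate = simulate, sexes = sexes,
         contrasts = contrasts, directions = directions,
         substances = substances, depression = depression,
         covariates = covariates, interaction = interaction,
         covariate_evaluation = covariate_evaluation, design = design,
         bootstrap = bootstrap, apply_exclusions = apply_exclusions,
         out_dir = out_dir, quiet = quiet),
    class = "analysis_config"
  )
}

CONTRAST_COLUMNS <- c(lifetime = "sae_lifetime", childhood = "sae_childhood",
                      repeated = "sae_repeated")

#' Validate an analysis configuration
#'
#' Always returns a findings report; [run_grid()] refuses to run when any
#' finding is fatal.
#'
#' @param config An [analysis_config()].
#' @return A tibble with columns `level` (`"fatal"` or `"note"`) and
#'   `message`; zero rows when the configuration is fully valid.
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1]] <<- tibble(level = level, message = msg)
  }
  if (!length(config$substances)) add("fatal", "substance (mediator) list is empty")
  if (!length(config$sexes)) add("fatal", "sex list is empty")
  bad_contrast <- setdiff(config$contrasts, names(CONTRAST_COLUMNS))
  if (length(bad_contrast)) {
    add("fatal", paste0("unknown contrast: ", paste(bad_contrast, collapse = ", ")))
  }
  if (config$depression %in% config$substances) {
    add("fatal", "mediator and outcome coincide: depression listed among substances")
  }
  need_cols <- c("sex", unname(CONTRAST_COLUMNS[config$contrasts]),
                 config$substances, config$depression, config$covariates)
  if (!is.null(config$data)) {
    absent <- setdiff(need_cols, names(config$data))
    for (nm in absent) add("fatal", paste0("unknown column: ", nm))
  } else {
    add("note", paste0("no data supplied; will simulate n = ",
                       config$simulate$n, " per sex with seed ",
                       config$simulate$seed))
  }
  if (is.null(config$bootstrap)) {
    add("note", "no bootstrap config; point estimates only")
  }
  if (length(findings)) bind_rows(findings) else
    tibble(level = character(), message = character())
}

# Recode one exposure contrast: returns data subset with the exposure
# column name, or NULL if the contrast column is absent.
build_contrast <- function(data, contrast) {
  col <- CONTRAST_COLUMNS[[contrast]]
  if (!col %in% names(data)) return(NULL)
  if (contrast != "lifetime" && "sae_lifetime" %in% names(data)) {
    keep <- !(data$sae_lifetime %in% 1 & !(data[[col]] %in% 1))
    data <- data[keep, , drop = FALSE]
  }
  list(data = data, exposure = col)
}

#' Run the full mediation analysis grid
#'
#' Executes the pre-analysis exclusion flow, stratifies by sex, and for
#' every grid cell applies listwise deletion, fits the mediation models,
#' and (when a bootstrap config is present) computes percentile intervals.
#' A cell that fails is recorded in the manifest and the remaining cells
#' are still produced.
#'
#' When `out_dir` is set, writes one results CSV per direction, a
#' descriptives CSV (weighted prevalences of exposure and health
#' variables by sex) and a JSON run manifest (configuration, per-cell
#' sample sizes, dropped-replicate tallies, software versions).
#'
#' @param config An [analysis_config()].
#' @return A list: `results` (tibble, one row per cell with OR/CI columns
#'   per effect, PM, n_used), `descriptives`, `manifest`, `estimates`
#'   (the underlying `mediation_estimate` objects).
#' @export
run_grid <- function(config) {
  findings <- validate_config(config)
  if (any(findings$level == "fatal")) {
    abort(paste0("fatal configuration findings:\n  ",
                 paste(findings$message[findings$level == "fatal"],
                       collapse = "\n  ")))
  }
  say <- function(...) if (!config$quiet) message(...)

  data <- config$data
  if (is.null(data)) {
    data <- bind_rows(lapply(config$sexes, function(sx) {
      generate_cohort(cohort_params(sx), config$simulate$n,
                      seed = config$simulate$seed +
                        match(sx, c("female", "male")))
    }))
  }

  exclusions <- c(missing_exposure = 0L, recent_exposure = 0L)
  if (config$apply_exclusions && all(c("sae_lifetime", "sae_recent") %in% names(data))) {
    data <- apply_exclusion_flow(data)
    exclusions <- exclusion_counts(data)
    say("exclusion flow: removed ", exclusions[1], " missing-exposure and ",
        exclusions[2], " recent-exposure records")
  }

  desc_vars <- intersect(
    c(unname(CONTRAST_COLUMNS[config$contrasts]), config$substances,
      config$depression),
    names(data))
  descriptives <- bind_rows(lapply(config$sexes, function(sx) {
    d <- data[data$sex == sx, , drop = FALSE]
    out <- prevalence_table(d, desc_vars, config$design)
    out$sex <- sx
    out
  }))

  grid <- expand.grid(sex = config$sexes, contrast = config$contrasts,
                      direction = config$directions,
                      substance = config$substances,
                      stringsAsFactors = FALSE)
  rows <- list(); estimates <- list(); failures <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cell_id <- paste(g$sex, g$contrast, g$direction, g$substance, sep = "/")
    d_sex <- data[data$sex == g$sex, , drop = FALSE]
    bc <- build_contrast(d_sex, g$contrast)
    if (is.null(bc)) {
      failures[[cell_id]] <- "contrast column absent"
      next
    }
    if (g$direction == "substance_mediator") {
      mediator <- g$substance; outcome <- config$depression
    } else {
      mediator <- config$depression; outcome <- g$substance
    }
    spec <- mediation_spec(bc$exposure, mediator, outcome,
                           covariates = config$covariates,
                           interaction = config$interaction,
                           covariate_evaluation = config$covariate_evaluation)
    est <- tryCatch({
      if (is.null(config$bootstrap)) {
        run_mediation(bc$data, spec, config$design)
      } else {
        bootstrap_mediation(bc$data, spec, config$design, config$bootstrap)
      }
    }, error = function(e) e)
    if (inherits(est, "error")) {
      say("cell ", cell_id, " failed: ", conditionMessage(est))
      failures[[cell_id]] <- conditionMessage(est)
      next
    }
    say("cell ", cell_id, ": OR_TE = ",
        sprintf("%.2f", est$effects$or[1]), ", n = ", est$n_used)
    estimates[[cell_id]] <- est
    eff <- est$effects
    wide <- tibble(
      sex = g$sex, contrast = g$contrast, direction = g$direction,
      mediator = mediator, outcome = outcome,
      or_te = eff$or[1], te_low = eff$ci_low[1], te_high = eff$ci_high[1],
      or_nde = eff$or[2], nde_low = eff$ci_low[2], nde_high = eff$ci_high[2],
      or_nie = eff$or[3], nie_low = eff$ci_low[3], nie_high = eff$ci_high[3],
      pm = est$pm, pm_percent = round(100 * est$pm, 1),
      n_used = est$n_used, n_bootstrap_ok = est$n_bootstrap_ok,
      outcome_prevalence = est$outcome_prevalence
    )
    rows[[cell_id]] <- wide
  }
  results <- bind_rows(rows)

  manifest <- list(
    package_version = as.character(utils::packageVersion("svymediate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    configuration = list(
      simulate = if (is.null(config$data)) config$simulate,
      sexes = config$sexes, contrasts = config$contrasts,
      directions = config$directions, substances = config$substances,
      covariates = config$covariates, interaction = config$interaction,
      covariate_evaluation = config$covariate_evaluation,
      bootstrap = if (!is.null(config$bootstrap)) unclass(config$bootstrap)
    ),
    exclusions = as.list(exclusions),
    cells = lapply(estimates, function(e) {
      list(n_used = e$n_used, n_bootstrap_ok = e$n_bootstrap_ok,
           outcome_prevalence = e$outcome_prevalence,
           dropped_replicates = if (!is.null(e$bootstrap))
             as.list(e$bootstrap$failures))
    }),
    failed_cells = failures
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (dir_nm in unique(results$direction)) {
      readr::write_csv(results[results$direction == dir_nm, ],
                       file.path(config$out_dir,
                                 paste0("results_", dir_nm, ".csv")))
    }
    readr::write_csv(descriptives, file.path(config$out_dir, "descriptives.csv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }

  list(results = results, descriptives = descriptives, manifest = manifest,
       estimates = estimates)
}
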