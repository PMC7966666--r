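#' Reproducible pipeline runs
#'
#' Glue binding the stages into a seeded, fully deterministic run:
#' simulate (or read) observations, estimate and apply registration
#' completeness, screen survey series, fit the spline model (or the sparse
#' fallback), reinsert crisis mortality, split by age band, aggregate to
#' regions, and validate out of sample.  Artifacts are plain CSV/JSON and
#' every run is a pure function of (config, seed).
#'
#' @name cli_io
NULL

#' Read an observation table from CSV
#'
#' The schema is the package observation schema
#' ([validate_observations()]); `q` must be stored per 1 -- a per-1000
#' file is refused rather than guessed at (values at or above 1 fail
#' validation).
#'
#' @param path CSV path.
#' @return Validated observation data frame.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("country", "series_id", "source_type", "ref_time",
                "collection_time", "age_start", "age_width", "q", "se_logq")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("observation file lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"excluded" %in% names(obs)) obs$excluded <- FALSE
  obs$excluded <- as.logical(obs$excluded)
  if (!"exclusion_reason" %in% names(obs)) obs$exclusion_reason <- NA_character_
  obs$exclusion_reason <- as.character(obs$exclusion_reason)
  bad <- which(!obs$source_type %in% source_types())
  if (length(bad)) {
    stop(sprintf("unknown source_type at data row(s) %s: %s",
                 paste(utils::head(bad, 5), collapse = ", "),
                 paste(unique(obs$source_type[bad]), collapse = ", ")))
  }
  bad_q <- which(!is.finite(obs$q) | obs$q < 0 | obs$q >= 1)
  if (length(bad_q)) {
    stop(sprintf(paste0("q outside [0, 1) at data row(s) %s;",
                        " probabilities must be stored per 1, not per 1000"),
                 paste(utils::head(bad_q, 5), collapse = ", ")))
  }
  validate_observations(obs)
  obs
}

#' Write a table to CSV
#'
#' @param x Data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Integer seed (mandatory for a run).
#' @param outdir Output directory.
#' @param n_countries,n_regions Synthetic-world size.
#' @param stages Character vector of stages to execute, in pipeline order.
#' @param cutoff_year Out-of-sample collection cutoff (default 2013).
#' @param screen_level Prediction-interval level of the quality screen.
#' @param report_years Years of the headline tables.
#' @param b3 A [b3_config()]; its seed is overridden by `seed`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed, outdir = tempfile("youthmort-run-"),
                       n_countries = 20, n_regions = 4,
                       stages = c("simulate", "completeness", "screen",
                                  "fit", "crisis", "split", "aggregate",
                                  "validate"),
                       cutoff_year = 2013, screen_level = 0.95,
                       report_years = c(1990, 2000, 2019),
                       b3 = b3_config()) {
  if (missing(seed)) stop("a seed is mandatory")
  b3$seed <- seed
  structure(list(seed = seed, outdir = outdir, n_countries = n_countries,
                 n_regions = n_regions, stages = stages,
                 cutoff_year = cutoff_year, screen_level = screen_level,
                 report_years = report_years, b3 = b3),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [run_config()] arguments, with `b3:`
#'   holding [b3_config()] overrides.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  b3 <- do.call(b3_config, y$b3 %||% list())
  args <- y[setdiff(names(y), "b3")]
  args$b3 <- b3
  do.call(run_config, args)
}

#' Execute the estimation pipeline on a synthetic world
#'
#' Stages run in order; each records counts entering and leaving it in the
#' run log.  The full run writes truth, observations, screen report,
#' country summaries, headline tables and the validation report as CSV/JSON
#' under `config$outdir`.
#'
#' @param config A [run_config()].
#' @return Invisible list with the world, the fitted objects, the
#'   aggregate, the tables, the validation report and the run `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("youthmort run seed=%d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = " > ")))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(s) s %in% config$stages
  if (!stage("simulate")) stop("this driver runs from the synthetic world; include the 'simulate' stage")

  world <- simulate_world(config$n_countries, config$n_regions, config$seed)
  obs <- world$observations
  note("simulate: %d observations, %d countries", nrow(obs), config$n_countries)
  write_summaries(world$truth, file.path(config$outdir, "truth.csv"))
  write_summaries(obs, file.path(config$outdir, "observations.csv"))
  write_summaries(world$population, file.path(config$outdir, "population.csv"))

  if (stage("completeness")) {
    n_adj <- 0
    for (cc in names(world$true_completeness)) {
      c_true <- world$true_completeness[[cc]]
      if (is.na(c_true) || c_true >= 1) next
      # census universe sized to the country: the youth bands are ~2/25 of it
      total_pop <- 12 * band_person_years(world$population, cc, 2005)
      tabs <- simulate_stable_population(completeness = c_true,
                                         size = max(1e6, total_pop),
                                         seed = child_seed(config$seed, 300 + match(cc, names(world$true_completeness))))
      est <- ggb_fit(tabs$census1, tabs$census2, tabs$deaths, tabs$t1, tabs$t2)
      rows <- obs$country == cc
      obs[rows, ] <- adjust_vr_series(obs[rows, ], est)
      n_adj <- n_adj + 1
    }
    note("completeness: adjusted VR for %d countries", n_adj)
  }

  if (stage("screen")) {
    ref <- reference_pairs(generate_truth(60, config$n_regions,
                                          child_seed(config$seed, 55)),
                           seed = child_seed(config$seed, 56))
    lq <- fit_logquad(ref)
    sc <- screen_surveys(obs, lq, config$screen_level)
    obs <- sc$observations
    note("screen: %d of %d series excluded",
         sum(sc$report$decision == "excluded"), nrow(sc$report))
    write_summaries(sc$report, file.path(config$outdir, "screen_report.csv"))
  }

  # crisis-year observations leave the likelihood before fitting
  if (stage("crisis") && nrow(world$events)) {
    for (i in seq_len(nrow(world$events))) {
      hit <- obs$country == world$events$country[i] &
        floor(obs$ref_time) == world$events$year[i] & !obs$excluded
      obs$excluded[hit] <- TRUE
      obs$exclusion_reason[hit] <- "crisis_year"
    }
    note("crisis: %d observations removed for crisis years",
         sum(obs$exclusion_reason == "crisis_year", na.rm = TRUE))
  }

  fit <- NULL; posts <- list(); validation <- NULL
  sparse_flags <- vapply(split(obs, obs$country), is_sparse, logical(1))
  if (stage("fit")) {
    dense <- names(sparse_flags)[!sparse_flags]
    fit <- fit_b3(obs[obs$country %in% dense, ], config = config$b3)
    if (stage("crisis")) fit <- crisis_adjust(fit, world$events, world$population)
    posts <- fit$posteriors
    note("fit: B3 on %d countries, %d sparse countries flagged",
         length(dense), sum(sparse_flags))
    if (any(sparse_flags)) {
      pairs <- sparse_training_pairs(fit, world$truth, world$region_map)
      mfit <- fit_mixed(pairs)
      for (cc in names(sparse_flags)[sparse_flags]) {
        tr <- world$truth[world$truth$country == cc, ]
        posts[[cc]] <- predict_sparse(
          data.frame(year = tr$year, u5mr = tr$q5_0_true),
          world$region_map$region[world$region_map$country == cc], mfit,
          country = cc, n_draws = nrow(fit$bias_draws),
          seed = child_seed(config$seed, 900 + match(cc, names(sparse_flags))))
      }
    }
    summ <- do.call(rbind, lapply(posts, summarize_posterior))
    summ$source <- vapply(summ$country, function(cc) posts[[cc]]$source, character(1))
    write_summaries(summ, file.path(config$outdir, "country_summaries.csv"))
  }

  agg <- NULL; tables <- NULL
  if (stage("split") && stage("fit")) {
    years_grid <- fit$years
    split_draws <- list()
    for (cc in names(posts)) {
      o5 <- obs[obs$country == cc & obs$age_start == 15 & obs$age_width == 5 &
                  !obs$excluded, ]
      rfit <- if (nrow(o5) >= 2) {
        fit_ratio_spline(ratio_observations(o5, posts[[cc]]), years_grid)
      } else {
        # no direct 5q15 measurements: use the generator-level mean share
        structure(list(years = years_grid,
                       r_hat = rep(0.46, length(years_grid)),
                       smoothing_penalty = Inf, n_obs_used = 0L),
                  class = "ratio_fit")
      }
      pc <- posts[[cc]]
      keep <- match(years_grid, pc$years)
      pc$draws <- pc$draws[, keep[!is.na(keep)], drop = FALSE]
      pc$years <- years_grid[!is.na(keep)]
      split_draws[[cc]] <- apply_split(pc, rfit)
    }
    if (stage("aggregate")) {
      if (is.null(world$population)) stop("aggregate stage requires the population artifact")
      agg <- aggregate_draws(split_draws, world$population, world$region_map)
      tables <- headline_tables(agg, intersect(config$report_years, agg$years))
      write_summaries(tables$q_table, file.path(config$outdir, "table1_q.csv"))
      write_summaries(tables$deaths_table, file.path(config$outdir, "table2_deaths.csv"))
      note("aggregate: %d regions + world", length(agg$regions))
    }
  }

  refit <- NULL; leftout <- NULL
  if (stage("validate")) {
    sets <- make_training_set(obs, config$cutoff_year)
    train_ok <- vapply(split(sets$training, sets$training$country),
                       function(o) !is_sparse(o), logical(1))
    dense_train <- names(train_ok)[train_ok]
    refit <- fit_b3(sets$training[sets$training$country %in% dense_train, ],
                    config = config$b3)
    leftout <- sets$leftout
    validation <- evaluate_predictions(refit, leftout,
                                       seed = child_seed(config$seed, 999))
    note("validate: n=%d median error %.2f per 1000, coverage %.3f",
         validation$n_leftout, validation$median_error, validation$coverage90)
    write_summaries(validation$records, file.path(config$outdir, "validation_records.csv"))
    jsonlite::write_json(validation[c("n_leftout", "median_error",
                                      "median_abs_error", "coverage90")],
                         file.path(config$outdir, "validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(list(world = world, observations = obs, fit = fit,
                 posteriors = posts, aggregate = agg, tables = tables,
                 validation = validation, validation_refit = refit,
                 validation_leftout = leftout, log = log_lines,
                 outdir = config$outdir))
}

#' Training pairs for the sparse-country regression
#'
#' Spline-model posterior medians at 5-year grid points paired with the
#' under-5 mortality series, as used to train [fit_mixed()].
#'
#' @param fit A `b3_fit` on the data-rich countries.
#' @param truth Data frame with `country`, `year` and `q5_0_true` (in a
#'   real run, an external under-5 estimate series).
#' @param region_map Data frame `country`, `region`.
#' @param grid_years Training years (default `seq(1990, 2015, 5)`).
#' @return Data frame `logq`, `logu5mr`, `region`, `country`, `year`.
#' @export
sparse_training_pairs <- function(fit, truth, region_map,
                                  grid_years = seq(1990, 2015, 5)) {
  rows <- list()
  for (cc in names(fit$posteriors)) {
    s <- summarize_posterior(fit$posteriors[[cc]],
                             intersect(grid_years, fit$posteriors[[cc]]$years))
    u5 <- truth[truth$country == cc, ]
    u5mr <- u5$q5_0_true[match(s$year, u5$year)]
    ok <- !is.na(u5mr)
    rows[[cc]] <- data.frame(
      logq = log(s$median[ok]), logu5mr = log(u5mr[ok]),
      region = region_map$region[region_map$country == cc],
      country = cc, year = s$year[ok], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
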