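#' @title Study analysis pipeline
#'
#' @description
#' Orchestration of the full analysis: simulate (or load) sweep sets,
#' preprocess each condition level, extract wave metrics and thresholds,
#' fit growth functions, average across polarity, and (optionally) run
#' the filter-model predictions. All randomness flows from one config
#' seed; identical config + seed gives identical outputs, and every
#' output table carries the config hash and seed as attributes.
#'
#' @name pipeline
NULL

# FNV-1a hash of a string, reported as 8 hex digits.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Default study configuration
#'
#' @param seed study seed.
#' @param generator named list of [gen_params()] overrides.
#' @param shapes,polarities,level_multipliers,phase_duration,interphase_gap
#'   study factors (see [simulate_study()]).
#' @param preprocess list of [preprocess_options()] overrides.
#' @param criterion threshold criterion, µV.
#' @param fit_alpha F-test alpha for model selection.
#' @param model `NULL` to skip the filter-model stage, otherwise a list
#'   with optional `reference_current` (µA; default: the pipeline's
#'   measured polarity-averaged rectangular threshold current).
#' @return config list.
#' @export
study_config <- function(seed = 1L, generator = list(),
                         shapes = PULSE_SHAPES, polarities = POLARITIES,
                         level_multipliers = c(0.7, 0.9, 1.1, 1.4, 1.8,
                                               2.3, 2.9, 3.6),
                         phase_duration = 25, interphase_gap = 10,
                         preprocess = list(), criterion = 0.1,
                         fit_alpha = 0.05, model = list()) {
  list(seed = as.integer(seed), generator = generator, shapes = shapes,
       polarities = polarities, level_multipliers = level_multipliers,
       phase_duration = phase_duration, interphase_gap = interphase_gap,
       preprocess = preprocess, criterion = criterion,
       fit_alpha = fit_alpha, model = model)
}

#' Analyze a study's sweep sets
#'
#' Core per-condition analysis shared by [run_pipeline()] and the CLI
#' subcommands: preprocess every shape/polarity/level (four delay tags),
#' extract wave II metrics, build growth series (per polarity and for the
#' polarity-averaged traces), detect thresholds and fit growth functions.
#'
#' @param study list with `sweepsets` as from [simulate_study()] or
#'   [read_container()].
#' @param options [preprocess_options()].
#' @param criterion threshold criterion, µV.
#' @param fit_alpha model-selection alpha.
#' @return list with `growth_table` (tidy per-level metrics incl. the
#'   polarity-averaged traces), `summary` (per shape x polarity threshold
#'   and slope plus per-shape polarity averages), `series` and `traces`.
#' @export
analyze_study <- function(study, options = preprocess_options(),
                          criterion = 0.1, fit_alpha = 0.05) {
  conds <- lapply(study$sweepsets, function(ss) ss$condition)
  key <- vapply(conds, function(cd) {
    paste(cd$shape, cd$polarity, cd$level_index, sep = "|")
  }, character(1))
  traces <- list()
  for (k in unique(key)) {
    sets <- study$sweepsets[key == k]
    traces[[k]] <- preprocess_level(sets, options)
  }
  shapes <- unique(vapply(conds, `[[`, character(1), "shape"))
  pols <- unique(vapply(conds, `[[`, character(1), "polarity"))
  series <- list()
  rows <- list()
  srows <- list()
  for (shape in shapes) {
    per_pol <- list()
    for (pol in pols) {
      keys <- grep(paste0("^", shape, "\\|", pol, "\\|"), names(traces),
                   value = TRUE)
      keys <- keys[order(as.integer(sub(".*\\|", "", keys)))]
      lv <- do.call(rbind, lapply(keys, function(k) {
        tr <- traces[[k]]
        wm <- find_wave(tr, "II")
        data.frame(charge = tr$condition$charge,
                   current = tr$condition$current,
                   amplitude = wm$amplitude, latency = wm$peak_latency,
                   above_facial_nerve =
                     isTRUE(tr$condition$above_facial_nerve))
      }))
      cond <- traces[[keys[1]]]$condition
      ser <- growth_series(cond, lv)
      series[[paste(shape, pol, sep = "|")]] <- ser
      per_pol[[pol]] <- ser
      rows[[length(rows) + 1L]] <- metrics_table(ser, criterion)
      srows[[length(srows) + 1L]] <-
        summarize_series(ser, shape, pol, criterion, fit_alpha)
    }
    # polarity-averaged traces (artifact cancellation check)
    if (all(POLARITIES %in% pols)) {
      ka <- grep(paste0("^", shape, "\\|ANODIC_FIRST\\|"), names(traces),
                 value = TRUE)
      ka <- ka[order(as.integer(sub(".*\\|", "", ka)))]
      lv <- do.call(rbind, lapply(ka, function(k) {
        kc <- sub("ANODIC_FIRST", "CATHODIC_FIRST", k)
        tr <- alternating_polarity_average(traces[[k]], traces[[kc]])
        wm <- find_wave(tr, "II")
        data.frame(charge = tr$condition$charge,
                   current = tr$condition$current,
                   amplitude = wm$amplitude, latency = wm$peak_latency,
                   above_facial_nerve =
                     isTRUE(tr$condition$above_facial_nerve))
      }))
      cond <- traces[[ka[1]]]$condition
      cond$polarity <- "AVERAGED"
      ser <- growth_series(cond, lv)
      series[[paste(shape, "AVERAGED", sep = "|")]] <- ser
      rows[[length(rows) + 1L]] <- metrics_table(ser, criterion)
      srows[[length(srows) + 1L]] <-
        summarize_series(ser, shape, "AVERAGED", criterion, fit_alpha)
    }
  }
  summary <- do.call(rbind, srows)
  # per-shape values averaged across polarity (one threshold and slope
  # value per pulse shape)
  for (shape in shapes) {
    sub <- summary[summary$shape == shape &
                     summary$polarity %in% POLARITIES, , drop = FALSE]
    if (nrow(sub) == 2) {
      summary <- rbind(summary, data.frame(
        shape = shape, polarity = "POLARITY_MEAN",
        threshold_charge = mean(sub$threshold_charge),
        threshold_current = mean(sub$threshold_current),
        slope_charge = mean(sub$slope_charge),
        slope_current = mean(sub$slope_current),
        model = NA, r_squared = NA,
        latency_3db = mean(sub$latency_3db),
        stringsAsFactors = FALSE))
    }
  }
  list(growth_table = do.call(rbind, rows), summary = summary,
       series = series, traces = traces)
}

summarize_series <- function(ser, shape, pol, criterion, fit_alpha) {
  thr <- detect_threshold(ser, criterion)
  slope_q <- NA_real_
  slope_i <- NA_real_
  model <- NA_character_
  r2 <- NA_real_
  lat3 <- NA_real_
  if (thr$defined) {
    n_supra <- nrow(suprathreshold_levels(ser, criterion))
    if (n_supra >= 2) {
      lin_q <- fit_linear(ser, "charge", criterion)
      sel <- lin_q
      if (n_supra >= 5) {
        bs_q <- tryCatch(fit_broken_stick(ser, "charge", criterion),
                         error = function(e) NULL)
        if (!is.null(bs_q)) {
          sel <- select_model(lin_q, bs_q, ser, alpha = fit_alpha,
                              criterion = criterion)
        }
      }
      slope_q <- sel$slope1
      model <- sel$model
      r2 <- sel$r_squared
      slope_i <- fit_linear(ser, "current", criterion)$slope1
    }
    lat3 <- tryCatch(
      suppressWarnings(level_at_db_above_threshold(ser, 3,
                                                   criterion)$latency),
      error = function(e) NA_real_)
  }
  data.frame(shape = shape, polarity = pol,
             threshold_charge = thr$threshold_charge,
             threshold_current = thr$threshold_current,
             slope_charge = slope_q, slope_current = slope_i,
             model = model, r_squared = r2, latency_3db = lat3,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Stages: simulate -> preprocess -> quantify -> fit -> model. The model
#' stage runs when `config$model` is a list and is calibrated to the
#' measured polarity-averaged rectangular threshold current (or the
#' supplied `reference_current`); it is skipped (and noted in provenance)
#' when `config$model` is `NULL`.
#'
#' @param config a [study_config()] list, or path to a JSON file of one.
#' @return list with `tables` (`growth`, `summary`, `model`),
#'   `ground_truth`, `analysis` and `provenance` (config hash, seed,
#'   executed stages).
#' @export
run_pipeline <- function(config = study_config()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$generator <- as.list(config$generator)
    config$preprocess <- as.list(config$preprocess)
    if (!is.null(config$model)) config$model <- as.list(config$model)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  hash <- fnv1a_hash(as.character(cfg_json))
  stages <- character()
  params <- do.call(gen_params, c(config$generator,
                                  list(seed = config$seed)))
  study <- simulate_study(params, shapes = config$shapes,
                          polarities = config$polarities,
                          level_multipliers = config$level_multipliers,
                          phase_duration = config$phase_duration,
                          interphase_gap = config$interphase_gap,
                          seed = config$seed)
  stages <- c(stages, "simulate")
  options <- do.call(preprocess_options, config$preprocess)
  analysis <- analyze_study(study, options, config$criterion,
                            config$fit_alpha)
  stages <- c(stages, "preprocess", "quantify", "fit")
  model_table <- NULL
  if (!is.null(config$model)) {
    spec <- filter_model_spec(rate = 23.3)
    mf <- design_model_filter(spec)
    ref_cur <- config$model$reference_current
    if (is.null(ref_cur)) {
      s <- analysis$summary
      ref_cur <- s$threshold_current[s$shape == "REC" &
                                       s$polarity == "POLARITY_MEAN"]
      if (!length(ref_cur) || is.na(ref_cur)) ref_cur <- NULL
    }
    conds <- data.frame(shape = config$shapes,
                        phase_duration = config$phase_duration,
                        interphase_gap = config$interphase_gap,
                        stringsAsFactors = FALSE)
    if (!is.null(ref_cur)) mf <- calibrate(mf, ref_cur)
    model_table <- predict_table(conds, mf)
    stages <- c(stages, "model")
  } else {
    stages <- c(stages, "model_skipped")
  }
  tables <- list(growth = analysis$growth_table,
                 summary = analysis$summary, model = model_table)
  tables <- lapply(tables, function(tb) {
    if (!is.null(tb)) {
      attr(tb, "config_hash") <- hash
      attr(tb, "seed") <- config$seed
    }
    tb
  })
  list(tables = tables, ground_truth = study$ground_truth,
       analysis = analysis,
       provenance = list(config_hash = hash, seed = config$seed,
                         stages = stages))
}

#' Write pipeline tables as delimited text
#'
#' Each table is written as TSV with `# config_hash` and `# seed` header
#' comment lines.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tables)) {
    tb <- result$tables[[nm]]
    if (is.null(tb)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(c(paste0("# config_hash: ", attr(tb, "config_hash")),
                 paste0("# seed: ", attr(tb, "seed"))), con)
    utils::write.table(tb, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(dir)
}
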