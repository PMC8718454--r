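# One-command orchestration of the six phases: Transform-Encode ->
# Segregate-Label -> Q-Prioritization -> Train-Test -> Predict-Interpret
# -> Validate. All artifacts are plain CSV/JSON so a run is auditable
# and each phase's output can be reloaded and re-run on its own.

#' Assemble a pipeline configuration
#'
#' @param input Path to a raw-response CSV, or a data frame (raw codes
#'   1..4 or rate points 0..3; `rate_points = TRUE` marks the latter).
#' @param out_dir Run directory for artifacts.
#' @param rate_points Set `TRUE` when `input` already holds 0..3 rate
#'   points and the encode step should be skipped.
#' @param sets Disorder sets (bands + default thresholds).
#' @param rth Named numeric overrides of the per-disorder relevance
#'   thresholds; `NULL` uses each set's default.
#' @param seed Seed for the training loop and holdout.
#' @param rate_step,valid_frac Passed to [train_balanced()].
#' @param explain Respondent ids to explain (PP/PN/counterfactual +
#'   feedback); `NULL` disables the interpret step.
#' @param importance_repeats Shuffles per query for the importance
#'   ranking.
#' @param pn_budget,x_weight,beta_reg Explainer settings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, rate_points = FALSE,
                            sets = default_disorder_sets(), rth = NULL,
                            seed = 1L, rate_step = 0.1, valid_frac = 0.2,
                            explain = NULL, importance_repeats = 10L,
                            pn_budget = 3L, x_weight = 1, beta_reg = 0.1) {
  structure(list(input = input, out_dir = out_dir,
                 rate_points = rate_points, sets = sets, rth = rth,
                 seed = seed, rate_step = rate_step,
                 valid_frac = valid_frac, explain = explain,
                 importance_repeats = importance_repeats,
                 pn_budget = pn_budget, x_weight = x_weight,
                 beta_reg = beta_reg),
            class = "pipeline_config")
}

phase <- function(name, log, code) {
  t0 <- Sys.time()
  res <- tryCatch(force(code), error = function(e)
    stop("pipeline aborted in phase '", name, "': ", conditionMessage(e),
         call. = FALSE))
  log(sprintf("%-18s %6.2fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full assessment pipeline
#'
#' Executes encode -> label -> prioritize -> train -> evaluate (and
#' optionally explain) for each disorder, writing every intermediate
#' artifact plus a run log into `out_dir`. Deterministic given the
#' config's seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-disorder models, rankings, metrics
#'   and the artifact manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  log <- function(msg) writeLines(msg, log_con)
  log(sprintf("seed = %d", config$seed))
  manifest <- character(0)
  keep <- function(p) { manifest <<- c(manifest, p); p }

  matrix <- phase("transform-encode", log, {
    x <- config$input
    if (is.character(x)) x <- read_responses(x)
    if (config$rate_points) {
      m <- as_rate_points(x)
    } else {
      m <- encode_rate_points(impute_missing(as_raw_responses(x)))
    }
    write_rate_points(m, keep(file.path(config$out_dir, "ratepoints.csv")))
    m
  })

  results <- list()
  for (ds in names(config$sets)) {
    set <- config$sets[[ds]]
    labeled <- phase(paste0("segregate-label/", ds), log, {
      tab <- assign_severity(compute_weight_scores(matrix, set), set)
      utils::write.csv(tab, keep(file.path(
        config$out_dir, paste0("labeled_", ds, ".csv"))), row.names = FALSE)
      tab
    })
    rth <- if (!is.null(config$rth) && ds %in% names(config$rth))
      config$rth[[ds]] else set$rth
    ranking <- phase(paste0("q-prioritization/", ds), log, {
      r <- prioritize(compute_priority_relevance(labeled,
                                                 queries = set$queries), rth)
      write_ranking(r, keep(file.path(
        config$out_dir, paste0("ranking_", ds, ".json"))))
      r
    })
    pruned <- apply_prioritization(labeled, ranking)
    model <- phase(paste0("train-test/", ds), log, {
      if (length(unique(as.character(pruned$Class))) < 2L) {
        log(sprintf("  %s: single class, skipping training", ds))
        NULL
      } else {
        m <- train_balanced(pruned, seed = config$seed,
                            rate_step = config$rate_step,
                            valid_frac = config$valid_frac)
        write_model(m, keep(file.path(
          config$out_dir, paste0("model_", ds, ".json"))))
        m
      }
    })
    metrics <- NULL
    reports <- NULL
    if (!is.null(model)) {
      metrics <- phase(paste0("validate/", ds), log, {
        hold <- pruned[model$valid_idx, , drop = FALSE]
        m <- evaluate_model(model, hold)
        jsonlite::write_json(
          list(accuracy = m$accuracy, macro_precision = m$macro_precision,
               macro_recall = m$macro_recall, macro_f = m$macro_f,
               mse = m$mse, n = m$n, per_class = m$per_class),
          keep(file.path(config$out_dir, paste0("metrics_", ds, ".json"))),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
        m
      })
      pred <- phase(paste0("predict/", ds), log, {
        p <- data.frame(respondent_id = pruned$respondent_id,
                        predicted = as.character(predict(model, pruned)))
        utils::write.csv(p, keep(file.path(
          config$out_dir, paste0("predictions_", ds, ".csv"))),
          row.names = FALSE)
        p
      })
      if (!is.null(config$explain)) {
        reports <- phase(paste0("interpret/", ds), log, {
          imp <- permuted_importance(model, pruned,
                                     repeats = config$importance_repeats,
                                     seed = config$seed)
          reps <- lapply(config$explain, function(rid) {
            row <- pruned[pruned$respondent_id == rid, , drop = FALSE]
            if (!nrow(row)) stop("unknown respondent id: ", rid)
            lvl <- as.character(predict(model, row))
            pp <- pertinent_positive(model, row)
            pn <- pertinent_negative(model, row,
                                     budget = config$pn_budget)
            lvls <- model$classes
            at <- match(lvl, lvls)
            cf <- if (at > 1L)
              counterfactual(model, row, target = lvls[at - 1L],
                             reference = pruned,
                             x_weight = config$x_weight,
                             beta_reg = config$beta_reg) else NULL
            fb <- render_feedback(rid, ds, lvl, pp = pp, pn = pn, cf = cf)
            list(respondent_id = rid, level = lvl, pp = pp$pp,
                 pn = pn$pn, pn_found = pn$found,
                 counterfactual = if (!is.null(cf))
                   list(target = cf$target, converged = cf$converged,
                        deltas = as.list(cf$deltas[abs(cf$deltas) > 1e-9]))
                 else NULL,
                 feedback = fb$text)
          })
          obj <- list(importance = imp, reports = reps)
          jsonlite::write_json(obj, keep(file.path(
            config$out_dir, paste0("explanations_", ds, ".json"))),
            auto_unbox = TRUE, digits = NA, dataframe = "rows",
            force = TRUE)
          reps
        })
      }
    }
    results[[ds]] <- list(ranking = ranking, model = model,
                          metrics = metrics, explanations = reports)
  }
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  invisible(list(results = results, manifest = manifest,
                 out_dir = config$out_dir))
}
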