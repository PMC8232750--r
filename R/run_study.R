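#' Study configuration
#'
#' Bundles every stage's settings for [run_study]. All randomness flows from
#' `seed` through named substreams (synthesis, bootstrap, selection,
#' protocol).
#'
#' @param design a [synth_design] supplying the recordings.
#' @param settings odorized settings to analyse (default AF, AM, EF, EM);
#'   each must map to a neutral partner in `neutral_pairing`.
#' @param neutral_pairing named map setting -> neutral condition.
#' @param te_cfg a [te_config].
#' @param lag_range delay-scan bounds in samples.
#' @param preprocess_cfg a [preprocess_config], or `NULL` when the design
#'   already generates at the analysis rate.
#' @param B bootstrap replicates for thresholding and selection.
#' @param level CI level in percent.
#' @param runs specificity-protocol repetitions.
#' @param seed master seed.
#' @export
study_config <- function(design,
                         settings = c("AF", "AM", "EF", "EM"),
                         neutral_pairing = NEUTRAL_PAIRING,
                         te_cfg = te_config(),
                         lag_range = c(0L, 50L),
                         preprocess_cfg = NULL,
                         B = 10000L, level = 95, runs = 1000L, seed = 1L) {
  stopifnot(inherits(design, "synth_design"))
  missing_pair <- setdiff(settings, names(neutral_pairing))
  if (length(missing_pair)) {
    stop("no neutral pairing for setting(s): ",
         paste(missing_pair, collapse = ", "))
  }
  structure(list(design = design, settings = settings,
                 neutral_pairing = neutral_pairing, te_cfg = te_cfg,
                 lag_range = lag_range, preprocess_cfg = preprocess_cfg,
                 B = as.integer(B), level = level, runs = as.integer(runs),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the channel-of-interest study end-to-end
#'
#' Generates (or conditions) per-subject recordings, computes all-pairs
#' lag-optimized TE matrices per setting, forms voice-matched neutral
#' contrasts, grand-averages them, applies bootstrap upper-CI thresholding
#' and out-degree selection, intersects the per-setting selections, runs the
#' common-channel group statistics and -- when enough settings retain the
#' common channels -- the specificity protocol. Optionally writes every
#' artifact plus a manifest to `out_dir`.
#'
#' @param config a [study_config].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param verbose print stage progress.
#' @return list of class `study_result`: `te` (per condition, per subject),
#'   `contrasts`, `grand` (per setting), `flows` ([bootstrap_upper_threshold]
#'   per setting), `selections`, `common`, `group_stats`, `specificity`,
#'   `lag_summary`, `seeds`, `manifest`.
#' @export
run_study <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  say <- function(...) if (verbose) message(...)
  conditions <- union(config$settings,
                      unname(config$neutral_pairing[config$settings]))
  subjects <- paste0("S", seq_len(design$n_subjects))

  say("stage: transfer entropy (", length(conditions), " conditions x ",
      length(subjects), " subjects)")
  te <- lapply(stats::setNames(conditions, conditions), function(cond) {
    lapply(stats::setNames(subjects, subjects), function(sub) {
      rec <- generate_recording(design, sub, cond)
      if (!is.null(config$preprocess_cfg)) {
        rec <- preprocess(rec, config$preprocess_cfg)$recording
      }
      pairwise_te(rec, config$te_cfg, config$lag_range)
    })
  })

  say("stage: neutral contrasts and grand averages")
  grand <- lapply(stats::setNames(config$settings, config$settings),
                  function(s) {
    neutral <- config$neutral_pairing[[s]]
    grand_average(lapply(subjects, function(sub)
      neutral_contrast(te[[s]][[sub]], te[[neutral]][[sub]])))
  })

  say("stage: bootstrap thresholding and channel selection")
  seeds <- list(threshold = config$seed + 101L, select = config$seed + 202L,
                protocol = config$seed + 303L)
  flows <- lapply(grand, bootstrap_upper_threshold, B = config$B,
                  level = config$level, seed = seeds$threshold)
  selections <- lapply(flows, select_channels, B = config$B,
                       level = config$level, seed = seeds$select)
  common <- common_channels(selections)

  lag_summary <- do.call(rbind, lapply(names(te), function(cond) {
    ms <- unlist(lapply(te[[cond]], function(m)
      lag_to_ms(m$lags[row(m$lags) != col(m$lags)], m$rate)))
    data.frame(setting = cond, mean_ms = mean(ms), sd_ms = sd(ms))
  }))

  group_stats <- NULL
  specificity <- NULL
  retained <- intersect(config$settings, common$retained)
  if (length(common$common) >= 2 && length(retained) >= 2) {
    say("stage: group statistics on common channels")
    rows_by_setting <- lapply(stats::setNames(retained, retained),
                              function(s) {
      flows[[s]]$surviving[common$common, , drop = FALSE]
    })
    pooled <- lapply(rows_by_setting, function(m) as.vector(m))
    group_stats <- list(
      normality = lilliefors_mc(unlist(pooled), seed = config$seed + 404L),
      kruskal = kruskal_wallis_r(pooled),
      pairwise = {
        prs <- utils::combn(retained, 2, simplify = FALSE)
        out <- lapply(prs, function(p)
          wilcoxon_r(pooled[[p[1]]], pooled[[p[2]]], mode = "ranksum"))
        names(out) <- vapply(prs, paste, character(1), collapse = " vs ")
        out
      })
    if (length(retained) >= 3) {
      say("stage: specificity protocol")
      ds <- build_dataset(rows_by_setting)
      specificity <- run_protocol(ds, runs = config$runs,
                                  seed = seeds$protocol)
    }
  }

  result <- structure(
    list(te = te, grand = grand, flows = flows, selections = selections,
         common = common, group_stats = group_stats,
         specificity = specificity, lag_summary = lag_summary,
         seeds = c(master = config$seed, seeds),
         config = config),
    class = "study_result")
  if (!is.null(out_dir)) result$manifest <- write_study(result, out_dir)
  result
}

# Serialize a study_result to CSV/JSON artifacts plus a manifest.
write_study <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(path, what) {
    manifest[[length(manifest) + 1L]] <<- list(file = path, what = what)
  }
  for (s in names(result$grand)) {
    p <- file.path(out_dir, paste0("grand_te_", s, ".csv"))
    write.csv(result$grand[[s]], p)
    add(p, paste("grand-averaged contrast TE matrix,", s))
    p <- file.path(out_dir, paste0("surviving_te_", s, ".csv"))
    write.csv(result$flows[[s]]$surviving, p)
    add(p, paste("thresholded TE matrix,", s))
    p <- file.path(out_dir, paste0("out_degree_", s, ".csv"))
    write.csv(data.frame(channel = result$flows[[s]]$labels,
                         out_degree = result$flows[[s]]$out_degree,
                         row.names = NULL), p, row.names = FALSE)
    add(p, paste("per-channel out-degree,", s))
  }
  p <- file.path(out_dir, "lag_summary.csv")
  write.csv(result$lag_summary, p, row.names = FALSE)
  add(p, "per-setting optimal-lag summary (ms)")
  summary_json <- list(
    thresholds = lapply(result$flows, `[[`, "threshold"),
    selected_channels = result$selections,
    common_channels = result$common$common,
    dropped_settings = result$common$dropped,
    seeds = as.list(result$seeds),
    package_version = as.character(utils::packageVersion("teflow"))
  )
  if (!is.null(result$specificity)) {
    sp <- result$specificity
    summary_json$specificity <- list(
      accuracy = c(mean = sp$accuracy_mean, sd = sp$accuracy_sd),
      precision = c(mean = sp$precision_mean, sd = sp$precision_sd),
      recall = c(mean = sp$recall_mean, sd = sp$recall_sd),
      f1 = c(mean = sp$f1_mean, sd = sp$f1_sd),
      confusion = sp$confusion, chance_level = sp$chance_level,
      seed = sp$seed)
    p <- file.path(out_dir, "weights.csv")
    write.csv(sp$weights, p)
    add(p, "per-setting mean logistic-regression weight maps")
  }
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, p, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  add(p, "study summary: thresholds, selections, seeds")
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE)
  manifest
}
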