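# Config-driven orchestration: simulate-or-load -> preprocess ->
# kinematics -> segmentation -> participant-level cohort table -> stats ->
# report files, with deterministic seeding and a provenance record.

.default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    sample_rate = 100,
    output_dir = "romocap_out",
    cohort = list(n_per_group = 21L, tasks = names(.task_defaults),
                  noise_sd = 1.0, within_correlation = 0.8,
                  rep_rom_sd = 3, n_reps = 6L, n_sets = 2L,
                  both_sides = TRUE, trend_acute = 0),
    input = list(metadata = NULL, directory = NULL),
    filter = list(cutoff = 5, order = 4L, zero_phase = TRUE),
    segmentation = list(expected_reps = 6L, prominence = 0.2),
    pooling = list(exclude_first = TRUE),
    stats = list(alpha = 0.05,
                 fatigue_tasks = c("lateral_bending", "twist",
                                   "anterior_flexion"))
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("config validation error: unknown key '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("config validation error: '", full, "' must be a mapping")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, rejects unknown keys, fills
#' defaults and checks cross-field constraints (e.g. the filter cutoff
#' must lie below the Nyquist frequency of `sample_rate`).
#'
#' @param path configuration file path, or a named list.
#' @return validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  user <- if (is.list(path)) path
          else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                                simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(.default_config(), user)
  if (!cfg$mode %in% c("simulate", "load"))
    stop("config validation error: mode must be 'simulate' or 'load'")
  if (cfg$filter$cutoff >= cfg$sample_rate / 2)
    stop("config validation error: filter cutoff ", cfg$filter$cutoff,
         " Hz is not below the Nyquist frequency (",
         cfg$sample_rate / 2, " Hz)")
  if (cfg$segmentation$prominence <= 0 || cfg$segmentation$prominence >= 1)
    stop("config validation error: segmentation.prominence must be in (0, 1)")
  if (cfg$mode == "load" && is.null(cfg$input$metadata))
    stop("config validation error: load mode needs input.metadata")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# flatten a rom_test into one stats-table row
.stat_row <- function(analysis, task, parameter, term, tst) {
  df <- unlist(tst$df)
  data.frame(analysis = analysis, task = task, parameter = parameter,
             term = term, statistic = tst$statistic,
             df1 = df[1], df2 = if (length(df) > 1) df[2] else NA_real_,
             p_value = tst$p_value,
             adjusted_p = tst$adjusted_p,
             d = tst$d, band = if (is.null(tst$band)) NA_character_ else tst$band)
}

#' Run the full analysis pipeline
#'
#' Executes all stages according to a validated configuration: simulate a
#' cohort (or load trial files listed in a metadata CSV), preprocess and
#' segment every trial, pool repetitions/sets/sides into a
#' participant-level cohort table, run the statistical workflow, and write
#' `cohort.csv`, `stats.csv`, `summary.txt` and `provenance.json` into the
#' output directory. Per-trial failures are logged and excluded; their
#' count is reported.
#'
#' @param config a [validate_config()] result, a config file path, or a
#'   named list.
#' @param quiet suppress progress messages.
#' @return invisibly, list with `cohort` (participant-level table),
#'   `rep_rom` (per-repetition table), `stats` (tidy test table),
#'   `failures`, `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
    say("created output directory ", cfg$output_dir)
  }
  fspec <- filter_spec(cfg$filter$cutoff, cfg$filter$order,
                       cfg$filter$zero_phase)
  trial_rows <- list()
  rep_rows <- list()
  failures <- 0L

  handle <- function(md, trajectory) {
    res <- tryCatch(
      analyze_trial(trajectory, md, fspec = fspec,
                    expected_reps = cfg$segmentation$expected_reps,
                    min_prominence_frac = cfg$segmentation$prominence,
                    exclude_first = cfg$pooling$exclude_first),
      error = function(e) {
        say("trial failed (", md$participant_id, " ", md$session, " ",
            md$task, " ", md$side, " set ", md$set_index, "): ",
            conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      failures <<- failures + 1L
      return(invisible(NULL))
    }
    trial_rows[[length(trial_rows) + 1L]] <<- data.frame(
      participant = md$participant_id, group = md$group,
      session = md$session, task = md$task, side = md$side,
      set_index = md$set_index,
      pooled_rom = res$pooled_rom, duration = res$duration,
      rep_count_mismatch = res$rep_count_mismatch)
    nr <- nrow(res$repetitions)
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      participant = md$participant_id, group = md$group,
      session = md$session, task = md$task, side = md$side,
      set_index = md$set_index, repetition = seq_len(nr),
      value = res$repetitions$rom)
    invisible(NULL)
  }

  say("stage 1/4: ", cfg$mode)
  if (cfg$mode == "simulate") {
    spec <- cohort_spec(
      n_per_group = cfg$cohort$n_per_group, tasks = cfg$cohort$tasks,
      within_correlation = cfg$cohort$within_correlation,
      noise_sd = cfg$cohort$noise_sd, rep_rom_sd = cfg$cohort$rep_rom_sd,
      n_reps = cfg$cohort$n_reps, n_sets = cfg$cohort$n_sets,
      both_sides = cfg$cohort$both_sides,
      trend_acute = cfg$cohort$trend_acute, seed = cfg$seed)
    simulate_cohort(spec, handler = function(md, tr)
      handle(md, tr$trajectory))
  } else {
    meta <- utils::read.csv(cfg$input$metadata, stringsAsFactors = FALSE)
    need <- c("file", "participant", "group", "session", "task", "side",
              "set_index")
    if (!all(need %in% names(meta)))
      stop("input metadata must have columns: ", paste(need, collapse = ", "))
    base <- if (is.null(cfg$input$directory)) dirname(cfg$input$metadata)
            else cfg$input$directory
    for (i in seq_len(nrow(meta))) {
      md <- trial_metadata(meta$participant[i], meta$group[i],
                           meta$session[i], meta$task[i], meta$side[i],
                           meta$set_index[i])
      trajectory <- tryCatch(read_trial(file.path(base, meta$file[i])),
                             error = function(e) {
                               say("unreadable trial ", meta$file[i], ": ",
                                   conditionMessage(e))
                               NULL
                             })
      if (is.null(trajectory)) failures <- failures + 1L else
        handle(md, trajectory)
    }
  }
  trials <- do.call(rbind, trial_rows)
  if (is.null(trials) || !nrow(trials))
    stop("pipeline stage 'segmentation': no trial produced a result")
  rep_rom <- do.call(rbind, rep_rows)

  say("stage 2/4: pooling")
  cohort <- .pool_cohort(trials, cfg$stats$alpha)
  say("stage 3/4: statistics")
  stats_tab <- .cohort_stats(cohort, rep_rom, cfg)
  say("stage 4/4: reports")
  files <- c(
    cohort = file.path(cfg$output_dir, "cohort.csv"),
    stats = file.path(cfg$output_dir, "stats.csv"),
    summary = file.path(cfg$output_dir, "summary.txt"),
    provenance = file.path(cfg$output_dir, "provenance.json"))
  write_cohort_table(cohort, files["cohort"])
  utils::write.csv(stats_tab, files["stats"], row.names = FALSE)
  writeLines(.summary_report(cohort, stats_tab, failures), files["summary"])
  provenance <- list(package = "romocap",
                     version = as.character(utils::packageVersion("romocap")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     seed = cfg$seed,
                     config = unclass(cfg),
                     trials_analyzed = nrow(trials),
                     trials_failed = failures)
  jsonlite::write_json(provenance, files["provenance"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(cohort = cohort, rep_rom = rep_rom, stats = stats_tab,
                 failures = failures, files = files))
}

# set-level trial rows -> participant-level cohort table (mean over the
# two sets, then sides pooled when the preliminary paired side test allows)
.pool_cohort <- function(trials, alpha) {
  ag <- stats::aggregate(cbind(pooled_rom, duration) ~
                           participant + group + session + task + side,
                         data = trials, FUN = mean)
  rows <- list()
  for (task in unique(ag$task)) {
    sub <- ag[ag$task == task, ]
    bilateral <- !any(sub$side == "none")
    pooled <- if (bilateral && all(c("left", "right") %in% sub$side)) {
      pre <- sub[sub$session == "PRE", ]
      just_rom <- tryCatch(
        side_comparison(data.frame(participant = pre$participant,
                                   side = pre$side,
                                   value = pre$pooled_rom),
                        alpha = alpha)$justified,
        error = function(e) TRUE)
      if (just_rom) {
        stats::aggregate(cbind(pooled_rom, duration) ~
                           participant + group + session + task,
                         data = sub, FUN = mean)
      } else {
        sub$task <- paste0(sub$task, "_", sub$side)
        stats::aggregate(cbind(pooled_rom, duration) ~
                           participant + group + session + task,
                         data = sub, FUN = mean)
      }
    } else {
      stats::aggregate(cbind(pooled_rom, duration) ~
                         participant + group + session + task,
                       data = sub, FUN = mean)
    }
    rows[[length(rows) + 1L]] <- pooled
  }
  wide <- do.call(rbind, rows)
  long <- rbind(
    data.frame(participant = wide$participant, group = wide$group,
               session = wide$session, task = wide$task,
               parameter = "ROM", value = wide$pooled_rom),
    data.frame(participant = wide$participant, group = wide$group,
               session = wide$session, task = wide$task,
               parameter = "duration", value = wide$duration))
  long[order(long$task, long$parameter, long$group, long$participant,
             long$session), ]
}

.cohort_stats <- function(cohort, rep_rom, cfg) {
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x
  for (task in unique(cohort$task)) {
    for (par in unique(cohort$parameter)) {
      sub <- cohort[cohort$task == task & cohort$parameter == par, ]
      wg <- sub[sub$group == "WG", ]
      cg <- sub[sub$group == "CG", ]
      if (nrow(wg) && nrow(cg) &&
          all(c("PRE", "POST") %in% intersect(wg$session, cg$session))) {
        mx <- tryCatch(mixed_rm_anova(sub), error = function(e) NULL)
        if (!is.null(mx)) {
          add(.stat_row("mixed_rm_anova", task, par, "session", mx$session))
          add(.stat_row("mixed_rm_anova", task, par, "group", mx$group))
          add(.stat_row("mixed_rm_anova", task, par, "session:group",
                        mx$interaction))
        }
      }
      if (length(unique(wg$session)) >= 2) {
        rm <- tryCatch(rm_anova_within(wg), error = function(e) NULL)
        if (!is.null(rm)) {
          add(.stat_row("rm_anova_within_wg", task, par, "session", rm))
          ph <- holm_posthoc(wg)
          for (i in seq_len(nrow(ph)))
            add(data.frame(analysis = "holm_posthoc_wg", task = task,
                           parameter = par, term = ph$comparison[i],
                           statistic = ph$t[i], df1 = ph$df[i],
                           df2 = NA_real_, p_value = ph$p_value[i],
                           adjusted_p = ph$adjusted_p[i], d = ph$d[i],
                           band = ph$band[i]))
        }
      }
      if (all(c("PRE", "POST") %in% cg$session)) {
        pp <- tryCatch(paired_prepost(cg), error = function(e) NULL)
        if (!is.null(pp))
          add(.stat_row("paired_prepost_cg", task, par, "PRE-POST", pp))
      }
    }
  }
  if (!is.null(rep_rom)) {
    for (task in intersect(cfg$stats$fatigue_tasks, unique(rep_rom$task))) {
      sub <- rep_rom[rep_rom$task == task & rep_rom$group == "WG", ]
      for (session in unique(sub$session)) {
        ses <- sub[sub$session == session, ]
        per <- stats::aggregate(value ~ participant + repetition, data = ses,
                                FUN = mean)
        fa <- tryCatch(fatigue_analysis(per), error = function(e) NULL)
        if (!is.null(fa)) {
          add(.stat_row("fatigue_rm_anova", task,
                        paste0("rep_rom_", session), "repetition", fa$anova))
          row <- .stat_row("fatigue_first_last", task,
                           paste0("rep_rom_", session), "first-last",
                           fa$first_vs_last)
          row$percent_change <- fa$percent_change
          add(row)
        }
      }
    }
  }
  out <- lapply(out, function(r) {
    if (!"percent_change" %in% names(r)) r$percent_change <- NA_real_
    r
  })
  do.call(rbind, out)
}

.summary_report <- function(cohort, stats_tab, failures) {
  lines <- c("romocap pipeline summary", strrep("=", 40), "")
  for (task in unique(cohort$task)) {
    for (par in unique(cohort$parameter)) {
      sub <- cohort[cohort$task == task & cohort$parameter == par, ]
      if (!nrow(sub)) next
      lines <- c(lines, sprintf("%s / %s:", task, par))
      for (g in c("WG", "CG")) {
        gs <- sub[sub$group == g, ]
        if (!nrow(gs)) next
        cells <- vapply(intersect(.sessions_all, unique(gs$session)),
                        function(s) {
          v <- gs$value[gs$session == s]
          sprintf("%s %.2f (%.2f)", s, mean(v), stats::sd(v))
        }, character(1))
        inter <- stats_tab[stats_tab$analysis == "mixed_rm_anova" &
                             stats_tab$task == task &
                             stats_tab$parameter == par &
                             stats_tab$term == "session:group", ]
        mark <- if (nrow(inter) && !is.na(inter$p_value[1]) &&
                    inter$p_value[1] < 0.05) " [session x group p < 0.05]"
                else ""
        lines <- c(lines, sprintf("  %s: %s%s", g,
                                  paste(cells, collapse = ", "),
                                  if (g == "CG") mark else ""))
      }
      lines <- c(lines, "")
    }
  }
  c(lines, sprintf("trials failed and excluded: %d", failures))
}
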