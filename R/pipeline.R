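# Orchestration of the full analysis over a time-lapse: slide a frame-pair
# window (optionally skipping k intermediate frames), detect events per
# pair, and write the tabular and visual artefacts.

#' Run the full event-detection pipeline over a time-lapse
#'
#' Pairs frame `t` with frame `t + 1 + k_skip` for every valid `t`,
#' pre-processing each frame exactly once. Writes `events.csv`,
#' `metrics.csv` (per-pair counts and network metrics with five-frame
#' simple-moving-average columns), one RGB overlay TIFF per pair, and
#' optionally per-event review patches. A failure in one pair is logged and
#' the run continues; only I/O or configuration errors abort.
#'
#' @param input a [time_lapse()], or a path accepted by [read_timelapse()].
#' @param output_dir directory for artefacts (created if needed).
#' @param cfg a [mel_config()], or a path to a YAML config.
#' @param k_skip overrides `cfg$k_skip` when not `NULL`.
#' @param patches write per-event review patches (PNG) as well.
#' @param overlays write per-pair RGB overlay stacks (TIFF).
#' @param spacing_override passed to [read_timelapse()] for path input.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `events` (combined data frame), `metrics`
#'   (data frame), and `failures` (named list of error messages, empty on a
#'   clean run).
#' @export
run_pipeline <- function(input, output_dir, cfg = mel_config(),
                         k_skip = NULL, patches = FALSE, overlays = TRUE,
                         spacing_override = NULL, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  if (!is.null(k_skip)) cfg$k_skip <- as.integer(k_skip)
  tl <- if (inherits(input, "mel_timelapse")) input else
    read_timelapse(input, spacing_override = spacing_override)
  nfr <- length(tl$frames)
  step <- 1L + cfg$k_skip
  if (nfr < 1L + step) stop("need at least ", 1L + step,
                            " frames for k_skip = ", cfg$k_skip)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pre <- vector("list", nfr) # lazy per-frame pre-processing cache
  get_pre <- function(i) {
    if (is.null(pre[[i]])) pre[[i]] <<- preprocess_frame(tl$frames[[i]], cfg)
    pre[[i]]
  }
  firsts <- seq_len(nfr - step)
  all_events <- list()
  metrics <- list()
  failures <- list()
  for (t in firsts) {
    t2 <- t + step
    res <- tryCatch(
      compare_frames(get_pre(t), get_pre(t2), cfg, tl$frame_interval, t),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(t)]] <- conditionMessage(res)
      say("pair (%d, %d): ERROR %s", t, t2, conditionMessage(res))
      next
    }
    ev <- res$events
    counts <- table(factor(ev$event_type,
                           levels = c("fusion", "fission", "depolarisation")))
    say("pair (%d, %d): %d fusion, %d fission, %d depolarisation, %d structures",
        t, t2, counts[["fusion"]], counts[["fission"]],
        counts[["depolarisation"]], res$n_structures)
    all_events[[length(all_events) + 1L]] <- ev
    metrics[[length(metrics) + 1L]] <- data.frame(
      frame_index = t, n_fusion = as.integer(counts[["fusion"]]),
      n_fission = as.integer(counts[["fission"]]),
      n_depol = as.integer(counts[["depolarisation"]]),
      n_structures = res$n_structures,
      total_volume_vox = res$total_volume_vox,
      average_volume_vox = res$average_volume_vox)
    if (overlays) {
      rgb <- render_overlay(get_pre(t)$norm, ev)
      write_overlay_tiff(rgb, file.path(output_dir,
                                        sprintf("overlay_%03d.tif", t)))
    }
    if (patches && nrow(ev)) {
      for (r in seq_len(nrow(ev))) {
        export_event_patches(ev[r, ], get_pre(t)$norm, get_pre(t2)$norm,
                             get_pre(t)$structures, get_pre(t2)$structures,
                             dir = file.path(output_dir, "patches"))
      }
    }
    pre[t] <- list(NULL) # frame t is never needed again
  }
  events_df <- if (length(all_events)) do.call(rbind, all_events) else
    empty_events()
  metrics_df <- if (length(metrics)) do.call(rbind, metrics) else NULL
  if (!is.null(metrics_df)) {
    for (col in c("n_fusion", "n_fission", "n_depol", "n_structures",
                  "average_volume_vox")) {
      metrics_df[[paste0(col, "_sma5")]] <- moving_average(metrics_df[[col]], 5L)
    }
  }
  write_event_table(events_df, file.path(output_dir, "events.csv"))
  if (!is.null(metrics_df))
    write_metrics_table(metrics_df, file.path(output_dir, "metrics.csv"))
  if (length(failures))
    say("completed with %d failed pair(s): %s", length(failures),
        paste(names(failures), collapse = ", "))
  invisible(list(events = events_df, metrics = metrics_df,
                 failures = failures))
}
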