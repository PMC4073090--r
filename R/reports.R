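#' Write a report bundle for simulation results
#'
#' Renders the standard summary artifacts for one or more simulated
#' conditions: serial-position recall and first-recall curves (CSV + PDF),
#' the pooled recall transcripts, and a machine-readable JSON summary.
#' Given two conditions (e.g. frontal on vs off) the curves are overlaid
#' as a contrast plot.  Given a single trial from [run_trial()], the
#' semantic-categorization weight matrix is additionally rendered as a
#' heatmap snapshot.  Every artifact embeds the parameter digest and seed,
#' so reruns with identical inputs reproduce identical summaries.
#'
#' All plots are derived views; numeric checks should use the CSV/JSON
#' summaries, never rendered images.
#'
#' @param results A `can_condition`, a list of them (optionally named), or
#'   a single [run_trial()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths of the written files.
#' @export
report_run <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  if (is.list(results) && !is.null(results$recall) &&
      inherits(results$recall, "can_recall")) {
    return(invisible(report_trial(results, out_dir)))
  }
  conds <- if (inherits(results, "can_condition")) list(results) else results
  if (length(conds) == 0L) stop("empty results", call. = FALSE)
  if (is.null(names(conds)) || any(!nzchar(names(conds)))) {
    names(conds) <- vapply(conds, function(cc)
      paste0(cc$design, if (cc$frontal) "_frontal" else "_lesioned"),
      character(1))
  }
  # curves CSV
  curves <- do.call(rbind, lapply(names(conds), function(nm) {
    cv <- conds[[nm]]$curve
    data.frame(condition = nm, position = cv$position,
               p_recall = cv$p_recall, p_first = cv$p_first)
  }))
  f <- file.path(out_dir, "serial_position_curves.csv")
  write_with_header(curves, f, conds)
  paths <- c(paths, f)
  # transcripts
  for (nm in names(conds)) {
    f <- file.path(out_dir, paste0("transcripts_", nm, ".csv"))
    write_transcripts(conds[[nm]]$transcripts, f,
                      header_comment = artifact_header(conds[[nm]]))
    paths <- c(paths, f)
  }
  # summary JSON
  summ <- lapply(conds, function(cc) {
    pr <- cc$per_run
    list(design = cc$design, frontal = cc$frontal,
         isolate_position = cc$isolate_position, n_runs = cc$n_runs,
         seed = cc$seed, params_digest = cc$params_digest,
         mean_correct = mean(pr$n_correct),
         sd_correct = stats::sd(pr$n_correct),
         mean_clustering = mean(pr$clustering, na.rm = TRUE),
         sd_clustering = stats::sd(pr$clustering, na.rm = TRUE),
         mean_buffer_late = mean(pr$buffer_late),
         mean_surprises = mean(pr$n_surprise),
         p_recall = cc$curve$p_recall, p_first = cc$curve$p_first)
  })
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, f)
  # curve plot (contrast overlay when several conditions)
  f <- file.path(out_dir, "serial_position_curves.pdf")
  grDevices::pdf(f, width = 8, height = 4.5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2))
  cols <- c("firebrick", "steelblue", "darkgreen", "orange")
  for (panel in c("p_recall", "p_first")) {
    L <- conds[[1]]$list_length
    graphics::plot(NULL, xlim = c(1, L), ylim = c(0, 1),
                   xlab = "serial position",
                   ylab = if (panel == "p_recall") "P(recall)"
                          else "P(first recall)",
                   main = if (panel == "p_recall") "Recall" else "First recall")
    for (i in seq_along(conds)) {
      graphics::lines(conds[[i]]$curve$position, conds[[i]]$curve[[panel]],
                      type = "b", pch = 16, col = cols[(i - 1) %% 4 + 1])
    }
    graphics::legend("topleft", legend = names(conds), bty = "n",
                     col = cols[seq_along(conds)], lty = 1, pch = 16, cex = 0.7)
  }
  paths <- c(paths, f)
  invisible(paths)
}

artifact_header <- function(cc) {
  paste0("seed=", cc$seed, " params_digest=", cc$params_digest,
         " design=", cc$design,
         " frontal=", cc$frontal, " n_runs=", cc$n_runs)
}

write_with_header <- function(df, path, conds) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cc in conds) writeLines(paste0("# ", artifact_header(cc)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

report_trial <- function(trial, out_dir) {
  paths <- character(0)
  ev <- trial$recall$events
  ev$run_id <- rep.int(1L, nrow(ev))
  digest <- params_digest(trial$encoding$params)
  f <- file.path(out_dir, "transcript.csv")
  write_transcripts(ev, f, header_comment = paste0("params_digest=", digest))
  paths <- c(paths, f)
  f <- file.path(out_dir, "weights_categorization.csv")
  utils::write.csv(trial$encoding$weights$W_yz, f, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(out_dir, "weights_categorization.pdf")
  grDevices::pdf(f, width = 5, height = 5)
  W <- trial$encoding$weights$W_yz
  graphics::image(seq_len(ncol(W)), seq_len(nrow(W)), t(W),
                  xlab = "categorization unit", ylab = "semantic feature",
                  main = "Semantic-categorization weights",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE))
  grDevices::dev.off()
  paths <- c(paths, f)
  invisible(paths)
}
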