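#' Summarize a classified time course
#'
#' Groups cells by time point and reports, per time point, the fraction of
#' cells carrying each label (including `REJECT`) and the 5/25/50/75/95%
#' quantiles of surprisal. During a reprogramming-style time course the
#' population's surprisal distribution drifts downward as cells converge on
#' the training states, and the label fractions trace which network states
#' the cells pass through.
#'
#' @param time numeric time point per cell (e.g. day)
#' @param labels factor of labels per cell, as from [classify_cells()]
#' @param surprisals surprisal per cell in bits, as from [surprisal()]
#' @return object of class `timecourse_summary`: `time_points` (sorted),
#'   `fractions` (data.frame time, label, fraction, n) and
#'   `surprisal` (data.frame time, q05, q25, q50, q75, q95, n)
#' @export
summarize_timecourse <- function(time, labels, surprisals) {
  if (anyNA(time)) stopf("every cell needs a time point")
  n <- length(time)
  if (length(labels) != n || length(surprisals) != n)
    stopf("time, labels and surprisals must have equal length")
  labels <- as.factor(labels)
  tps <- sort(unique(time))
  frac <- do.call(rbind, lapply(tps, function(tp) {
    sel <- time == tp
    tab <- table(labels[sel])
    data.frame(time = tp, label = names(tab),
               fraction = as.numeric(tab) / sum(sel),
               n = as.integer(tab), row.names = NULL)
  }))
  qs <- do.call(rbind, lapply(tps, function(tp) {
    s <- surprisals[time == tp]
    q <- stats::quantile(s, c(0.05, 0.25, 0.50, 0.75, 0.95), names = FALSE)
    data.frame(time = tp, q05 = q[1], q25 = q[2], q50 = q[3],
               q75 = q[4], q95 = q[5], n = length(s))
  }))
  structure(list(time_points = tps, fractions = frac, surprisal = qs),
            class = "timecourse_summary")
}

#' @export
print.timecourse_summary <- function(x, ...) {
  cat(sprintf("time course: %d time points, %d cells\n",
              length(x$time_points), sum(x$surprisal$n)))
  cat("median surprisal by time point:\n")
  print(stats::setNames(round(x$surprisal$q50, 2), x$surprisal$time))
  invisible(x)
}

#' Write and plot a time-course summary
#'
#' Writes the label-fraction and surprisal-quantile tables as TSV and
#' renders two PNG figures (stacked state fractions; surprisal quantile
#' band around the median). Plotting failures never corrupt the data
#' outputs: TSVs are written first and a failed device is reported as a
#' warning.
#'
#' @param summary a `timecourse_summary`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the paths written
#' @export
plot_summary <- function(summary, dir, prefix = "timecourse") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_frac <- file.path(dir, paste0(prefix, "_fractions.tsv"))
  p_surp <- file.path(dir, paste0(prefix, "_surprisal.tsv"))
  utils::write.table(summary$fractions, p_frac, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$surprisal, p_surp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(p_frac, p_surp)
  fig1 <- file.path(dir, paste0(prefix, "_fractions.png"))
  fig2 <- file.path(dir, paste0(prefix, "_surprisal.png"))
  if (render_png(fig1, function() {
    fr <- summary$fractions
    labs <- unique(fr$label)
    mat <- t(sapply(labs, function(l) {
      sub <- fr[fr$label == l, ]
      v <- sub$fraction[match(summary$time_points, sub$time)]
      ifelse(is.na(v), 0, v)
    }))
    graphics::barplot(mat, names.arg = summary$time_points,
                      col = grDevices::hcl.colors(length(labs), "Dark 3"),
                      xlab = "time", ylab = "fraction of cells",
                      legend.text = labs, args.legend = list(x = "topright"))
  })) paths <- c(paths, fig1)
  if (render_png(fig2, function() {
    s <- summary$surprisal
    graphics::plot(s$time, s$q50, type = "n", ylim = range(s$q05, s$q95),
                   xlab = "time", ylab = "surprisal (bits)")
    graphics::polygon(c(s$time, rev(s$time)), c(s$q05, rev(s$q95)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::polygon(c(s$time, rev(s$time)), c(s$q25, rev(s$q75)),
                      col = grDevices::adjustcolor("steelblue", 0.5),
                      border = NA)
    graphics::lines(s$time, s$q50, lwd = 2)
    graphics::points(s$time, s$q50, pch = 19)
  })) paths <- c(paths, fig2)
  invisible(paths)
}

# open a png device, run draw(), always close; FALSE (with a warning) on
# failure so plotting can never corrupt data outputs
render_png <- function(path, draw, width = 900, height = 540) {
  tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    draw()
    TRUE
  }, error = function(e) {
    warnf("plot '%s' failed: %s", basename(path), conditionMessage(e))
    FALSE
  })
}
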