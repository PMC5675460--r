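## S3 methods for simulation recordings.

#' @export
print.thalamic_recording <- function(x, ...) {
  cat("Thalamic network recording\n")
  cat(sprintf("  %.0f ms at dt = %g ms (discard %g ms), seed %d\n",
              x$duration, x$dt, x$discard, x$seed))
  cat("  cells:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                        collapse = ", "), "\n")
  cat("  spikes recorded:", nrow(x$spikes), "\n")
  invisible(x)
}

#' @export
summary.thalamic_recording <- function(object, ...) {
  r <- object
  rates <- population_rates(r)
  res <- list(rates = rates)
  if (r$duration - r$discard >= 1500) {
    sl <- compute_slfp(r)
    pk <- dominant_frequency(sl)
    res$frequency <- pk$frequency
    res$power <- pk$power
  }
  cat("Thalamic network recording summary\n")
  cat("  mean firing rates (Hz):",
      paste(sprintf("%s %.1f", names(rates), rates), collapse = ", "), "\n")
  if (!is.null(res$frequency))
    cat(sprintf("  dominant sLFP frequency: %.2f Hz (peak power %.3g mV^2)\n",
                res$frequency, res$power))
  invisible(res)
}

#' Plot a recording: spike raster and sLFP
#'
#' @param x a `thalamic_recording`.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.thalamic_recording <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  st <- x$spikes[x$spikes$time >= x$discard, ]
  offs <- c(0, cumsum(x$sizes))[seq_along(x$sizes)]
  names(offs) <- names(x$sizes)
  gid <- offs[st$pop] + st$cell
  graphics::plot(st$time, gid, pch = ".", xlab = "time (ms)", ylab = "cell",
                 main = "")
  graphics::abline(h = cumsum(x$sizes)[-4], col = "grey")
  if (x$duration - x$discard >= 1500) {
    sl <- compute_slfp(x)
    graphics::plot(sl$t, sl$x, type = "l", xlab = "time (ms)",
                   ylab = "sLFP (mV)")
  }
  invisible(x)
}

#' Write spikes and the sLFP of a recording as delimited text
#'
#' @param recording a `thalamic_recording`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(recording$spikes, file.path(dir, "spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  sl <- try(compute_slfp(recording), silent = TRUE)
  if (!inherits(sl, "try-error"))
    write.table(data.frame(time_ms = sl$t, slfp_mv = sl$x),
                file.path(dir, "slfp.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  manifest <- list(duration = recording$duration, dt = recording$dt,
                   discard = recording$discard, seed = recording$seed,
                   sizes = as.list(recording$sizes),
                   g_KL = as.list(recording$params$g_KL),
                   g_input = as.list(recording$params$g_input))
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
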