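# Run, mask and result serialization. A run is a directory bundle:
#   signal.tsv   samples x channels (header ch_0001...)
#   events.tsv   BIDS-like: onset_sample, duration_samples, label
#   meta.json    sampling rate, grid geometry, ground truth, seed

#' Write a recording run to a directory bundle
#'
#' @param run An `ecog_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "ecog_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- data.table::as.data.table(t(run$signal))
  data.table::setnames(sig, sprintf("ch_%04d", seq_len(nrow(run$signal))))
  data.table::fwrite(sig, file.path(dir, "signal.tsv"), sep = "\t")
  data.table::fwrite(run$events, file.path(dir, "events.tsv"), sep = "\t")
  meta <- list(sampling_rate_hz = run$sampling_rate_hz,
               n_rows = run$layout$n_rows, n_cols = run$layout$n_cols,
               spacing_mm = run$layout$spacing_mm,
               truth = run$truth[setdiff(names(run$truth), "gains")])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a recording run from a directory bundle
#'
#' @param dir Directory written by [write_run()].
#' @return An `ecog_run`.
#' @export
read_run <- function(dir) {
  for (f in c("signal.tsv", "events.tsv", "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("missing run file: %s", file.path(dir, f)), call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sig <- data.table::fread(file.path(dir, "signal.tsv"), sep = "\t")
  ev <- as.data.frame(data.table::fread(file.path(dir, "events.tsv"), sep = "\t"))
  truth <- meta$truth
  if (!is.null(truth$class_centers)) {
    truth$class_centers <- lapply(seq_len(nrow(truth$class_centers)),
                                  function(i) as.numeric(truth$class_centers[i, ]))
  }
  structure(
    list(signal = t(as.matrix(sig)),
         sampling_rate_hz = meta$sampling_rate_hz,
         layout = grid_layout(meta$n_rows, meta$n_cols, meta$spacing_mm),
         events = ev, truth = truth),
    class = "ecog_run"
  )
}

#' Write a channel mask as TSV
#'
#' @param mask A `channel_mask`.
#' @param path Output file.
#' @export
write_channel_mask <- function(mask, path) {
  data.table::fwrite(as.data.frame(mask), path, sep = "\t")
  invisible(path)
}

#' Write a selection result as TSV (long format)
#'
#' One row per electrode x movement with `r2` (6 decimals), `p` and `sig`.
#'
#' @param selection A `selection_result`.
#' @param path Output file.
#' @export
write_selection <- function(selection, path) {
  long <- do.call(rbind, lapply(seq_along(selection$movements), function(m) {
    data.frame(electrode = seq_len(nrow(selection$r2)),
               movement = selection$movements[m],
               r2 = sprintf("%.6f", selection$r2[, m]),
               p = selection$pvals[, m], sig = selection$sig[, m])
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a winner-takes-all map as TSV
#'
#' Columns: electrode, row, col, winner, winner_r2 (6 decimals). Requires a
#' map built with a layout.
#'
#' @param topo A `topo_map`.
#' @param path Output file.
#' @export
write_topo_map <- function(topo, path) {
  if (is.null(topo$layout)) stop("topo map has no layout", call. = FALSE)
  pos <- channel_positions(topo$layout)
  out <- data.frame(electrode = topo$map$electrode,
                    row = pos$row[topo$map$electrode],
                    col = pos$col[topo$map$electrode],
                    winner = ifelse(is.na(topo$map$winner), "none",
                                    topo$map$winner),
                    winner_r2 = sprintf("%.6f", topo$map$winner_r2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation result as JSON
#'
#' @param cv A `cv_result`.
#' @param path Output file.
#' @export
write_cv_result <- function(cv, path) {
  out <- list(mode = cv$mode, n_folds = cv$n_folds,
              fold_accuracies = cv$fold_acc, mean_accuracy = cv$mean_acc,
              sd_accuracy = cv$sd_acc,
              confusion = matrix(as.integer(cv$confusion), nrow(cv$confusion)),
              p_value = cv$p_value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
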