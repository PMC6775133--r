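#' Winner-takes-all movement map
#'
#' Labels every electrode with the movement that has the highest r-squared,
#' provided that maximum exceeds `threshold` (strictly — an electrode whose
#' best r-squared is exactly at the threshold is excluded). Ties go to the
#' lowest class index.
#'
#' @param selection A [permutation_fdr()] result (its `r2` matrix is used).
#' @param threshold Inclusion threshold on the best r-squared (default 0.2).
#' @param layout Optional [grid_layout()] carried along for plotting/export.
#' @return A `topo_map`: data frame `map` with `electrode`, `winner`
#'   (movement name or `NA`), `winner_r2`, plus the threshold, movements and
#'   layout.
#' @export
winner_takes_all <- function(selection, threshold = 0.2, layout = NULL) {
  stopifnot(inherits(selection, "selection_result"))
  r2 <- selection$r2
  best <- max.col(r2, ties.method = "first")
  best_r2 <- r2[cbind(seq_len(nrow(r2)), best)]
  winner <- ifelse(best_r2 > threshold, selection$movements[best], NA_character_)
  structure(
    list(map = data.frame(electrode = seq_len(nrow(r2)), winner = winner,
                          winner_r2 = best_r2, stringsAsFactors = FALSE),
         threshold = threshold, movements = selection$movements,
         layout = layout),
    class = "topo_map"
  )
}

#' Per-movement r-squared grids
#'
#' Arranges the per-electrode r-squared values of every movement on the
#' electrode grid (rows x columns x movements), for rendering and export.
#' Values are carried through unchanged.
#'
#' @param selection A [permutation_fdr()] result.
#' @param layout A [grid_layout()] whose channel count matches the selection.
#' @return A 3-d array `n_rows x n_cols x movements`.
#' @export
mean_r2_map <- function(selection, layout) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(layout, "grid_layout"))
  if (nrow(selection$r2) != layout$n_channels) {
    stop("electrode count does not match the layout", call. = FALSE)
  }
  out <- array(NA_real_, c(layout$n_rows, layout$n_cols,
                           ncol(selection$r2)),
               dimnames = list(NULL, NULL, selection$movements))
  pos <- channel_positions(layout)
  for (m in seq_len(ncol(selection$r2))) {
    out[cbind(pos$row, pos$col, m)] <- selection$r2[, m]
  }
  out
}

#' Plot a winner-takes-all topographic map
#'
#' @param x A `topo_map` built with a layout.
#' @param ... Ignored.
#' @export
plot.topo_map <- function(x, ...) {
  if (is.null(x$layout)) stop("topo map has no layout", call. = FALSE)
  pos <- channel_positions(x$layout)
  cls <- match(x$map$winner, x$movements)
  cols <- grDevices::hcl.colors(length(x$movements), "Dark 3")
  graphics::plot(pos$col, max(pos$row) - pos$row + 1, pch = 22, cex = 3,
                 bg = ifelse(is.na(cls), "grey90", cols[cls]),
                 xlab = "column", ylab = "row",
                 main = sprintf("winner-takes-all (r2 > %g)", x$threshold))
  graphics::legend("topright", legend = x$movements, pt.bg = cols, pch = 22,
                   bty = "n")
  invisible(x)
}

#' @export
print.topo_map <- function(x, ...) {
  n_in <- sum(!is.na(x$map$winner))
  cat(sprintf("<topo_map> %d/%d electrodes above r2 > %g\n",
              n_in, nrow(x$map), x$threshold))
  invisible(x)
}
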