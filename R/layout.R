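#' Rectangular electrode-grid layout
#'
#' Describes a high-density subdural grid: electrodes on an `n_rows` x
#' `n_cols` rectangle with a fixed inter-electrode distance in millimetres.
#' Channels are numbered row-major, so channel \eqn{i} sits at row
#' \code{(i - 1) \%/\% n_cols + 1} and column \code{(i - 1) \%\% n_cols + 1}.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param spacing_mm Centre-to-centre electrode distance in mm (positive).
#'
#' @return An object of class `grid_layout` with fields `n_rows`, `n_cols`,
#'   `spacing_mm` and `n_channels`.
#' @examples
#' lay <- grid_layout(8, 8, 4)
#' channel_positions(lay)[1:3, ]
#' @export
grid_layout <- function(n_rows, n_cols, spacing_mm) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  stop_if_not_scalar_pos(spacing_mm, "spacing_mm")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, spacing_mm = spacing_mm,
         n_channels = n_rows * n_cols),
    class = "grid_layout"
  )
}

#' Channel positions of a grid layout
#'
#' @param layout A [grid_layout()].
#' @return A data frame with columns `channel`, `row`, `col`, `x_mm`, `y_mm`
#'   (row-major channel order; x runs along columns, y along rows).
#' @export
channel_positions <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  ch <- seq_len(layout$n_channels)
  row <- (ch - 1L) %/% layout$n_cols + 1L
  col <- (ch - 1L) %% layout$n_cols + 1L
  data.frame(channel = ch, row = row, col = col,
             x_mm = (col - 1L) * layout$spacing_mm,
             y_mm = (row - 1L) * layout$spacing_mm)
}

#' Channel index at a grid position
#'
#' @param layout A [grid_layout()].
#' @param row,col Grid coordinates (1-based).
#' @return Integer channel index (row-major).
#' @export
channel_at <- function(layout, row, col) {
  stopifnot(inherits(layout, "grid_layout"))
  if (any(row < 1 | row > layout$n_rows | col < 1 | col > layout$n_cols)) {
    stop("position outside the grid", call. = FALSE)
  }
  as.integer((row - 1L) * layout$n_cols + col)
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout> %d x %d electrodes, %.3g mm spacing (%d channels)\n",
              x$n_rows, x$n_cols, x$spacing_mm, x$n_channels))
  invisible(x)
}
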