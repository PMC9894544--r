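#' Adenoma growth geometry: the cell-number to linear-size law
#'
#' An adenoma's proliferating (initiated) cell population of `y` cells is
#' linked to its linear size `S` (cm) by a power law
#' `y / y_r = (S / S_r)^d` with growth dimension `d = 2` (areal growth within
#' crypt-like structures) or `d = 3` (volumetric growth). `y_r` is the cell
#' number at the reference size `S_r = 1` cm; only the ratio of the division
#' rate to `y_r` is identifiable in fits, so `y_r` is fixed by convention:
#' 800 (2d) / 3200 (3d) cells for sessile and flat adenoma, 200 (2d) /
#' 400 (3d) for peduncular adenoma.
#'
#' @param d growth dimension, 2 or 3.
#' @param y_r reference cell number at `S_r`.
#' @param y0 detection limit in cells (smallest detectable clone).
#' @param S_r reference linear size in cm (default 1).
#' @return an object of class `adenoma_geometry`.
#' @examples
#' g <- geometry(d = 2, y_r = 800, y0 = 30)
#' cells_to_size(g, 30)   # detection limit ~0.19 cm
#' @export
geometry <- function(d, y_r, y0, S_r = 1) {
  stopifnot(d %in% c(2, 3), is.numeric(y_r), y_r > 0, is.numeric(y0), y0 >= 1,
            S_r > 0)
  structure(list(d = d, y_r = y_r, y0 = y0, S_r = S_r),
            class = "adenoma_geometry")
}

#' Default geometry for a given adenoma shape and growth dimension
#'
#' Applies the conventional reference cell numbers (800/3200 sessile and flat,
#' 200/400 peduncular for 2d/3d) and the optimized detection limits: 30 cells
#' for sessile/flat and 40 cells for peduncular adenoma.
#'
#' @param shape one of `"sessile"`, `"peduncular"`, `"flat"`, `"all"`.
#' @param d growth dimension, 2 or 3.
#' @export
default_geometry <- function(shape = c("all", "sessile", "peduncular", "flat"),
                             d = 2) {
  shape <- match.arg(shape)
  y_r <- if (shape == "peduncular") c(`2` = 200, `3` = 400)[[as.character(d)]]
         else c(`2` = 800, `3` = 3200)[[as.character(d)]]
  y0 <- if (shape == "peduncular") 40 else 30
  geometry(d = d, y_r = y_r, y0 = y0)
}

#' Convert cell numbers to linear size and back
#'
#' `cells_to_size()` maps a clone of `y` initiated cells to its linear size in
#' cm, `S = S_r * (y / y_r)^(1/d)`; `size_to_cells()` is the inverse
#' `y = y_r * (S / S_r)^d`. Cell numbers may be fractional (size-category
#' boundaries are kept exact; only simulation rounds).
#'
#' @param g an [geometry()] object.
#' @param y cell number(s), positive.
#' @param S linear size(s) in cm, positive.
#' @return numeric vector of sizes (cm) or cell numbers.
#' @export
cells_to_size <- function(g, y) {
  stopifnot(inherits(g, "adenoma_geometry"))
  if (any(!is.finite(y) | y <= 0)) stop("cell number must be positive")
  g$S_r * (y / g$y_r)^(1 / g$d)
}

#' @rdname cells_to_size
#' @export
size_to_cells <- function(g, S) {
  stopifnot(inherits(g, "adenoma_geometry"))
  if (any(!is.finite(S) | S <= 0)) stop("size must be positive")
  g$y_r * (S / g$S_r)^g$d
}

#' @export
print.adenoma_geometry <- function(x, ...) {
  cat(sprintf("adenoma geometry: d = %d, y_r = %g cells at %g cm, y0 = %g cells (%.2f cm)\n",
              x$d, x$y_r, x$S_r, x$y0, cells_to_size(x, x$y0)))
  invisible(x)
}
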