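#' Electrode grid geometry
#'
#' An `electrode_grid` maps each channel to a position on the cortical
#' surface in millimetres relative to bregma: ML (medio-lateral, positive
#' lateral from the midline) and AP (antero-posterior, positive anterior of
#' bregma).  Positions must lie on a regular square lattice with spacing
#' `pitch_mm`; the default pitch of 0.5 mm matches a dense epidural
#' recording array.  Grid adjacency uses 8-connectivity (the 8 surrounding
#' lattice nodes), which keeps diagonally touching regions connected at
#' sub-millimetre pitch.
#'
#' @param layout data.frame with columns `channel_id`, `ml_mm`, `ap_mm`
#'   (one row per channel), or a named list `channel_id -> c(ml, ap)`.
#' @param pitch_mm inter-electrode spacing in mm (default 0.5).
#' @param side recording hemisphere, `"left"` or `"right"` (metadata only).
#' @return object of class `electrode_grid`: `positions` (data.frame
#'   channel_id/ml_mm/ap_mm), `pitch_mm`, `side`, and integer lattice
#'   coordinates `col`/`row` used for adjacency.
#' @examples
#' lay <- data.frame(channel_id = c("a", "b", "c", "d"),
#'                   ml_mm = c(0, 0.5, 0, 0.5), ap_mm = c(0, 0, 0.5, 0.5))
#' g <- electrode_grid(lay, pitch_mm = 0.5)
#' grid_neighbors(g, "a")
#' @export
electrode_grid <- function(layout, pitch_mm = 0.5, side = c("left", "right")) {
  side <- match.arg(side)
  if (is.list(layout) && !is.data.frame(layout)) {
    layout <- data.frame(
      channel_id = names(layout),
      ml_mm = vapply(layout, function(p) as.numeric(p[[1]]), 0),
      ap_mm = vapply(layout, function(p) as.numeric(p[[2]]), 0),
      stringsAsFactors = FALSE)
  }
  req <- c("channel_id", "ml_mm", "ap_mm")
  if (!all(req %in% names(layout)))
    stop("layout must provide columns: ", paste(req, collapse = ", "))
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || pitch_mm <= 0)
    stop("`pitch_mm` must be a single positive number")
  ids <- as.character(layout$channel_id)
  if (anyDuplicated(ids))
    stop("duplicate channel_id in layout: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ml <- as.numeric(layout$ml_mm); ap <- as.numeric(layout$ap_mm)
  if (!all(is.finite(ml)) || !all(is.finite(ap)))
    stop("non-finite electrode coordinates")
  col <- lattice_index(ml, pitch_mm, "ml_mm")
  row <- lattice_index(ap, pitch_mm, "ap_mm")
  key <- paste(col, row)
  if (anyDuplicated(key))
    stop("duplicate electrode position(s): ",
         paste(ids[duplicated(key)], collapse = ", "))
  structure(
    list(positions = data.frame(channel_id = ids, ml_mm = ml, ap_mm = ap,
                                stringsAsFactors = FALSE),
         pitch_mm = pitch_mm, side = side, col = col, row = row),
    class = "electrode_grid")
}

# snap coordinates to integer lattice indices; off-lattice is a hard error
# (tolerance 1e-9 mm so float-parsed layouts still validate)
lattice_index <- function(x, pitch, what) {
  rel <- (x - min(x)) / pitch
  idx <- round(rel)
  off <- abs(rel - idx) * pitch
  if (any(off > 1e-9))
    stop("off-lattice ", what, " coordinate(s) (pitch ", pitch, " mm): ",
         paste(format(x[off > 1e-9]), collapse = ", "))
  as.integer(idx)
}

#' Read an electrode layout file
#'
#' Accepts a 3-column CSV (`channel_id, ml_mm, ap_mm`) or a JSON object
#' `{channel_id: [ml_mm, ap_mm], ...}`.
#'
#' @param path file path; format chosen by extension (`.json` vs `.csv`).
#' @inheritParams electrode_grid
#' @return an [electrode_grid()].
#' @export
read_layout <- function(path, pitch_mm = 0.5, side = "left") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lay <- jsonlite::read_json(path, simplifyVector = TRUE)
    electrode_grid(as.list(lay), pitch_mm = pitch_mm, side = side)
  } else {
    lay <- utils::read.csv(path, stringsAsFactors = FALSE)
    electrode_grid(lay, pitch_mm = pitch_mm, side = side)
  }
}

#' @rdname electrode_grid
#' @param grid an `electrode_grid`.
#' @param channel_id single channel label.
#' @return `grid_neighbors`: character vector of the 8-connected neighbours
#'   of `channel_id` present on the grid.
#' @export
grid_neighbors <- function(grid, channel_id) {
  stopifnot(inherits(grid, "electrode_grid"))
  i <- match(channel_id, grid$positions$channel_id)
  if (is.na(i)) stop("unknown channel_id: ", channel_id)
  dc <- abs(grid$col - grid$col[i]); dr <- abs(grid$row - grid$row[i])
  nb <- dc <= 1L & dr <= 1L & !(dc == 0L & dr == 0L)
  grid$positions$channel_id[nb]
}

# adjacency edge list (pairs of channel indices) under 8-connectivity
grid_edges <- function(grid, subset = NULL) {
  n <- length(grid$col)
  idx <- if (is.null(subset)) seq_len(n) else subset
  col <- grid$col[idx]; row <- grid$row[idx]
  edges <- NULL
  for (a in seq_along(idx)) {
    dc <- abs(col - col[a]); dr <- abs(row - row[a])
    nb <- which(dc <= 1L & dr <= 1L & seq_along(idx) > a)
    if (length(nb)) edges <- rbind(edges, cbind(a, nb))
  }
  edges
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat("electrode_grid: ", nrow(x$positions), " channels, pitch ",
      x$pitch_mm, " mm, ", x$side, " hemisphere\n",
      "  ML span [", min(x$positions$ml_mm), ", ", max(x$positions$ml_mm),
      "] mm, AP span [", min(x$positions$ap_mm), ", ",
      max(x$positions$ap_mm), "] mm (bregma origin)\n", sep = "")
  invisible(x)
}

#' Build a regular rectangular grid layout
#'
#' Convenience constructor for a dense rectangular array: `n_ap` rows
#' (antero-posterior) by `n_ml` columns (medio-lateral) at a fixed pitch.
#' The default 16 x 12 = 192 channels at 0.5 mm pitch spans 7.5 mm (AP) by
#' 5.5 mm (ML), emulating a dense epidural array over one hemisphere.
#'
#' @param n_ap,n_ml number of rows (AP) and columns (ML).
#' @param pitch_mm lattice pitch in mm.
#' @param ml_origin,ap_origin coordinates (mm from bregma) of the most
#'   medial, most posterior electrode.
#' @inheritParams electrode_grid
#' @return an [electrode_grid()]; channels are labelled `ch001 ...` in
#'   row-major order (AP rows from posterior to anterior, ML within row).
#' @export
rect_grid <- function(n_ap = 16L, n_ml = 12L, pitch_mm = 0.5,
                      ml_origin = 1.0, ap_origin = -5.5, side = "left") {
  ap <- ap_origin + pitch_mm * rep(seq_len(n_ap) - 1L, each = n_ml)
  ml <- ml_origin + pitch_mm * rep(seq_len(n_ml) - 1L, times = n_ap)
  ids <- sprintf("ch%03d", seq_len(n_ap * n_ml))
  electrode_grid(data.frame(channel_id = ids, ml_mm = ml, ap_mm = ap,
                            stringsAsFactors = FALSE),
                 pitch_mm = pitch_mm, side = side)
}
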