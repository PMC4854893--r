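#' Participation-index threshold curve
#'
#' As the PI threshold is lowered from the maximum observed value, more and
#' more channels fall inside the network boundary.  This curve — the number
#' of channels with `PI >= threshold`, evaluated at each distinct PI value
#' in descending order — is the "PI histogram" whose knee point defines the
#' network boundary threshold.
#'
#' @param pm a [participation_index()] map.
#' @param cluster_rank which retained cluster (eigenvalue rank) to use;
#'   default the strongest.
#' @return object of class `pi_curve`: `thresholds` (distinct PI values,
#'   descending), `counts` (channels with PI >= threshold, strictly
#'   increasing; last element = M), `cluster_rank`.
#' @export
pi_curve <- function(pm, cluster_rank = pm$cluster_ranks[1]) {
  stopifnot(inherits(pm, "participation_map"))
  col <- match(cluster_rank, pm$cluster_ranks)
  if (is.na(col)) stop("cluster rank ", cluster_rank, " not in this map")
  v <- pm$PI[, col]
  thresholds <- sort(unique(v), decreasing = TRUE)
  counts <- vapply(thresholds, function(t) sum(v >= t), 0L)
  structure(list(thresholds = thresholds, counts = counts,
                 cluster_rank = cluster_rank),
            class = "pi_curve")
}

#' Knee point of the PI threshold curve
#'
#' Finds where the growth in channel count slows: both axes of the
#' (threshold, count) polyline are min-max scaled to `[0, 1]` and the point
#' with maximum perpendicular distance to the chord joining the curve's
#' endpoints is returned (the maximum-chord-distance, "Kneedle"-style
#' rule).  Ties are broken toward the higher PI value, i.e. the smaller and
#' more conservative network.  A perfectly linear curve has no knee; the
#' highest-PI interior point is returned with a warning.
#'
#' @param curve a [pi_curve()] with at least 3 distinct thresholds.
#' @return the PI threshold at the knee (numeric scalar), with attribute
#'   `index` giving its position on the curve.
#' @export
knee_point <- function(curve) {
  stopifnot(inherits(curve, "pi_curve"))
  th <- curve$thresholds; ct <- as.numeric(curve$counts)
  n <- length(th)
  if (n < 3L) {
    e <- simpleError(paste0("degenerate PI curve: need >= 3 distinct ",
                            "thresholds, got ", n))
    class(e) <- c("degenerate_curve_error", class(e))
    stop(e)
  }
  x <- (th - min(th)) / (max(th) - min(th))
  y <- (ct - min(ct)) / (max(ct) - min(ct))
  # perpendicular distance from each point to the endpoint chord
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  d <- abs(dx * (y - y[1]) - dy * (x - x[1])) / sqrt(dx^2 + dy^2)
  interior <- 2:(n - 1L)
  dmax <- max(d[interior])
  cand <- interior[d[interior] >= dmax - 1e-12]
  idx <- cand[1L]                          # thresholds descend: first = highest PI
  if (dmax < 1e-12)
    warning("no clear knee: PI curve is linear; using highest-PI interior point")
  structure(th[idx], index = idx)
}

#' Demarcate the network boundary on the electrode grid
#'
#' Thresholds the PI map of one cluster at the knee value, labels
#' 8-connected components among the supra-threshold channels, and keeps the
#' component containing the maximum-PI channel.  The retained member set is
#' the functional network; its area is the member count times the squared
#' electrode pitch.  A cluster whose maximum PI is below 0.2 is flagged
#' weak (such networks have fairly small synchronization strength and are
#' excluded from the headline network count).
#'
#' @param pm a [participation_index()] map.
#' @param cluster_rank which retained cluster to demarcate.
#' @param grid the [electrode_grid()]; must cover the same channels.
#' @param threshold PI threshold, normally from [knee_point()].  `NULL`
#'   falls back (with a warning) to including every channel — used when the
#'   PI curve is degenerate.
#' @param weak_pi_max clusters with maximum PI below this are flagged weak
#'   (default 0.2).
#' @return object of class `network_boundary`: `cluster_rank`,
#'   `pi_threshold`, `member_channels`, `area_mm2`
#'   (= members x pitch_mm^2), `is_weak`, `max_pi`, and `outline`
#'   (ordered boundary polygon(s) in mm, for overlay plots).
#' @export
demarcate_boundary <- function(pm, cluster_rank, grid, threshold,
                               weak_pi_max = 0.2) {
  stopifnot(inherits(pm, "participation_map"),
            inherits(grid, "electrode_grid"))
  col <- match(cluster_rank, pm$cluster_ranks)
  if (is.na(col)) stop("cluster rank ", cluster_rank, " not in this map")
  v <- pm$PI[, col]
  pos <- match(pm$channel_ids, grid$positions$channel_id)
  if (anyNA(pos)) stop("channels missing from the electrode grid: ",
                       paste(pm$channel_ids[is.na(pos)], collapse = ", "))
  if (is.null(threshold)) {
    warning("no PI threshold: including all channels in the boundary")
    threshold <- min(v)
  }
  if (threshold > max(v) || threshold < 0)
    stop("threshold ", threshold, " outside the PI range [0, ", max(v), "]")
  supra <- which(v >= threshold)
  if (!length(supra)) {
    e <- simpleError("empty network: no channel reaches the PI threshold")
    class(e) <- c("empty_network_error", class(e))
    stop(e)
  }
  comp <- label_components(grid, pos[supra])
  keep <- comp == comp[which.max(v[supra])]
  members <- pm$channel_ids[supra[keep]]
  structure(
    list(cluster_rank = cluster_rank,
         pi_threshold = as.numeric(threshold),
         member_channels = members,
         area_mm2 = length(members) * grid$pitch_mm^2,
         is_weak = max(v) < weak_pi_max,
         max_pi = max(v),
         outline = member_outline(grid, members)),
    class = "network_boundary")
}

# label 8-connected components among grid nodes `idx` (indices into the
# grid's channel order); returns a component id per element of `idx`
label_components <- function(grid, idx) {
  n <- length(idx)
  if (n == 1L) return(1L)
  edges <- grid_edges(grid, subset = idx)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# ordered outline polygon(s) of the member cells: each member occupies a
# pitch-sized square centred on its electrode; edges shared by two members
# cancel, the rest are chained into closed loops (list of data.frames with
# ml_mm/ap_mm columns, largest loop first)
member_outline <- function(grid, members) {
  i <- match(members, grid$positions$channel_id)
  h <- grid$pitch_mm / 2
  ml <- grid$positions$ml_mm[i]; ap <- grid$positions$ap_mm[i]
  # edge key: quantized endpoints (lattice half-steps are exact multiples)
  q <- function(x) as.integer(round(x / h))
  seg <- function(x1, y1, x2, y2) cbind(q(x1), q(y1), q(x2), q(y2))
  edges <- rbind(seg(ml - h, ap - h, ml + h, ap - h),   # bottom
                 seg(ml + h, ap - h, ml + h, ap + h),   # right
                 seg(ml + h, ap + h, ml - h, ap + h),   # top
                 seg(ml - h, ap + h, ml - h, ap - h))   # left
  und <- apply(edges, 1, function(e)
    paste(pmin(e[c(1, 2)], e[c(3, 4)])[1], pmin(e[2], e[4]),
          pmax(e[1], e[3]), pmax(e[2], e[4])))
  keep <- und %in% names(which(table(und) == 1L))
  edges <- edges[keep, , drop = FALSE]
  loops <- list()
  used <- rep(FALSE, nrow(edges))
  starts <- paste(edges[, 1], edges[, 2])
  while (any(!used)) {
    cur <- which(!used)[1L]
    loop <- edges[cur, 1:2, drop = FALSE]
    used[cur] <- TRUE
    repeat {
      tail_key <- paste(edges[cur, 3], edges[cur, 4])
      loop <- rbind(loop, edges[cur, 3:4])
      nxt <- which(!used & starts == tail_key)
      if (!length(nxt)) break
      cur <- nxt[1L]
      used[cur] <- TRUE
    }
    loops[[length(loops) + 1L]] <-
      data.frame(ml_mm = loop[, 1] * h, ap_mm = loop[, 2] * h)
  }
  loops[order(-vapply(loops, nrow, 0L))]
}

#' @export
print.network_boundary <- function(x, ...) {
  cat("network_boundary: cluster ", x$cluster_rank, ", ",
      length(x$member_channels), " channels, area ", x$area_mm2,
      " mm^2, PI threshold ", signif(x$pi_threshold, 4),
      if (x$is_weak) " [weak: max PI < 0.2]", "\n", sep = "")
  invisible(x)
}

#' Render the PI topography
#'
#' Writes a machine-readable channel map (JSON: per-channel PI, position
#' and network membership) and optionally a PNG heatmap of the PI over the
#' electrode grid with the network boundary overlaid.  Rendering is
#' deterministic for fixed inputs.
#'
#' @param pm a [participation_index()] map.
#' @param grid the [electrode_grid()].
#' @param boundary a [demarcate_boundary()] result.
#' @param json_path path for the JSON map (`NULL` to skip writing).
#' @param png_path path for the PNG heatmap (`NULL`, the default, skips
#'   plotting — headless mode).
#' @return invisibly, the per-channel map as a data.frame
#'   (`channel_id, ml_mm, ap_mm, pi, member`).
#' @export
render_topography <- function(pm, grid, boundary, json_path = NULL,
                              png_path = NULL) {
  stopifnot(inherits(pm, "participation_map"),
            inherits(boundary, "network_boundary"))
  col <- match(boundary$cluster_rank, pm$cluster_ranks)
  pos <- grid$positions[match(pm$channel_ids, grid$positions$channel_id), ]
  map <- data.frame(channel_id = pm$channel_ids,
                    ml_mm = pos$ml_mm, ap_mm = pos$ap_mm,
                    pi = as.numeric(pm$PI[, col]),
                    member = pm$channel_ids %in% boundary$member_channels,
                    stringsAsFactors = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(map, json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    mls <- sort(unique(map$ml_mm)); aps <- sort(unique(map$ap_mm))
    zm <- matrix(NA_real_, length(mls), length(aps))
    zm[cbind(match(map$ml_mm, mls), match(map$ap_mm, aps))] <- map$pi
    graphics::image(mls, aps, zm, col = grDevices::hcl.colors(64, "YlOrRd",
                                                              rev = TRUE),
                    xlab = "ML (mm)", ylab = "AP (mm)",
                    main = sprintf("Participation index, cluster %d (area %.2f mm2)",
                                   boundary$cluster_rank, boundary$area_mm2))
    for (loop in boundary$outline)
      graphics::lines(loop$ml_mm, loop$ap_mm, lwd = 2, lty = 2)
    graphics::abline(h = 0, lty = 3)       # bregma line
  }
  invisible(map)
}
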