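#' High-density subdural grid geometry
#'
#' Default geometry: 8x8 contacts of 1.08 mm^2 at 3 mm center-to-center pitch.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch Center-to-center pitch, mm.
#' @param electrode_area Contact surface area, mm^2.
#' @return Object of class `grid_layout` with a `positions` data frame
#'   (`channel`, `row`, `col`), row-major channel order.
#' @export
grid_layout <- function(n_rows = 8L, n_cols = 8L, pitch = 3, electrode_area = 1.08) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0, electrode_area > 0)
  pos <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))[, c("row", "col")]
  pos$channel <- sprintf("ch%02d", seq_len(nrow(pos)))
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      pitch = pitch, electrode_area = electrode_area,
      positions = pos[, c("channel", "row", "col")]
    ),
    class = "grid_layout"
  )
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf(
    "<grid_layout> %dx%d, pitch %g mm, contact area %g mm^2\n",
    x$n_rows, x$n_cols, x$pitch, x$electrode_area
  ))
  invisible(x)
}

#' Virtual electrode-shorting scheme
#'
#' Tiles the grid into groups of adjacent contacts that are electrically
#' shorted (averaged): `"small"` keeps every contact separate, `"pair"` groups
#' 1x2 neighbours, `"quad"` groups 2x2 blocks. The effective contact area of a
#' group is the contact area times the group size (1.08 / 2.16 / 4.32 mm^2 on
#' the default grid), while the summed physical area over the whole grid is
#' unchanged.
#'
#' @param layout A [grid_layout()].
#' @param label `"small"`, `"pair"` or `"quad"`.
#' @param orientation Pair orientation, `"horizontal"` (default) or
#'   `"vertical"`.
#' @return Object of class `shorting_scheme`: `groups` (named list of channel
#'   vectors, deterministic tiling from the top-left corner), `effective_area`
#'   (mm^2 per group), `label`, `centroids` (group positions).
#' @export
make_shorting_scheme <- function(layout, label = c("small", "pair", "quad"),
                                 orientation = c("horizontal", "vertical")) {
  stopifnot(inherits(layout, "grid_layout"))
  label <- match.arg(label)
  orientation <- match.arg(orientation)
  pos <- layout$positions
  key <- function(r, c) pos$channel[match(paste(r, c), paste(pos$row, pos$col))]
  groups <- switch(label,
    small = as.list(pos$channel),
    pair = {
      if (orientation == "horizontal") {
        if (layout$n_cols %% 2 != 0) stop("n_cols not divisible by 2")
        unlist(lapply(seq_len(layout$n_rows), function(r) {
          lapply(seq(1, layout$n_cols, by = 2), function(c) key(r, c(c, c + 1)))
        }), recursive = FALSE)
      } else {
        if (layout$n_rows %% 2 != 0) stop("n_rows not divisible by 2")
        unlist(lapply(seq(1, layout$n_rows, by = 2), function(r) {
          lapply(seq_len(layout$n_cols), function(c) key(c(r, r + 1), c))
        }), recursive = FALSE)
      }
    },
    quad = {
      if (layout$n_rows %% 2 != 0 || layout$n_cols %% 2 != 0) {
        stop("grid not divisible into 2x2 blocks")
      }
      unlist(lapply(seq(1, layout$n_rows, by = 2), function(r) {
        lapply(seq(1, layout$n_cols, by = 2), function(c) {
          key(c(r, r, r + 1, r + 1), c(c, c + 1, c, c + 1))
        })
      }), recursive = FALSE)
    }
  )
  names(groups) <- sprintf("g%02d", seq_along(groups))
  centroids <- do.call(rbind, lapply(groups, function(g) {
    p <- pos[pos$channel %in% g, ]
    data.frame(row = mean(p$row), col = mean(p$col))
  }))
  centroids$group <- names(groups)
  structure(
    list(
      groups = groups,
      effective_area = layout$electrode_area * length(groups[[1]]),
      label = label,
      electrode_area = layout$electrode_area,
      centroids = centroids[, c("group", "row", "col")]
    ),
    class = "shorting_scheme"
  )
}

#' @export
print.shorting_scheme <- function(x, ...) {
  cat(sprintf(
    "<shorting_scheme> '%s': %d groups of %d, effective area %g mm^2\n",
    x$label, length(x$groups), length(x$groups[[1]]), x$effective_area
  ))
  invisible(x)
}

#' Summed physical contact area of a scheme
#'
#' Identical across small/pair/quad schemes on the same grid
#' (64 x 1.08 = 69.12 mm^2 by default).
#'
#' @param scheme A [make_shorting_scheme()] result.
#' @return Total area, mm^2.
#' @export
scheme_total_area <- function(scheme) {
  stopifnot(inherits(scheme, "shorting_scheme"))
  length(scheme$groups) * scheme$effective_area
}

#' Apply virtual shorting to a recording
#'
#' Shorted contacts average the activity of their underlying tissue: each
#' output channel is the arithmetic mean of its group's member signals.
#'
#' @param rec An [recording()].
#' @param scheme A [make_shorting_scheme()] result; its channels must all be
#'   present in `rec`.
#' @return A [recording()] with one channel per group, carrying the group's
#'   effective area.
#' @export
apply_shorting <- function(rec, scheme) {
  stopifnot(inherits(rec, "hfo_recording"), inherits(scheme, "shorting_scheme"))
  missing <- setdiff(unlist(scheme$groups), rec$channel_ids)
  if (length(missing) > 0) {
    stop("channels not present in recording: ", paste(missing, collapse = ", "))
  }
  data <- do.call(rbind, lapply(scheme$groups, function(g) {
    colMeans(rec$data[g, , drop = FALSE])
  }))
  recording(data, rec$fs,
            channel_ids = names(scheme$groups), layout = rec$layout,
            electrode_area = scheme$effective_area)
}

#' Common-average re-referencing
#'
#' Subtracts the per-sample mean across channels from every channel; the mean
#' (CAR signal) is returned for artifact screening.
#'
#' @param rec A multi-channel [recording()].
#' @return `list(recording =, car =)` where `car` is the common-average
#'   waveform.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "hfo_recording"))
  if (nrow(rec$data) < 2) stop("common average reference needs >= 2 channels")
  car <- colMeans(rec$data)
  out <- rec
  out$data <- sweep(rec$data, 2, car)
  list(recording = out, car = car)
}
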