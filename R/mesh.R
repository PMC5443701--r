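## Graded 1-D meshes.
##
## Axes are built by marching with a spacing function
##   h(x) = min(h_max, h_k + slope * |x - x_k|)  over all anchors x_k,
## i.e. fine spacing at anchor points (charged surfaces, walls, layer
## interfaces) growing linearly with distance, capped at h_max. Anchors are
## always nodes of the resulting axis.

## march across one segment [a, b] with end spacings ha, hb
.march_segment <- function(a, b, ha, hb, slope, h_max) {
  len <- b - a
  if (len <= 0) return(numeric(0))
  hmin <- min(ha, hb, h_max)
  if (len <= 1.5 * hmin) return(c(a, b))
  pts <- a
  x <- a
  repeat {
    h <- min(h_max, ha + slope * (x - a), hb + slope * (b - x))
    x <- x + h
    hb_end <- min(h_max, hb)
    if (x >= b - 0.55 * hb_end) break
    pts <- c(pts, x)
  }
  c(pts, b)
}

#' Graded 1-D axis with anchored refinement
#'
#' Builds a node vector spanning the anchor points, with the requested
#' spacing at each anchor and spacing growing linearly (slope `growth`)
#' away from anchors, capped at `h_max`. All anchors are nodes.
#'
#' @param anchors positions that must be nodes (nm), sorted or not.
#' @param h_anchor target spacing at each anchor (recycled).
#' @param growth dimensionless growth slope of the spacing away from an
#'   anchor (default 0.35).
#' @param h_max maximum spacing (nm).
#' @return sorted numeric vector of node positions.
#' @keywords internal
graded_axis <- function(anchors, h_anchor, growth = 0.35, h_max) {
  o <- order(anchors)
  anchors <- anchors[o]
  h_anchor <- rep_len(h_anchor, length(anchors))[o]
  ## collapse duplicate anchors, keeping the finest spacing
  keep <- !duplicated(signif(anchors, 12))
  if (!all(keep)) {
    h_anchor <- vapply(unique(signif(anchors, 12)), function(a)
      min(h_anchor[signif(anchors, 12) == a]), 0)
    anchors <- unique(signif(anchors, 12))
  }
  pts <- anchors[1]
  for (k in seq_len(length(anchors) - 1)) {
    seg <- .march_segment(anchors[k], anchors[k + 1],
                          h_anchor[k], h_anchor[k + 1], growth, h_max)
    pts <- c(pts, seg[-1])
  }
  sort(unique(pts))
}

## insert midpoints everywhere (used by grid-convergence checks)
.refine_axis <- function(x) sort(unique(c(x, (x[-1] + x[-length(x)]) / 2)))
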