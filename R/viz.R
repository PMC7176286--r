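# Circular rule-network rendering. Items are laid out on a circle grouped
# by gene; each rule contributes one curved edge per RHS item, drawn from
# the centroid of its LHS items (a hyperedge fan for multi-item sides).
# True hierarchical edge bundling is approximated with quadratic Bezier
# curves whose control point is pulled toward the circle centre by a
# configurable bundling strength.

#' Build the plot specification for a rule network
#'
#' Computes the node layout and the per-edge visual channels without
#' touching a graphics device, so the channel mappings can be inspected
#' and tested: edge width increases with `seq_conf`, color intensity with
#' the chosen metric (default `cf`), and the line style marks rules with a
#' TF measure >= 1 (solid) versus the rest (dashed).
#'
#' @param ruleset a non-empty `RuleSet`.
#' @param color_by metric column driving color intensity.
#' @return list with data.frames `nodes` (`item`, `label`, `angle`, `x`,
#'   `y`) and `edges` (`rule`, `from_x`, `from_y`, `to`, `width`, `color`,
#'   `lty`, `value`).
#' @export
build_plot_spec <- function(ruleset, color_by = "cf") {
  if (!nrow(ruleset)) stop("nothing to plot: empty rule set")
  if (!color_by %in% names(ruleset)) stop("unknown metric: ", color_by)
  cb <- attr(ruleset, "codebook")
  items <- sort(unique(unlist(c(ruleset$lhs, ruleset$rhs))))
  lab <- if (is.null(cb)) as.character(items) else item_label(items, cb)
  ord <- order(lab)
  items <- items[ord]; lab <- lab[ord]
  angle <- 2 * pi * (seq_along(items) - 1L) / length(items)
  nodes <- data.frame(item = items, label = lab, angle = angle,
                      x = cos(angle), y = sin(angle),
                      stringsAsFactors = FALSE)

  conf <- ruleset$seq_conf
  width <- 0.5 + 2.5 * conf                      # monotone in seq_conf
  val <- ruleset[[color_by]]
  vr <- range(val[is.finite(val)], na.rm = TRUE)
  intensity <- if (diff(vr) > 0)
    (pmin(pmax(val, vr[1L]), vr[2L]) - vr[1L]) / diff(vr) else rep(1, length(val))
  intensity[!is.finite(intensity)] <- 1
  color <- grDevices::rgb(0.8 * intensity + 0.1, 0.1, 0.5 - 0.4 * intensity)
  tf <- if (is.null(ruleset$tf)) rep(NA_real_, nrow(ruleset)) else ruleset$tf
  lty <- ifelse(!is.na(tf) & tf >= 1, 1L, 2L)

  edges <- do.call(rbind, lapply(seq_len(nrow(ruleset)), function(i) {
    li <- match(ruleset$lhs[[i]], nodes$item)
    ri <- match(ruleset$rhs[[i]], nodes$item)
    data.frame(rule = i,
               from_x = mean(nodes$x[li]), from_y = mean(nodes$y[li]),
               to = ri, width = width[i], color = color[i], lty = lty[i],
               value = val[i], stringsAsFactors = FALSE)
  }))
  list(nodes = nodes, edges = edges, color_by = color_by)
}

quad_bezier <- function(x0, y0, cx, cy, x1, y1, n = 40L) {
  t <- seq(0, 1, length.out = n)
  list(x = (1 - t)^2 * x0 + 2 * (1 - t) * t * cx + t^2 * x1,
       y = (1 - t)^2 * y0 + 2 * (1 - t) * t * cy + t^2 * y1)
}

#' Plot a rule set as a circular bundled-edge network
#'
#' Nodes are the distinct items (labelled `probe/GENE=state`), arranged on
#' a circle; each rule draws one curved edge per RHS item from its LHS
#' centroid, so the edge count is at least the rule count. Layout and
#' output are deterministic given the seed; the same input and seed
#' produce a byte-identical SVG.
#'
#' @param ruleset a non-empty `RuleSet`.
#' @param path output file; extension selects the device (svg, png, pdf).
#' @param color_by metric column driving color intensity.
#' @param bundling pull of the Bezier control point toward the centre,
#'   in `[0, 1]`.
#' @param seed layout seed (kept for the determinism contract).
#' @return the plot spec, invisibly.
#' @export
plot_rule_network <- function(ruleset, path, color_by = "cf",
                              bundling = 0.8, seed = 0L) {
  spec <- build_plot_spec(ruleset, color_by)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = 8, height = 8),
         png = grDevices::png(path, width = 800, height = 800),
         pdf = grDevices::pdf(path, width = 8, height = 8),
         stop("unsupported plot format: ", ext))
  on.exit(grDevices::dev.off())
  set.seed(seed)
  graphics::par(mar = c(1, 1, 3, 1))  # device-local, discarded on close
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.7, 1.7), ylim = c(-1.7, 1.7), asp = 1)
  nd <- spec$nodes; ed <- spec$edges
  for (i in seq_len(nrow(ed))) {
    tx <- nd$x[ed$to[i]]; ty <- nd$y[ed$to[i]]
    mx <- (ed$from_x[i] + tx) / 2; my <- (ed$from_y[i] + ty) / 2
    bz <- quad_bezier(ed$from_x[i], ed$from_y[i],
                      mx * (1 - bundling), my * (1 - bundling), tx, ty)
    graphics::lines(bz$x, bz$y, lwd = ed$width[i], col = ed$color[i],
                    lty = ed$lty[i])
    graphics::points(tx, ty, pch = 20, cex = 0.8, col = ed$color[i])
  }
  graphics::points(nd$x, nd$y, pch = 21, bg = "grey85", cex = 1.4)
  off <- 1.08
  for (i in seq_len(nrow(nd))) {
    deg <- nd$angle[i] * 180 / pi
    flip <- deg > 90 && deg < 270
    graphics::text(nd$x[i] * off, nd$y[i] * off, nd$label[i], cex = 0.55,
                   srt = if (flip) deg + 180 else deg,
                   adj = if (flip) 1 else 0)
  }
  graphics::title(main = sprintf("%d sequential rules (color: %s)",
                                 nrow(ruleset), spec$color_by))
  graphics::legend(
    "bottomleft", bty = "n", cex = 0.6,
    lty = c(1, 1, 1, 2), lwd = c(3, 1, 1.5, 1.5),
    col = c("grey40", "grey40",
            grDevices::rgb(0.9, 0.1, 0.1), "grey40"),
    legend = c("high seqConf (wide)", "low seqConf (thin)",
               sprintf("high %s (warm)", spec$color_by),
               "no TF support (dashed)"))
  invisible(spec)
}
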