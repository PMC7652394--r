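# Deterministic SVG rendering of lineage trees following the live-cell
# figure conventions: interphase as a gray bar, mitosis as a green bar,
# division as a bifurcation, MN as a red cross and bi/multi-nucleation as
# an orange double circle at cycle start, death as a purple square and
# fading as a hollow diamond at event time, cell fusion as a blue
# connector. SVG text is generated directly so output is byte-stable.

#' Default tree rendering style
#'
#' @param px_per_hour Horizontal scale (pixels per hour).
#' @param row_height Vertical distance between leaf branches (pixels).
#' @param movie_length Right edge for censored branches (hours); defaults
#'   to the latest time observed in the tree.
#' @return A list of style settings (colors follow the figure
#'   conventions; override any entry).
#' @export
tree_style <- function(px_per_hour = 10, row_height = 24,
                       movie_length = NULL) {
  list(px_per_hour = px_per_hour, row_height = row_height,
       movie_length = movie_length, margin = 30,
       interphase_col = "#9e9e9e", mitosis_col = "#2e9e46",
       connector_col = "#9e9e9e", fusion_col = "#1f63c4",
       mn_col = "#d62728", death_col = "#7b2d8b", bi_col = "#e08214",
       fading_col = "#b8a000", bar_width = 6)
}

# leaf-stacked y layout; children in label order, internal cells centered
tree_layout <- function(tree) {
  ys <- new.env(parent = emptyenv())
  leaf <- 0
  assign_y <- function(cell) {
    kids <- tree$children[[cell]]
    y <- if (is.null(kids) || length(kids) == 0L) {
      leaf <<- leaf + 1
      leaf
    } else {
      mean(vapply(kids, assign_y, numeric(1)))
    }
    assign(cell, y, envir = ys)
    y
  }
  assign_y(tree$root)
  list(y = ys, n_leaves = leaf)
}

#' Render a lineage tree as SVG
#'
#' Produces a deterministic stand-alone SVG document for one lineage
#' tree; every cell record maps to exactly one horizontal segment whose
#' extent is the cell's observed lifespan.
#'
#' @param tree A `lineage_tree`.
#' @param path Optional output path; when given the SVG is written there.
#' @param style A [tree_style()] list.
#' @return The SVG document as a character vector of lines (invisibly
#'   when `path` is given).
#' @export
render_tree <- function(tree, path = NULL, style = tree_style()) {
  r <- tree$records
  tmax <- style$movie_length %||%
    max(c(r$t_birth, r$t_nebd, r$t_division), na.rm = TRUE)
  lay <- tree_layout(tree)
  px <- function(t) style$margin + t * style$px_per_hour
  py <- function(cell) style$margin + get(cell, envir = lay$y) * style$row_height
  w <- ceiling(px(tmax) + style$margin)
  h <- ceiling(style$margin * 2 + (lay$n_leaves + 1) * style$row_height)
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   w, h, w, h),
           sprintf('<title>lineage %s</title>', tree$lineage_id))
  line <- function(x1, y1, x2, y2, col, sw) {
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
            fmt_num(x1), fmt_num(y1), fmt_num(x2), fmt_num(y2), col,
            fmt_num(sw))
  }
  for (i in seq_len(nrow(r))) {
    cell <- r$cell_id[i]
    y <- py(cell)
    t0 <- r$t_birth[i]
    t_end <- if (!is.na(r$t_division[i])) r$t_division[i]
             else if (!is.na(r$t_nebd[i])) r$t_nebd[i]
             else tmax
    t_gray_end <- if (!is.na(r$t_nebd[i])) r$t_nebd[i] else t_end
    out <- c(out, line(px(t0), y, px(t_gray_end), y,
                       style$interphase_col, style$bar_width))
    if (!is.na(r$t_nebd[i]) && !is.na(r$t_division[i])) {
      out <- c(out, line(px(r$t_nebd[i]), y, px(r$t_division[i]), y,
                         style$mitosis_col, style$bar_width))
    }
    kids <- tree$children[[cell]]
    if (!is.null(kids) && length(kids) > 0L && !is.na(r$t_division[i])) {
      yk <- vapply(kids, py, numeric(1))
      out <- c(out, line(px(r$t_division[i]), min(yk),
                         px(r$t_division[i]), max(yk),
                         style$connector_col, 2))
    }
    # event symbols
    if (r$micronuclei[i]) {
      out <- c(out,
               line(px(t0) - 4, y - 4, px(t0) + 4, y + 4, style$mn_col, 2),
               line(px(t0) - 4, y + 4, px(t0) + 4, y - 4, style$mn_col, 2))
    }
    if (r$bi_multi_nuclei[i]) {
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="4" fill="none" stroke="%s" stroke-width="2"/>',
        fmt_num(px(t0) + 8), fmt_num(y - 8), style$bi_col))
    }
    if (r$death[i]) {
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="8" height="8" fill="%s"/>',
        fmt_num(px(t_end) - 4), fmt_num(y - 4), style$death_col))
    }
    if (r$fading[i]) {
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="8" height="8" fill="none" stroke="%s" stroke-width="2" transform="rotate(45 %s %s)"/>',
        fmt_num(px(t_end) - 4), fmt_num(y - 4), style$fading_col,
        fmt_num(px(t_end)), fmt_num(y)))
    }
  }
  if (nrow(tree$fusions) > 0L) {
    for (i in seq_len(nrow(tree$fusions))) {
      a <- tree$fusions[i, 1]; b <- tree$fusions[i, 2]
      ta <- r$t_birth[match(a, r$cell_id)]
      out <- c(out, line(px(ta) + 4, py(a), px(ta) + 4, py(b),
                         style$fusion_col, 2))
    }
  }
  # time axis (hours)
  ax_y <- h - style$margin / 2
  out <- c(out, line(px(0), ax_y, px(tmax), ax_y, "#000000", 1))
  for (t in seq(0, floor(tmax), by = 12)) {
    out <- c(out,
             line(px(t), ax_y - 3, px(t), ax_y + 3, "#000000", 1),
             sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%s h</text>',
                     fmt_num(px(t)), fmt_num(ax_y + 14), fmt_num(t)))
  }
  out <- c(out, "</svg>")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Render every tree of a dataset as an SVG gallery
#'
#' Writes one SVG per lineage into per-condition subdirectories of
#' `dir` (the supplementary-panel layout: all trees grouped by
#' condition).
#'
#' @param trees List of `lineage_tree` objects.
#' @param dir Output directory (created if needed).
#' @param style A [tree_style()] list.
#' @return Character vector of written paths, invisibly.
#' @export
render_gallery <- function(trees, dir, style = tree_style()) {
  paths <- character(0)
  for (tree in trees) {
    cond <- paste(tree$condition, collapse = "_")
    cond <- gsub("[^A-Za-z0-9_.-]", "-", cond)
    sub <- file.path(dir, cond)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(sub, paste0(tree$lineage_id, ".svg"))
    render_tree(tree, p, style)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Plot a lineage tree with base graphics
#'
#' Quick interactive view using the same layout and symbol conventions as
#' [render_tree()].
#'
#' @param x A `lineage_tree`.
#' @param movie_length Right edge for censored branches (hours).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lineage_tree <- function(x, movie_length = NULL, ...) {
  r <- x$records
  tmax <- movie_length %||%
    max(c(r$t_birth, r$t_nebd, r$t_division), na.rm = TRUE)
  lay <- tree_layout(x)
  py <- function(cell) get(cell, envir = lay$y)
  graphics::plot(NA, xlim = c(0, tmax), ylim = c(lay$n_leaves + 1, 0),
                 xlab = "time (h)", ylab = "", yaxt = "n",
                 main = x$lineage_id, ...)
  for (i in seq_len(nrow(r))) {
    cell <- r$cell_id[i]
    y <- py(cell)
    t_end <- if (!is.na(r$t_division[i])) r$t_division[i]
             else if (!is.na(r$t_nebd[i])) r$t_nebd[i]
             else tmax
    tg <- if (!is.na(r$t_nebd[i])) r$t_nebd[i] else t_end
    graphics::segments(r$t_birth[i], y, tg, y, col = "gray55", lwd = 4)
    if (!is.na(r$t_nebd[i]) && !is.na(r$t_division[i])) {
      graphics::segments(r$t_nebd[i], y, r$t_division[i], y,
                         col = "forestgreen", lwd = 4)
    }
    kids <- x$children[[cell]]
    if (!is.null(kids) && length(kids) > 0L && !is.na(r$t_division[i])) {
      yk <- vapply(kids, py, numeric(1))
      graphics::segments(r$t_division[i], min(yk), r$t_division[i], max(yk),
                         col = "gray55")
    }
    if (r$micronuclei[i]) graphics::points(r$t_birth[i], y, pch = 4,
                                           col = "red", lwd = 2)
    if (r$death[i]) graphics::points(t_end, y, pch = 15, col = "purple")
    if (r$fading[i]) graphics::points(t_end, y, pch = 5, col = "goldenrod")
    if (r$bi_multi_nuclei[i]) graphics::points(r$t_birth[i] + 0.5, y - 0.25,
                                               pch = 1, col = "darkorange")
  }
  invisible(x)
}
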