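# Weight-proportional Voronoi treemaps: additively weighted (power) Voronoi
# diagrams with Lloyd centroid moves and multiplicative weight adaptation,
# nested recursively for term hierarchies, coloured by adjusted significance
# and serialised as deterministic SVG.

#' Layout configuration for Voronoi treemaps
#'
#' @param container convex polygon as an n x 2 matrix of vertices
#'   (counter-clockwise); default the unit square.
#' @param max_area_error per-cell relative area error tolerance in (0, 0.2);
#'   the default 0.01 means every converged cell's area is within 1 percent
#'   of its weight share.
#' @param max_iterations iteration cap of the solver.
#' @param seed integer seed for initial site placement.
#' @return a `layout_config` list.
#' @export
layout_config <- function(container = unit_square(), max_area_error = 0.01,
                          max_iterations = 500L, seed = 1L) {
  container <- as.matrix(container)
  if (ncol(container) != 2L || nrow(container) < 3L)
    stop("container must be an n x 2 polygon matrix")
  if (!is_convex(container)) stop("container must be convex")
  if (max_area_error <= 0 || max_area_error >= 0.2)
    stop("max_area_error must lie in (0, 0.2)")
  structure(list(container = container, max_area_error = max_area_error,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "layout_config")
}

#' Unit square container polygon
#' @export
unit_square <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2L, byrow = TRUE)
}

#' Regular polygon approximating a circle, usable as a container
#' @param center,radius circle parameters.
#' @param n number of vertices.
#' @export
circle_container <- function(center = c(0.5, 0.5), radius = 0.5, n = 64L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

is_convex <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1L, ]; c_ <- poly[((i + 1L) %% n) + 1L, ]
    cr <- (b[1L] - a[1L]) * (c_[2L] - b[2L]) - (b[2L] - a[2L]) * (c_[1L] - b[1L])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

poly_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  i <- seq_len(n); j <- c(2:n, 1L)
  abs(sum(poly[i, 1L] * poly[j, 2L] - poly[j, 1L] * poly[i, 2L])) / 2
}

point_in_convex <- function(p, poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1L, ]
    cr <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    if (abs(cr) < 1e-14) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

random_points_in_poly <- function(n, poly) {
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    p <- c(runif(1, xr[1L], xr[2L]), runif(1, yr[1L], yr[2L]))
    if (point_in_convex(p, poly)) {
      got <- got + 1L
      out[got, ] <- p
    }
  }
  out
}

#' Power diagram (additively weighted Voronoi) clipped to a container
#'
#' Cell i is the set of container points x with
#' `|x - p_i|^2 - w_i <= |x - p_j|^2 - w_j` for all j, computed by iterative
#' half-plane clipping of the convex container. Coincident sites with equal
#' weights are separated by a seeded jitter of 1e-9 (logged as a message).
#'
#' @param sites n x 2 matrix of site coordinates inside the container.
#' @param weights numeric power weights (`w = r^2`), one per site.
#' @param container convex polygon matrix.
#' @param seed seed for the coincident-site jitter.
#' @return list of cell polygons (possibly empty matrices), one per site;
#'   their areas sum to the container area.
#' @export
power_diagram <- function(sites, weights, container = unit_square(), seed = 1L) {
  sites <- as.matrix(sites)
  if (nrow(sites) != length(weights)) stop("one weight per site required")
  key <- paste(sites[, 1L], sites[, 2L], weights)
  if (anyDuplicated(key)) {
    message("coincident sites with equal weights: applying 1e-9 jitter")
    dup <- which(duplicated(key))
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    sites[dup, ] <- sites[dup, , drop = FALSE] +
      matrix(runif(2L * length(dup), -1e-9, 1e-9), ncol = 2L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  cpp_power_diagram(sites[, 1L], sites[, 2L], weights, as.matrix(container))
}

#' Solve a weight-proportional Voronoi partition
#'
#' Iteratively moves each site to its cell centroid and rescales its power
#' weight until every cell's relative area error is at most
#' `config$max_area_error`, or `config$max_iterations` is reached (then
#' flagged non-converged). Deterministic given `config$seed`.
#'
#' @param weights positive target weights, one per cell.
#' @param config a [layout_config()].
#' @return a `treemap_layout`: list with `polygons` (list of matrices),
#'   `areas`, `targets` (normalised weights), `sites`, `converged`,
#'   `iterations`, `max_rel_error`, `container`.
#' @export
solve_areas <- function(weights, config = layout_config()) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive")
  n <- length(weights)
  cont <- config$container
  if (n == 1L) {
    out <- list(polygons = list(cont), areas = poly_area(cont),
                targets = 1, sites = matrix(colMeans(cont), 1L),
                converged = TRUE, iterations = 0L, max_rel_error = 0,
                container = cont)
    class(out) <- "treemap_layout"
    return(out)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config$seed)
  sites <- random_points_in_poly(n, cont)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  w0 <- rep(1e-9 * poly_area(cont), n)
  res <- cpp_solve_areas(sites[, 1L], sites[, 2L], w0, weights,
                         as.matrix(cont), config$max_area_error,
                         config$max_iterations)
  out <- list(polygons = res$cells, areas = res$areas,
              targets = weights / sum(weights),
              sites = cbind(res$x, res$y), converged = res$converged,
              iterations = res$iterations,
              max_rel_error = res$max_rel_error, container = cont)
  class(out) <- "treemap_layout"
  out
}

#' @export
print.treemap_layout <- function(x, ...) {
  cat(sprintf("treemap_layout: %d cells, %s after %d iterations (max rel. area error %.3g)\n",
              length(x$polygons),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_rel_error))
  invisible(x)
}

#' Lay out a weighted term hierarchy as a nested Voronoi treemap
#'
#' The top level partitions the container among the root terms; each child
#' level recursively partitions its parent's polygon. An internal term whose
#' weight exceeds the sum of its children keeps the excess as its own
#' residual cell.
#'
#' @param terms data frame with columns `term`, `parent` (`NA` for top-level
#'   terms) and positive `weight`; every internal term's weight must be at
#'   least the sum of its children's weights.
#' @param config a [layout_config()].
#' @return a `treemap_cells` data frame with columns `term`, `parent`,
#'   `level`, `weight`, `area`, `converged`, and a `polygons` attribute
#'   (named list of cell polygons).
#' @export
layout_hierarchy <- function(terms, config = layout_config()) {
  stopifnot(all(c("term", "parent", "weight") %in% names(terms)))
  if (any(terms$weight <= 0)) stop("weights must be positive")
  if (anyDuplicated(terms$term)) stop("duplicate term in hierarchy")
  known <- terms$parent %in% c(NA, terms$term)
  if (!all(known)) stop("parent term absent from hierarchy")
  # cycle check: parent links must form a forest
  g <- igraph::graph_from_data_frame(
    data.frame(from = terms$term[!is.na(terms$parent)],
               to = terms$parent[!is.na(terms$parent)]),
    directed = TRUE, vertices = data.frame(name = terms$term))
  if (!igraph::is_dag(g)) stop("cyclic term graph")
  children <- split(terms$term, factor(terms$parent, levels = terms$term))
  rows <- list()
  polys <- list()
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  recurse <- function(term_ids, weights, polygon, parent, level) {
    counter$i <- counter$i + 1L
    cfg <- layout_config(container = polygon,
                         max_area_error = config$max_area_error,
                         max_iterations = config$max_iterations,
                         seed = config$seed + counter$i)
    lay <- solve_areas(weights, cfg)
    for (i in seq_along(term_ids)) {
      id <- term_ids[i]
      rows[[length(rows) + 1L]] <<- data.frame(
        term = id, parent = parent, level = level, weight = weights[i],
        area = lay$areas[i], converged = lay$converged,
        stringsAsFactors = FALSE)
      polys[[id]] <<- lay$polygons[[i]]
      kids <- children[[id]]
      if (!is.null(kids) && length(kids) && !grepl("::residual$", id)) {
        kw <- terms$weight[match(kids, terms$term)]
        wsum <- sum(kw)
        if (wsum > weights[i] * (1 + 1e-9))
          stop(sprintf("children of '%s' outweigh their parent", id))
        excess <- weights[i] - wsum
        ids2 <- kids; w2 <- kw
        if (excess > 1e-9 * weights[i]) {
          ids2 <- c(kids, paste0(id, "::residual"))
          w2 <- c(kw, excess)
        }
        recurse(ids2, w2, lay$polygons[[i]], id, level + 1L)
      }
    }
  }
  top <- terms$term[is.na(terms$parent)]
  recurse(top, terms$weight[match(top, terms$term)], config$container,
          NA_character_, 1L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "polygons") <- polys
  attr(out, "container") <- config$container
  class(out) <- c("treemap_cells", "data.frame")
  out
}

#' Colour treemap cells by adjusted significance
#'
#' Continuous ramp over `-log10(p_adj)` for significant terms (darker for
#' smaller p), a visually distinct flat band for non-significant terms
#' (`p_adj >= alpha`, strict `<` rule), neutral grey for cells without a
#' result row.
#'
#' @param cells a `treemap_cells` data frame.
#' @param results an `enrichment_result` (needs `term` and `p_adj`).
#' @param alpha significance threshold.
#' @param ramp_low,ramp_high hex colours of the ramp endpoints, fixed for
#'   reproducibility.
#' @param cap `-log10(p)` value mapped to the dark end of the ramp.
#' @return `cells` with `p_adj` and `color` columns added.
#' @export
color_by_significance <- function(cells, results, alpha = 0.05,
                                  ramp_low = "#FDD49E", ramp_high = "#7F0000",
                                  cap = 10) {
  ns_color <- "#D9D9D9"; missing_color <- "#BBBBBB"
  p <- results$p_adj[match(cells$term, results$term)]
  ramp <- colorRamp(c(ramp_low, ramp_high))
  colors <- vapply(p, function(pi) {
    if (is.na(pi)) return(missing_color)
    if (pi >= alpha) return(ns_color)
    t0 <- -log10(alpha)
    t <- min(1, max(0, (-log10(pi) - t0) / (cap - t0)))
    rgb(ramp(t)[1L], ramp(t)[2L], ramp(t)[3L], maxColorValue = 255)
  }, character(1))
  cells$p_adj <- p
  cells$color <- colors
  cells
}

fmt_num <- function(x) sprintf("%.6f", x)

#' Serialise treemap cells as SVG
#'
#' One `<g>` group per hierarchy level; each polygon carries its term id,
#' weight, achieved area and adjusted p as data attributes. Output is byte
#' deterministic for identical inputs.
#'
#' @param cells a `treemap_cells` data frame, optionally coloured by
#'   [color_by_significance()].
#' @param path output path of the SVG file.
#' @param width,height pixel size of the drawing.
#' @return the path, invisibly.
#' @export
treemap_svg <- function(cells, path, width = 600, height = 600) {
  polys <- attr(cells, "polygons")
  cont <- attr(cells, "container")
  xr <- range(cont[, 1L]); yr <- range(cont[, 2L])
  sx <- function(x) (x - xr[1L]) / diff(xr) * width
  sy <- function(y) height - (y - yr[1L]) / diff(yr) * height
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                     as.integer(width), as.integer(height),
                     as.integer(width), as.integer(height)))
  for (lev in sort(unique(cells$level))) {
    lines <- c(lines, sprintf('<g id="level%d">', lev))
    sel <- which(cells$level == lev)
    for (i in sel) {
      poly <- polys[[cells$term[i]]]
      if (is.null(poly) || nrow(poly) < 3L) next
      pts <- paste(paste(fmt_num(sx(poly[, 1L])), fmt_num(sy(poly[, 2L])),
                         sep = ","), collapse = " ")
      fill <- if ("color" %in% names(cells)) cells$color[i] else "#FFFFFF"
      padj <- if ("p_adj" %in% names(cells) && !is.na(cells$p_adj[i]))
        sprintf("%.6g", cells$p_adj[i]) else "NA"
      lines <- c(lines, sprintf(
        '<polygon points="%s" fill="%s" stroke="#000000" stroke-width="%s" data-term="%s" data-weight="%s" data-area="%s" data-p-adj="%s"/>',
        pts, fill, fmt_num(1 / lev), cells$term[i],
        fmt_num(cells$weight[i]), fmt_num(cells$area[i]), padj))
    }
    lines <- c(lines, "</g>")
  }
  lines <- c(lines, "</svg>")
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Write treemap cell geometries as TSV
#'
#' One row per cell: term, parent, level, weight, area, p_adj, colour and
#' the polygon as a semicolon-separated vertex list.
#' @param cells a `treemap_cells` data frame.
#' @param path output path.
#' @export
write_cells_tsv <- function(cells, path) {
  polys <- attr(cells, "polygons")
  geom <- vapply(cells$term, function(id) {
    p <- polys[[id]]
    if (is.null(p) || !nrow(p)) return("")
    paste(paste(fmt_num(p[, 1L]), fmt_num(p[, 2L]), sep = ","), collapse = ";")
  }, character(1))
  df <- as.data.frame(cells)
  df$polygon <- geom
  write_tsv(df, path)
}
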