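# Static report: 2D scatterplot with convex hulls per cluster, coloring by
# cluster / bin / annotation, and per-cluster / per-bin count charts, as a
# self-contained HTML file plus a machine-readable JSON twin.

#' Convex hulls of clustered points
#'
#' Computes the 2D convex hull of each non-noise cluster, vertices in
#' counter-clockwise order. Clusters of one or two points (or collinear
#' points) yield degenerate hulls -- a point or a segment -- returned as-is.
#'
#' @param coords n x 2 matrix of coordinates (rownames = IDs).
#' @param labels Named vector of cluster labels (`-1` = noise) covering a
#'   subset of the rownames.
#' @return Named list, one entry per non-noise cluster, each an m x 2 matrix
#'   of hull vertices (CCW).
#' @export
convex_hulls <- function(coords, labels) {
  if (inherits(labels, "cluster_labels")) labels <- labels$labels
  labs <- sort(unique(labels[labels != -1]))
  out <- list()
  for (lab in labs) {
    ids <- names(labels)[labels == lab]
    pts <- coords[ids, , drop = FALSE]
    if (nrow(pts) <= 2L) {
      out[[as.character(lab)]] <- unname(pts)
      next
    }
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    hull <- pts[h, , drop = FALSE]
    # chull returns clockwise order; flip if the signed area is negative
    x <- hull[, 1L]; y <- hull[, 2L]
    area2 <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
    if (area2 < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
    out[[as.character(lab)]] <- unname(hull)
  }
  out
}

report_palette <- function(n) {
  if (n <= 0) return(character(0))
  grDevices::hcl.colors(max(n, 2L), "Dark 3")[seq_len(n)]
}

#' Render the binning report
#'
#' Writes `report.json` (all plotted data, verbatim) and `report.html` (a
#' self-contained page: the 2D scatterplot with convex hulls, buttons to
#' color by cluster, bin or annotation, and per-cluster / per-bin count bar
#' charts). Points carry the sequence ID as a tooltip. Associates without
#' own coordinates are plotted at their representative's position and
#' flagged as such in the JSON.
#'
#' @param bundle A list with elements `points` (data frame: `id`, `x`, `y`,
#'   `role`, `cluster`, `bin`, `annotation`, `placed_at_representative`),
#'   `hulls` (from [convex_hulls()]), `counts` (list with `cluster` and
#'   `bin` named count vectors).
#' @param out_dir Output directory.
#' @return Invisibly, the paths of the two files written.
#' @export
render_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create report directory: ", out_dir)
  pts <- bundle$points
  json_path <- file.path(out_dir, "report.json")
  html_path <- file.path(out_dir, "report.html")

  payload <- list(
    points = pts,
    hulls = lapply(bundle$hulls, function(h)
      lapply(seq_len(nrow(h)), function(i) as.numeric(h[i, ]))),
    counts = list(cluster = as.list(bundle$counts$cluster),
                  bin = as.list(bundle$counts$bin))
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")

  html <- build_report_html(pts, bundle$hulls, bundle$counts)
  writeLines(html, html_path)
  invisible(c(html = html_path, json = json_path))
}

# -- internal HTML assembly ------------------------------------------------

svg_scatter <- function(pts, hulls, width = 760, height = 560) {
  ok <- is.finite(pts$x) & is.finite(pts$y)
  p <- pts[ok, , drop = FALSE]
  pad <- 20
  rx <- range(p$x); ry <- range(p$y)
  sx <- function(x) pad + (x - rx[1]) / max(diff(rx), 1e-12) * (width - 2 * pad)
  sy <- function(y) height - pad - (y - ry[1]) / max(diff(ry), 1e-12) *
    (height - 2 * pad)
  polys <- vapply(hulls, function(h) {
    sprintf('<polygon points="%s" fill="none" stroke="black" stroke-width="1"/>',
            paste(sprintf("%.1f,%.1f", sx(h[, 1]), sy(h[, 2])),
                  collapse = " "))
  }, character(1))
  circ <- sprintf(
    '<circle cx="%.1f" cy="%.1f" r="3" data-cluster="%s" data-bin="%s" data-annotation="%s"><title>%s</title></circle>',
    sx(p$x), sy(p$y), p$cluster, p$bin,
    ifelse(is.na(p$annotation), "", p$annotation), p$id)
  c(sprintf('<svg id="scatter" width="%d" height="%d">', width, height),
    polys, circ, "</svg>")
}

svg_barchart <- function(counts, title, width = 360, height = 220) {
  if (length(counts) == 0) return(sprintf("<p>%s: none</p>", title))
  counts <- counts[order(names(counts))]
  n <- length(counts)
  pad <- 24
  bw <- (width - 2 * pad) / n
  h <- (height - 2 * pad) * as.numeric(counts) / max(as.numeric(counts))
  cols <- report_palette(n)
  bars <- sprintf(
    '<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s"><title>%s: %d</title></rect>',
    pad + (seq_len(n) - 1) * bw, height - pad - h, bw * 0.85, h, cols,
    names(counts), as.integer(counts))
  labs <- sprintf(
    '<text x="%.1f" y="%d" font-size="9" text-anchor="middle">%s</text>',
    pad + (seq_len(n) - 0.55) * bw, height - pad + 12, names(counts))
  c(sprintf("<h3>%s</h3>", title),
    sprintf('<svg width="%d" height="%d">', width, height), bars, labs,
    "</svg>")
}

build_report_html <- function(pts, hulls, counts) {
  cl_levels <- sort(unique(stats::na.omit(pts$cluster)))
  bin_levels <- sort(unique(stats::na.omit(pts$bin)))
  ann_levels <- sort(unique(stats::na.omit(pts$annotation)))
  pal <- function(lv) jsonlite::toJSON(
    stats::setNames(as.list(report_palette(length(lv))), as.character(lv)),
    auto_unbox = TRUE)
  c("<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>Binning report</title>",
    "<style>body{font-family:sans-serif;margin:20px}button{margin:2px}</style>",
    "</head><body>",
    "<h2>Bootstrapped supervised binning report</h2>",
    "<div>Color by: <button onclick=\"recolor('cluster')\">cluster</button>",
    "<button onclick=\"recolor('bin')\">bin</button>",
    "<button onclick=\"recolor('annotation')\">annotation</button></div>",
    svg_scatter(pts, hulls),
    svg_barchart(counts$cluster, "Sequences per cluster"),
    svg_barchart(counts$bin, "Sequences per bin"),
    "<script>",
    sprintf("var palettes = {cluster: %s, bin: %s, annotation: %s};",
            pal(cl_levels), pal(bin_levels), pal(ann_levels)),
    "function recolor(mode){",
    "  document.querySelectorAll('#scatter circle').forEach(function(c){",
    "    var v = c.getAttribute('data-' + mode);",
    "    var col = (v === '-1') ? '#999999' : palettes[mode][v];",
    "    c.setAttribute('fill', col || '#cccccc');",
    "  });",
    "}",
    "recolor('cluster');",
    "</script></body></html>")
}
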