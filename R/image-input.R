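#' Turn a raster image into an artificial conductivity field
#'
#' Reads a greyscale or colour raster (PNG/TIFF path, or a numeric matrix /
#' H x W x C array with values in `[0, 1]`), block-mean downsamples it by an
#' integer factor, maps intensity to a single channel (Rec. 709 luminance by
#' default) and masks out pixels below `threshold`. The surviving intensity
#' plays the role of an artificial equilibrium conductivity \eqn{\mu^*} on
#' the pixel grid, with pixel centres mapped into the unit square preserving
#' the aspect ratio (longest side = 1, origin at the lower-left corner).
#'
#' @param image file path (`.png`, `.tif`, `.tiff`) or numeric matrix/array.
#' @param downsample integer block size (`>= 1`).
#' @param mapping `"greyscale"` (luminance) or `"red"`, `"green"`, `"blue"`.
#' @param threshold mask threshold \eqn{\delta_{img}} in `[0, 1)`.
#' @return a `density_grid`: list with `values` (H x W), `x`, `y` (pixel
#'   centre coordinate matrices), `mask` (logical H x W), `scale`.
#' @export
image_to_density <- function(image, downsample = 1L,
                             mapping = c("greyscale", "red", "green", "blue"),
                             threshold = 0.1) {
  mapping <- match.arg(mapping)
  if (is.character(image)) {
    if (!file.exists(image)) stop("cannot read image file: ", image, call. = FALSE)
    ext <- tolower(tools::file_ext(image))
    image <- switch(ext,
      png = png::readPNG(image),
      tif = ,
      tiff = tiff::readTIFF(image),
      stop("unsupported image format: .", ext, call. = FALSE))
  }
  if (length(dim(image)) == 3L) {
    image <- switch(mapping,
      greyscale = 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3],
      red = image[, , 1], green = image[, , 2], blue = image[, , 3])
  }
  image <- as.matrix(image)
  if (any(image < 0)) stop("image intensities must be non-negative", call. = FALSE)
  downsample <- as.integer(downsample)
  if (downsample < 1L) stop("'downsample' must be >= 1", call. = FALSE)
  if (downsample > 1L) {
    H <- nrow(image) %/% downsample; W <- ncol(image) %/% downsample
    if (H < 1L || W < 1L) stop("downsampling factor larger than the image", call. = FALSE)
    image <- image[seq_len(H * downsample), seq_len(W * downsample), drop = FALSE]
    # block mean: average rows then columns
    rb <- (seq_len(nrow(image)) - 1L) %/% downsample + 1L
    cb <- (seq_len(ncol(image)) - 1L) %/% downsample + 1L
    image <- rowsum(image, rb) / downsample
    image <- t(rowsum(t(image), cb)) / downsample
  }
  H <- nrow(image); W <- ncol(image)
  scale <- 1 / max(H, W)
  # matrix row 1 is the top of the image; flip so y grows upwards
  x <- matrix(rep((seq_len(W) - 0.5) * scale, each = H), nrow = H)
  y <- matrix(rep((H - seq_len(H) + 0.5) * scale, times = W), nrow = H)
  mask <- image >= threshold
  if (!any(mask))
    warning("no pixel passes the intensity threshold; the graph will be empty",
            call. = FALSE)
  structure(list(values = image, x = x, y = y, mask = mask, scale = scale),
            class = "density_grid")
}

#' Pre-extract a pixel graph from a density grid
#'
#' Pixel cells play the role of the triangles of the mesh-based
#' pre-extraction: one node per masked pixel at its centre, edges between
#' mask-adjacent pixels (4-connectivity shares a side, like edge-only
#' sharing; 8-connectivity also shares corners, like edge-or-node sharing),
#' weights by the same AVG / ER rules on pixel intensities. ER conserves the
#' total masked intensity over non-isolated pixels.
#'
#' @param grid a [image_to_density()] grid.
#' @param connectivity 4 or 8.
#' @param weight_rule `"AVG"` or `"ER"`.
#' @return an igraph with `name` (`"p<row>_<col>"`), `x`, `y` vertex and
#'   `weight`, `length` edge attributes.
#' @export
grid_to_pregraph <- function(grid, connectivity = c(8, 4),
                             weight_rule = c("ER", "AVG")) {
  connectivity <- match.arg(as.character(connectivity[1]), c("8", "4"))
  weight_rule <- match.arg(weight_rule)
  H <- nrow(grid$values); W <- ncol(grid$values)
  idx <- which(grid$mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("the density mask is empty", call. = FALSE)
  key <- function(r, c) paste0("p", r, "_", c)
  on <- matrix(FALSE, H, W); on[idx] <- TRUE
  steps <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == "8") steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
  from <- character(0); to <- character(0)
  for (s in steps) {
    r2 <- idx[, 1] + s[1]; c2 <- idx[, 2] + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    ok[ok] <- on[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      from <- c(from, key(idx[ok, 1], idx[ok, 2]))
      to <- c(to, key(r2[ok], c2[ok]))
    }
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = key(idx[, 1], idx[, 2]),
                          x = grid$x[idx], y = grid$y[idx]))
  val <- stats::setNames(grid$values[idx], key(idx[, 1], idx[, 2]))
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    if (weight_rule == "AVG") {
      igraph::E(g)$weight <- (val[el[, 1]] + val[el[, 2]]) / 2
    } else {
      deg <- igraph::degree(g)
      igraph::E(g)$weight <- val[el[, 1]] / deg[el[, 1]] + val[el[, 2]] / deg[el[, 2]]
    }
    eln <- igraph::as_edgelist(g, names = FALSE)
    dx <- igraph::V(g)$x[eln[, 1]] - igraph::V(g)$x[eln[, 2]]
    dy <- igraph::V(g)$y[eln[, 1]] - igraph::V(g)$y[eln[, 2]]
    igraph::E(g)$length <- sqrt(dx^2 + dy^2)
  } else {
    igraph::E(g)$weight <- numeric(0)
    igraph::E(g)$length <- numeric(0)
  }
  g
}

#' Maximum-weight spanning forest
#'
#' Returns a spanning forest of maximal total edge weight -- the tree-like
#' structure closest to a loopy pre-extracted graph, suitable as input to the
#' tree-producing filter when loop recovery is intended afterwards.
#'
#' @param graph an igraph with a `weight` edge attribute.
#' @return an igraph spanning forest (same vertex set).
#' @export
max_weight_forest <- function(graph) {
  igraph::mst(graph, weights = -igraph::E(graph)$weight)
}

#' Re-insert loop-closing paths removed by the filter
#'
#' The filter can only produce tree-like components. For every pair of
#' candidate nodes (the terminals plus the leaves of the filtered graph)
#' whose hop distance in the pre-extracted graph is at most `radius` but
#' whose distance in the filtered graph is larger, the shortest pre-extracted
#' path between them (with its original weights) is re-inserted, restoring
#' the short loops the filter cut. `radius = 0` returns the filtered graph
#' unchanged.
#'
#' @param pregraph the loopy pre-extracted graph.
#' @param filtered the filtered graph (vertex names must be a subset of
#'   `pregraph`'s).
#' @param terminals optional `terminal_set` or character vector of node
#'   names; leaves of `filtered` are always candidates.
#' @param radius hop-count search radius, default 2.
#' @return an igraph whose edge set lies between `filtered`'s and
#'   `pregraph`'s.
#' @export
recover_loops <- function(pregraph, filtered, terminals = NULL, radius = 2L) {
  cand <- igraph::V(filtered)$name[igraph::degree(filtered) <= 1L]
  if (inherits(terminals, "terminal_set"))
    terminals <- c(terminals$sources, terminals$sinks)
  cand <- unique(c(cand, intersect(terminals, igraph::V(filtered)$name)))
  keep_names <- igraph::V(filtered)$name
  el <- igraph::as_edgelist(filtered, names = TRUE)
  keep_keys <- character(0)
  if (nrow(el)) keep_keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  if (radius >= 1L && length(cand) > 1L) {
    d_pre <- igraph::distances(pregraph, v = cand, to = cand, weights = NA)
    d_fil <- igraph::distances(filtered, v = cand, to = cand, weights = NA)
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
      if (b <= a) next
      if (d_pre[a, b] <= radius && d_fil[a, b] > d_pre[a, b]) {
        p <- igraph::shortest_paths(pregraph, from = cand[a], to = cand[b],
                                    weights = NA, output = "vpath")$vpath[[1]]
        pn <- igraph::as_ids(p)
        if (length(pn) > 1L) {
          seg <- cbind(pn[-length(pn)], pn[-1L])
          keep_keys <- c(keep_keys, paste(pmin(seg[, 1], seg[, 2]),
                                          pmax(seg[, 1], seg[, 2])))
          keep_names <- c(keep_names, pn)
        }
      }
    }
  }
  elp <- igraph::as_edgelist(pregraph, names = TRUE)
  pre_keys <- paste(pmin(elp[, 1], elp[, 2]), pmax(elp[, 1], elp[, 2]))
  eids <- which(pre_keys %in% unique(keep_keys))
  out <- igraph::subgraph_from_edges(pregraph, eids, delete.vertices = FALSE)
  out <- igraph::induced_subgraph(out, unique(keep_names))
  # filtered weights (e.g. BPW) take precedence on edges that survived the filter
  if (nrow(el)) {
    oel <- igraph::as_edgelist(out, names = TRUE)
    okey <- paste(pmin(oel[, 1], oel[, 2]), pmax(oel[, 1], oel[, 2]))
    fkey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    hit <- match(okey, fkey)
    w <- igraph::E(out)$weight
    w[!is.na(hit)] <- igraph::E(filtered)$weight[hit[!is.na(hit)]]
    igraph::E(out)$weight <- w
  }
  out
}
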