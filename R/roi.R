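#' Region annotations for valve sections
#'
#' An annotation is a set of named polygons outlining the anatomical regions
#' analysed separately throughout the pipeline: the valve `leaflet`s, the
#' `commissure`s (junctions of adjacent leaflets with the root wall, the site
#' of earliest mineral deposition in this model) and the aortic `root`.
#' Several polygons may share a name (e.g. two commissures); they are merged
#' at rasterization.
#'
#' Polygon vertices are `(x, y)` pairs in pixel units with `x` the column and
#' `y` the row, origin at the top-left image corner — the convention of common
#' annotation tools, fixed here so the ROI JSON round-trips unambiguously.
#'
#' @param regions a list of entries, each `list(name =, polygon =)` where
#'   `polygon` is an n-by-2 numeric matrix (or coercible) of `(x, y)` vertices.
#' @return a `region_annotation` object.
#' @export
region_annotation <- function(regions) {
  stopifnot(is.list(regions), length(regions) >= 1L)
  vocab <- c("leaflet", "commissure", "root")
  regions <- lapply(regions, function(r) {
    if (is.null(r$name) || !r$name %in% vocab)
      stop("region name must be one of: ", paste(vocab, collapse = ", "))
    poly <- as.matrix(r$polygon)
    storage.mode(poly) <- "double"
    if (nrow(poly) < 3L)
      stop("polygon for region '", r$name, "' has fewer than 3 vertices")
    if (ncol(poly) != 2L || anyNA(poly) || any(!is.finite(poly)))
      stop("polygon vertices must be a finite n-by-2 (x, y) matrix")
    list(name = r$name, polygon = poly)
  })
  structure(list(regions = regions), class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("<region_annotation>", length(x$regions), "polygon(s):\n")
  for (r in x$regions)
    cat("  ", r$name, ": ", nrow(r$polygon), " vertices\n", sep = "")
  invisible(x)
}

#' Read / write ROI polygon annotations as JSON
#'
#' Schema: `{"regions":[{"name":"commissure","polygon":[[x,y],...]}]}`.
#'
#' @param path file path.
#' @param annotation a [region_annotation()].
#' @return `read_roi_json` returns a `region_annotation`;
#'   `write_roi_json` returns `path` invisibly.
#' @export
read_roi_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  region_annotation(lapply(doc$regions, function(r) {
    poly <- r$polygon
    if (!is.matrix(poly)) poly <- do.call(rbind, lapply(poly, unlist))
    list(name = r$name, polygon = poly)
  }))
}

#' @rdname read_roi_json
#' @export
write_roi_json <- function(annotation, path) {
  stopifnot(inherits(annotation, "region_annotation"))
  doc <- list(regions = lapply(annotation$regions, function(r)
    list(name = jsonlite::unbox(r$name),
         polygon = lapply(seq_len(nrow(r$polygon)),
                          function(i) unname(r$polygon[i, ])))))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Even-odd ray-casting test, vectorized over points. Pixel centers sit at
# half-integer coordinates so integer-vertex polygon edges never hit a center
# exactly; the strict/non-strict pairing below gives half-open behaviour on
# the lattice (a [0,w)x[0,h) rectangle claims exactly w*h pixels).
point_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize region polygons to binary masks
#'
#' A pixel belongs to a region iff its center lies inside one of the region's
#' polygons (even-odd rule). Pixel `(row r, col c)` (1-based in R) covers the
#' unit square `[c-1, c) x [r-1, r)` so its center is `(c - 0.5, r - 0.5)`.
#'
#' @param annotation a [region_annotation()].
#' @param image_shape integer `c(height, width)` in pixels.
#' @return a `region_mask`: list with `masks` (named list of logical
#'   height-by-width matrices, one per distinct region name) and `shape`.
#' @export
rasterize <- function(annotation, image_shape) {
  stopifnot(inherits(annotation, "region_annotation"),
            length(image_shape) == 2L, all(image_shape >= 1L))
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  for (r in annotation$regions) {
    if (any(r$polygon[, 1] < 0 | r$polygon[, 1] > w |
            r$polygon[, 2] < 0 | r$polygon[, 2] > h))
      stop("polygon for region '", r$name, "' has vertices outside image bounds")
  }
  cx <- rep(seq_len(w) - 0.5, each = h)   # column-major like R matrices
  cy <- rep(seq_len(h) - 0.5, times = w)
  names_u <- unique(vapply(annotation$regions, `[[`, "", "name"))
  masks <- stats::setNames(vector("list", length(names_u)), names_u)
  for (nm in names_u) masks[[nm]] <- matrix(FALSE, h, w)
  for (r in annotation$regions) {
    inside <- matrix(point_in_polygon(cx, cy, r$polygon), h, w)
    masks[[r$name]] <- masks[[r$name]] | inside
  }
  structure(list(masks = masks, shape = c(h, w)), class = "region_mask")
}

#' Per-region mean of a scalar field
#'
#' Averages `field` over each region mask, optionally restricted to a `valid`
#' pixel field (e.g. the valid mask of a ratio map). An empty region yields
#' `NaN` with `empty = TRUE` rather than a silent zero.
#'
#' @param field numeric matrix.
#' @param mask a `region_mask` from [rasterize()], or a single logical matrix.
#' @param valid optional logical matrix of usable pixels.
#' @return data.frame with columns `region`, `mean`, `n_pixels`, `empty`.
#' @export
region_mean <- function(field, mask, valid = NULL) {
  masks <- if (inherits(mask, "region_mask")) mask$masks else list(region = mask)
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!all(dim(m) == dim(field))) stop("mask/field shape mismatch")
    if (!is.null(valid)) {
      if (!all(dim(valid) == dim(field))) stop("valid/field shape mismatch")
      m <- m & valid
    }
    n <- sum(m)
    data.frame(region = nm,
               mean = if (n > 0L) mean(field[m]) else NaN,
               n_pixels = n, empty = n == 0L)
  })
  do.call(rbind, out)
}
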