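#' Active-zone field
#'
#' One electron-microscopy section profile: the active-zone (AZ) membrane
#' modelled as a straight segment in the section plane, plus the centres
#' and radii of the surrounding synaptic vesicles, all in nm.
#'
#' @param az_id Identifier.
#' @param p1,p2 Segment endpoints, numeric length-2 `(x, y)` in nm.
#' @param vesicles Matrix or data frame with columns `x`, `y`, `radius`
#'   (nm); may have zero rows.
#' @param pixel_size_nm Rasterization scale for the distance-map path.
#' @return An object of class `psq_az_field`.
#' @export
az_field <- function(az_id, p1, p2, vesicles, pixel_size_nm = 1) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (sqrt(sum((p2 - p1)^2)) <= 0) stop("degenerate AZ segment")
  ves <- as.matrix(vesicles)
  if (nrow(ves) > 0) {
    stopifnot(ncol(ves) >= 3)
    colnames(ves)[1:3] <- c("x", "y", "radius")
    if (any(ves[, "radius"] <= 0)) stop("vesicle radii must be > 0")
  }
  structure(list(az_id = az_id, p1 = p1, p2 = p2, vesicles = ves,
                 pixel_size_nm = pixel_size_nm), class = "psq_az_field")
}

#' Active-zone length
#' @param field A `psq_az_field`.
#' @return Euclidean length of the AZ segment in nm.
#' @export
az_length <- function(field) {
  sqrt(sum((field$p2 - field$p1)^2))
}

## exact point-to-segment (capsule) distance
point_segment_distance <- function(pts, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d^2)
  rel <- sweep(pts, 2, p1)
  tproj <- pmin(pmax((rel %*% d) / len2, 0), 1)
  foot <- cbind(p1[1] + tproj * d[1], p1[2] + tproj * d[2])
  sqrt(rowSums((pts - foot)^2))
}

## Euclidean distance map of the rasterized segment, sampled at the
## vesicle centres (nearest pixel)
raster_center_distance <- function(field) {
  px <- field$pixel_size_nm
  ves <- field$vesicles
  ## the distance transform only needs to cover the segment and the
  ## vesicle centres at which it is sampled
  pad <- 2 * px
  x0 <- min(field$p1[1], field$p2[1], ves[, "x"]) - pad
  y0 <- min(field$p1[2], field$p2[2], ves[, "y"]) - pad
  x1 <- max(field$p1[1], field$p2[1], ves[, "x"]) + pad
  y1 <- max(field$p1[2], field$p2[2], ves[, "y"]) + pad
  nx <- ceiling((x1 - x0) / px) + 1L
  ny <- ceiling((y1 - y0) / px) + 1L
  img <- matrix(1, nx, ny)
  ## stamp the segment densely (sub-pixel steps so no gaps appear)
  seg_len <- az_length(field)
  tseq <- seq(0, 1, length.out = max(2L, ceiling(seg_len / (0.25 * px))))
  sx <- round((field$p1[1] + tseq * (field$p2[1] - field$p1[1]) - x0) / px) + 1L
  sy <- round((field$p1[2] + tseq * (field$p2[2] - field$p1[2]) - y0) / px) + 1L
  img[cbind(sx, sy)] <- 0
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(img)))
  ix <- round((ves[, "x"] - x0) / px) + 1L
  iy <- round((ves[, "y"] - y0) / px) + 1L
  dm[cbind(ix, iy)] * px
}

#' Vesicle-to-membrane distances
#'
#' Edge distance of each vesicle to the AZ membrane: the distance from the
#' vesicle centre to the AZ segment minus the vesicle radius, floored at
#' zero.  The `exact` method uses point-to-segment geometry; the `raster`
#' method mirrors a distance-map image workflow (32-bit Euclidean distance
#' transform of the rasterized segment, sampled at the vesicle centre) and
#' serves as a cross-check.  Only vesicles with edge distance below 200 nm
#' are returned.
#'
#' @param field A `psq_az_field`.
#' @param method `"exact"` (default) or `"raster"`.
#' @return Data frame `(vesicle, distance_nm)`; `vesicle` indexes rows of
#'   `field$vesicles`.
#' @export
vesicle_distances <- function(field, method = c("exact", "raster")) {
  method <- match.arg(method)
  ves <- field$vesicles
  if (nrow(ves) == 0)
    return(data.frame(vesicle = integer(0), distance_nm = numeric(0)))
  cd <- if (method == "exact")
    point_segment_distance(ves[, c("x", "y"), drop = FALSE],
                           field$p1, field$p2)
  else raster_center_distance(field)
  edge <- pmax(cd - ves[, "radius"], 0)
  keep <- edge < 200
  data.frame(vesicle = which(keep), distance_nm = unname(edge[keep]))
}

#' Binned vesicle distance histogram
#'
#' Half-open 5 nm bins `[0,5), [5,10), ..., [195,200)`; vesicles with edge
#' distance below 5 nm fall in the first bin and are counted as docked.
#'
#' @param distances Numeric edge distances (nm), all >= 0, or the data
#'   frame returned by [vesicle_distances()].
#' @param az_id Optional identifier carried through.
#' @return A list of class `psq_distance_histogram`: `bin_edges`,
#'   `counts`, `docked_count`, `az_id`.
#' @export
distance_histogram <- function(distances, az_id = NA) {
  if (is.data.frame(distances)) distances <- distances$distance_nm
  if (any(distances < 0)) stop("distances must be >= 0")
  edges <- seq(0, 200, by = 5)
  counts <- as.integer(table(cut(distances[distances < 200], breaks = edges,
                                 right = FALSE, include.lowest = FALSE,
                                 labels = FALSE)) [as.character(1:40)])
  counts[is.na(counts)] <- 0L
  structure(list(bin_edges = edges, counts = counts,
                 docked_count = counts[1L], az_id = az_id),
            class = "psq_distance_histogram")
}

#' Docked-vesicle summary over active zones
#'
#' Mean and standard error of the per-AZ docked-vesicle count (edge
#' distance < 5 nm).
#'
#' @param fields List of `psq_az_field` objects.
#' @param method Distance method passed to [vesicle_distances()].
#' @return `list(mean, sem, n, counts)`.
#' @export
docked_summary <- function(fields, method = "exact") {
  stopifnot(length(fields) >= 1)
  counts <- vapply(fields, function(f) {
    d <- vesicle_distances(f, method)
    sum(d$distance_nm < 5)
  }, numeric(1))
  n <- length(counts)
  sem <- if (n > 1) stats::sd(counts) / sqrt(n) else 0
  list(mean = mean(counts), sem = sem, n = n, counts = counts)
}

#' Write / read active-zone fields as TSV
#'
#' Plain-text interchange: one `az` record per field
#' (`az_id, x1, y1, x2, y2`) followed by its vesicle records
#' (`az_id, x, y, radius`), distinguished by a leading `record` column.
#'
#' @param fields List of `psq_az_field` objects.
#' @param path File path.
#' @return `write_em_fields` returns `path` invisibly; `read_em_fields`
#'   returns a list of `psq_az_field`.
#' @export
write_em_fields <- function(fields, path) {
  rows <- lapply(fields, function(f) {
    az <- data.frame(record = "az", az_id = f$az_id,
                     a = f$p1[1], b = f$p1[2], c = f$p2[1], d = f$p2[2])
    if (nrow(f$vesicles) > 0) {
      vs <- data.frame(record = "vesicle", az_id = f$az_id,
                       a = f$vesicles[, "x"], b = f$vesicles[, "y"],
                       c = f$vesicles[, "radius"], d = NA)
      rbind(az, vs)
    } else az
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_em_fields
#' @export
read_em_fields <- function(path) {
  df <- utils::read.delim(path)
  lapply(split(df, df$az_id), function(d) {
    az <- d[d$record == "az", ]
    vs <- d[d$record == "vesicle", ]
    ves <- if (nrow(vs) > 0)
      cbind(x = vs$a, y = vs$b, radius = vs$c)
    else matrix(numeric(0), 0, 3,
                dimnames = list(NULL, c("x", "y", "radius")))
    az_field(az$az_id[1], c(az$a, az$b), c(az$c, az$d), ves)
  })
}
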