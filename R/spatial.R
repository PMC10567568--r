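#' Equal-area grid specification
#'
#' Defines a world grid of square cells in the Behrmann cylindrical
#' equal-area projection (standard parallel 30 degrees), so every cell has
#' the same area on the sphere. Presets cover the two cell sizes used for
#' richness maps (865 km^2) and driver maps (7,775 km^2); any positive area
#' is accepted.
#'
#' @param cell_area_km2 cell area in square kilometres.
#' @return list of class `"grid_spec"`: cell size (km), numbers of columns
#'   and rows, and projection constants.
#' @export
grid_spec <- function(cell_area_km2 = 865) {
  stopifnot(cell_area_km2 > 0)
  R <- 6371.0072                       # authalic Earth radius, km
  side <- sqrt(cell_area_km2)
  cosphi1 <- cos(30 * pi / 180)        # Behrmann standard parallel
  width <- 2 * pi * R * cosphi1        # projected world width, km
  height <- 2 * R / cosphi1            # projected world height, km
  structure(list(cell_area_km2 = cell_area_km2, side_km = side,
                 ncol = ceiling(width / side), nrow = ceiling(height / side),
                 R = R, cosphi1 = cosphi1, width = width, height = height),
            class = "grid_spec")
}

# lon/lat (degrees) -> Behrmann x/y (km)
.behrmann <- function(lon, lat, g) {
  list(x = g$R * (lon * pi / 180) * g$cosphi1,
       y = g$R * sin(lat * pi / 180) / g$cosphi1)
}

# projected x/y -> "col_row" cell id
.cell_of <- function(x, y, g) {
  col <- pmin(pmax(floor((x + g$width / 2) / g$side_km), 0), g$ncol - 1L)
  row <- pmin(pmax(floor((y + g$height / 2) / g$side_km), 0), g$nrow - 1L)
  paste0(col, "_", row)
}

#' Build species-by-cell incidence
#'
#' Two input modes. Pair mode takes a data frame of `species_id`, `cell_id`
#' pairs and deduplicates them (a species contributes at most once per
#' cell). Polygon mode takes range polygons as a GeoJSON file or parsed
#' GeoJSON list (FeatureCollection of Polygon/MultiPolygon features with a
#' `species_id` property) and rasterizes each range onto the grid: a cell
#' is occupied if its center falls inside the polygon or if any polygon
#' vertex or densified boundary point falls in the cell. Features with
#' `presence`/`origin` attributes are filtered to extant native ranges when
#' those attributes are present; invalid features are skipped with a
#' warning and counted.
#'
#' @param x pair data frame, GeoJSON path, or parsed GeoJSON list.
#' @param grid a [grid_spec()]; only used in polygon mode.
#' @return data frame of class `"grid_incidence"` with unique
#'   `species_id`, `cell_id` pairs; attribute `n_skipped` in polygon mode.
#' @export
build_incidence <- function(x, grid = grid_spec()) {
  if (is.data.frame(x)) {
    stopifnot(all(c("species_id", "cell_id") %in% names(x)))
    inc <- unique(x[, c("species_id", "cell_id")])
    rownames(inc) <- NULL
    class(inc) <- c("grid_incidence", "data.frame")
    return(inc)
  }
  gj <- if (is.character(x)) jsonlite::read_json(x) else x
  stopifnot(identical(gj$type, "FeatureCollection"))
  pairs <- list(); skipped <- 0L
  for (f in gj$features) {
    res <- tryCatch(.rasterize_feature(f, grid), error = function(e) e)
    if (inherits(res, "error") || is.null(res)) {
      if (inherits(res, "error"))
        warning("skipping invalid feature: ", conditionMessage(res),
                call. = FALSE)
      skipped <- skipped + inherits(res, "error")
      next
    }
    pairs[[length(pairs) + 1L]] <- res
  }
  inc <- if (length(pairs)) unique(do.call(rbind, pairs)) else
    data.frame(species_id = character(), cell_id = character())
  rownames(inc) <- NULL
  class(inc) <- c("grid_incidence", "data.frame")
  attr(inc, "n_skipped") <- skipped
  inc
}

.rasterize_feature <- function(f, g) {
  props <- f$properties
  sid <- props$species_id
  if (is.null(sid)) stop("feature without species_id property")
  if (!is.null(props$presence) && !props$presence %in% c(1, 2)) return(NULL)
  if (!is.null(props$origin) && !props$origin %in% c(1, 2)) return(NULL)
  geom <- f$geometry
  rings <- switch(geom$type,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    stop("unsupported geometry type ", geom$type))
  cells <- character()
  for (poly in rings) {
    outer <- do.call(rbind, lapply(poly[[1]], function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    if (nrow(outer) < 4) stop("degenerate ring")
    p <- .behrmann(outer[, 1], outer[, 2], g)
    # densify edges so thin polygons still touch every crossed cell
    dx <- diff(p$x); dy <- diff(p$y)
    nseg <- pmax(1L, ceiling(sqrt(dx^2 + dy^2) / (g$side_km / 2)))
    xs <- unlist(lapply(seq_along(dx), function(i)
      p$x[i] + dx[i] * seq(0, 1, length.out = nseg[i] + 1L)))
    ys <- unlist(lapply(seq_along(dy), function(i)
      p$y[i] + dy[i] * seq(0, 1, length.out = nseg[i] + 1L)))
    cells <- c(cells, .cell_of(xs, ys, g))
    # cells whose center lies inside the outer ring
    cand <- unique(.cells_in_bbox(range(p$x), range(p$y), g))
    ctr <- .cell_centers(cand, g)
    inside <- mgcv::in.out(cbind(p$x, p$y), cbind(ctr$x, ctr$y))
    cells <- c(cells, cand[inside])
  }
  data.frame(species_id = as.character(sid), cell_id = unique(cells),
             stringsAsFactors = FALSE)
}

.cells_in_bbox <- function(xr, yr, g) {
  c0 <- floor((xr[1] + g$width / 2) / g$side_km)
  c1 <- floor((xr[2] + g$width / 2) / g$side_km)
  r0 <- floor((yr[1] + g$height / 2) / g$side_km)
  r1 <- floor((yr[2] + g$height / 2) / g$side_km)
  grid <- expand.grid(col = c0:c1, row = r0:r1)
  paste0(pmin(pmax(grid$col, 0), g$ncol - 1L), "_",
         pmin(pmax(grid$row, 0), g$nrow - 1L))
}

.cell_centers <- function(cell_id, g) {
  cr <- do.call(rbind, strsplit(cell_id, "_", fixed = TRUE))
  col <- as.numeric(cr[, 1]); row <- as.numeric(cr[, 2])
  list(x = (col + 0.5) * g$side_km - g$width / 2,
       y = (row + 0.5) * g$side_km - g$height / 2)
}

#' Per-cell species richness
#'
#' @param incidence a [build_incidence()] result.
#' @return data frame `cell_id`, `richness` (occupied cells only).
#' @export
cell_richness <- function(incidence) {
  tab <- table(incidence$cell_id)
  data.frame(cell_id = names(tab), richness = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Quantile classes of cell richness
#'
#' Assigns each occupied cell a class 1..k from the k-quantiles of the
#' occupied-cell richness distribution: a cell's class is determined by the
#' position of its richness in the sorted richness vector, with tied
#' richness values sharing the lowest class any of them reaches. With n
#' cells of distinct richness, class c covers sorted ranks
#' (n(c-1)/k, nc/k]. When there are fewer distinct richness values than
#' classes, some classes are empty (merged); the number actually used is
#' reported as an attribute.
#'
#' @param richness data frame from [cell_richness()] (or an incidence to
#'   tabulate first).
#' @param k number of quantile classes, default 10.
#' @return the richness data frame with a `class` column; attribute
#'   `n_classes_used`.
#' @export
richness_quantiles <- function(richness, k = 10) {
  if (!"richness" %in% names(richness)) richness <- cell_richness(richness)
  stopifnot(k >= 1, nrow(richness) >= 1)
  r <- richness$richness
  n <- length(r)
  rank_min <- rank(r, ties.method = "min") - 1L             # 0-based
  cls <- as.integer(floor(rank_min * k / n) + 1L)
  richness$class <- cls
  used <- length(unique(cls))
  if (used < k)
    message("richness has fewer distinct levels than classes: ",
            used, " of ", k, " classes used")
  structure(richness, n_classes_used = used)
}

#' Dominant deterioration driver per grid cell
#'
#' For one interval, tallies per cell the species that genuinely
#' deteriorated, by driver group, using the incidence to place species in
#' cells. The most frequent driver wins the cell. A two-way tie keeps both
#' labels (joined with `"+"`) and sets `tie_flag` (maps would show an
#' intermediate colour); a cell whose dominant driver is undetermined or
#' numerous — or where three or more drivers tie — sets `star_flag`.
#'
#' @param incidence a [build_incidence()] result.
#' @param changes change-record data frame from [derive_changes()].
#' @param epoch_from start year of the interval.
#' @return data frame `cell_id`, `n_deteriorated`, `driver`, `tie_flag`,
#'   `star_flag` (cells with at least one deteriorated species only).
#' @export
dominant_driver <- function(incidence, changes, epoch_from) {
  det <- changes[isTRUE_v(changes$genuine) &
                 changes$direction == "deterioration" &
                 changes$epoch_from == epoch_from, , drop = FALSE]
  drv <- ifelse(is.na(det$driver_group), "undetermined", det$driver_group)
  di <- match(incidence$species_id, det$species_id)
  hit <- !is.na(di)
  if (!any(hit))
    return(data.frame(cell_id = character(), n_deteriorated = integer(),
                      driver = character(), tie_flag = logical(),
                      star_flag = logical(), stringsAsFactors = FALSE))
  cell <- incidence$cell_id[hit]
  cdrv <- drv[di[hit]]
  out <- lapply(split(cdrv, cell), function(v) {
    tab <- table(v)
    top <- sort(names(tab)[tab == max(tab)])     # deterministic order
    tie <- length(top) == 2L
    star <- length(top) >= 3L ||
      any(top %in% c("undetermined", "numerous"))
    data.frame(n_deteriorated = length(v),
               driver = paste(top, collapse = "+"),
               tie_flag = tie, star_flag = star, stringsAsFactors = FALSE)
  })
  res <- cbind(data.frame(cell_id = names(out), stringsAsFactors = FALSE),
               do.call(rbind, out))
  rownames(res) <- NULL
  res
}
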