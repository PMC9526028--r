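#' Land-cover label raster
#'
#' Minimal in-memory raster: an integer class-label grid with a square pixel
#' size and an origin (coordinates of the lower-left corner). Row 1 of the
#' grid is the top (northern) row, matching ESRI ASCII grid order.
#'
#' @param grid integer matrix of class labels.
#' @param cellsize pixel edge length in meters (> 0).
#' @param xll,yll coordinates of the lower-left corner.
#' @param legend named integer vector mapping class names to labels.
#' @return object of class `land_raster`.
#' @export
land_raster <- function(grid, cellsize, xll = 0, yll = 0, legend = NULL) {
  grid <- as.matrix(grid)
  if (cellsize <= 0) stop("cellsize must be > 0")
  labs <- sort(unique(as.vector(grid)))
  if (is.null(legend)) {
    legend <- labs; names(legend) <- paste0("class_", labs)
  }
  if (!all(labs %in% legend)) stop("grid labels missing from legend")
  structure(list(grid = grid, cellsize = cellsize, xll = xll, yll = yll,
                 legend = legend), class = "land_raster")
}

#' Read / write an ESRI ASCII grid
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' grid, top row first.
#'
#' @param path file path.
#' @param legend optional legend passed to [land_raster()].
#' @return a `land_raster`.
#' @export
read_ascii_grid <- function(path, legend = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  g <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  land_raster(g, cellsize = hdr$cellsize, xll = hdr$xllcorner,
              yll = hdr$yllcorner, legend = legend)
}

#' @rdname read_ascii_grid
#' @param raster a `land_raster`.
#' @export
write_ascii_grid <- function(raster, path) {
  con <- file(path, "w"); on.exit(close(con))
  g <- raster$grid
  writeLines(c(paste("ncols", ncol(g)), paste("nrows", nrow(g)),
               paste("xllcorner", raster$xll), paste("yllcorner", raster$yll),
               paste("cellsize", raster$cellsize), "NODATA_value -9999"), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregated land-cover proportions within a circular buffer
#'
#' Counts pixels whose centers lie within `radius_m` of `point`, maps raw
#' classes to aggregated classes, removes water from numerator and
#' denominator, and returns proportions over the non-water classes (which
#' sum to 1). A buffer not fully contained in the raster extent returns
#' `NULL` with a warning, mirroring the study's exclusion of such sites.
#'
#' @param raster a `land_raster`.
#' @param point numeric `c(x, y)` in the raster's coordinate system.
#' @param radius_m buffer radius in meters.
#' @param aggregation named list mapping aggregated class names
#'   (`impervious`, `open_green`, `closed_green`, `water`, `other`) to
#'   vectors of raw labels. Unmapped labels count as `other`.
#' @return named numeric vector of proportions over
#'   `impervious`/`open_green`/`closed_green`/`other`, or `NULL` when the
#'   buffer is not contained.
#' @export
buffer_proportions <- function(raster, point, radius_m, aggregation = NULL) {
  g <- raster$grid; cs <- raster$cellsize
  nr <- nrow(g); nc <- ncol(g)
  xmax <- raster$xll + nc * cs; ymax <- raster$yll + nr * cs
  if (point[1] - radius_m < raster$xll || point[1] + radius_m > xmax ||
      point[2] - radius_m < raster$yll || point[2] + radius_m > ymax) {
    warning("buffer not fully contained in raster extent; site skipped")
    return(NULL)
  }
  ## pixel centers: column j -> x = xll + (j - 0.5) cs; row i (from top) ->
  ## y = ymax - (i - 0.5) cs
  jr <- range(floor((point[1] - radius_m - raster$xll) / cs) + 1,
              ceiling((point[1] + radius_m - raster$xll) / cs))
  ir <- range(floor((ymax - point[2] - radius_m) / cs) + 1,
              ceiling((ymax - point[2] + radius_m) / cs))
  jr <- pmin(pmax(jr, 1), nc); ir <- pmin(pmax(ir, 1), nr)
  js <- jr[1]:jr[2]; is <- ir[1]:ir[2]
  xc <- raster$xll + (js - 0.5) * cs
  yc <- ymax - (is - 0.5) * cs
  inside <- outer(yc - point[2], xc - point[1],
                  function(dy, dx) dx^2 + dy^2 <= radius_m^2)
  labs <- g[is, js, drop = FALSE][inside]
  if (!length(labs)) stop("radius smaller than pixel size: no pixel centers in buffer")
  agg_of <- rep("other", max(raster$legend) + 1)
  if (is.null(aggregation))
    aggregation <- stats::setNames(as.list(raster$legend), names(raster$legend))
  for (cls in names(aggregation))
    agg_of[unlist(aggregation[[cls]]) + 1] <- cls
  a <- agg_of[labs + 1]
  a <- a[a != "water"]
  if (!length(a)) stop("buffer contains only water pixels")
  classes <- c("impervious", "open_green", "closed_green", "other")
  counts <- table(factor(a, levels = classes))
  stats::setNames(as.numeric(counts) / length(a), classes)
}

#' Attach buffer land-cover covariates to a site table
#'
#' Computes [buffer_proportions()] at each radius for every site with
#' coordinates and adds `impervious_<r>`, `open_green_<r>`,
#' `closed_green_<r>` columns. Sites whose buffer is not fully contained at
#' a radius are dropped (all radii must succeed), with their ids recorded.
#'
#' @param st a [site_table()]-like data.frame with `site_id`, `x`, `y`.
#' @param raster a `land_raster`.
#' @param radii buffer radii in meters (default `c(250, 500)`).
#' @param aggregation see [buffer_proportions()].
#' @return a [site_table()] restricted to contained sites, with attribute
#'   `dropped_sites`.
#' @export
attach_covariates <- function(st, raster, radii = c(250, 500), aggregation = NULL) {
  df <- if (inherits(st, "site_table")) st$sites else as.data.frame(st)
  if (!all(c("x", "y") %in% names(df))) {
    stop("missing coordinates for sites: ",
         paste(df$site_id, collapse = ", "))
  }
  if (anyNA(df$x) | anyNA(df$y))
    stop("missing coordinates for sites: ",
         paste(df$site_id[is.na(df$x) | is.na(df$y)], collapse = ", "))
  keep <- rep(TRUE, nrow(df))
  for (r in radii)
    for (cls in c("impervious", "open_green", "closed_green"))
      df[[paste0(cls, "_", r)]] <- NA_real_
  for (i in seq_len(nrow(df))) {
    for (r in radii) {
      pr <- suppressWarnings(
        buffer_proportions(raster, c(df$x[i], df$y[i]), r, aggregation))
      if (is.null(pr)) { keep[i] <- FALSE; break }
      for (cls in c("impervious", "open_green", "closed_green"))
        df[[paste0(cls, "_", r)]][i] <- pr[[cls]]
    }
  }
  out <- site_table(df[keep, , drop = FALSE], scales = radii)
  attr(out, "dropped_sites") <- df$site_id[!keep]
  out
}
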