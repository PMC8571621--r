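#' Construct a single-band raster grid
#'
#' The in-memory raster container used throughout the package: a row-major
#' numeric matrix (row 1 = northernmost row) with square cells and `NA`
#' marking NoData. The `nodata` sentinel is only materialized on write.
#'
#' @param values Numeric matrix; `NA` cells are NoData.
#' @param cellsize Side length of a (square) cell in map units. Must be > 0.
#' @param xll,yll Map coordinates of the lower-left corner of the grid.
#' @param nodata Sentinel written to file for `NA` cells. Must not collide
#'   with any valid value.
#' @param crs Opaque coordinate-reference-system tag (not interpreted).
#' @return An object of class `lf_grid`.
#' @examples
#' g <- lf_grid(matrix(1:9, 3, 3), cellsize = 1000)
#' @export
lf_grid <- function(values, cellsize = 1, xll = 0, yll = 0,
                    nodata = -9999, crs = NA_character_) {
  if (!is.matrix(values)) {
    lf_abort("`values` must be a matrix.", "usage")
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    lf_abort("`cellsize` must be a single positive number.", "usage")
  }
  if (any(values == nodata, na.rm = TRUE)) {
    lf_abort("NoData sentinel collides with a data value.", "usage")
  }
  storage.mode(values) <- if (is.integer(values)) "integer" else "double"
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = nodata, crs = crs),
    class = "lf_grid"
  )
}

#' @export
print.lf_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<lf_grid> %d x %d, cellsize %g, %d valid cells",
              nrow(x$values), ncol(x$values), x$cellsize, length(v)))
  if (length(v) > 0) {
    cat(sprintf(", range [%g, %g]", min(v), max(v)))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.lf_grid <- function(x) dim(x$values)

is_categorical <- function(values) {
  all(values[!is.na(values)] == round(values[!is.na(values)]))
}

grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cellsize - b$cellsize) <= tol * max(a$cellsize, 1) &&
    abs(a$xll - b$xll) <= tol * max(a$cellsize, 1) &&
    abs(a$yll - b$yll) <= tol * max(a$cellsize, 1)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner` or
#' `xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, `nodata_value`)
#' followed by whitespace-separated values, northernmost row first.
#'
#' @param path Path to a `.asc` file.
#' @param categorical If `TRUE`, require all values to be integral and
#'   return an integer grid; non-integral values raise a type error.
#' @return An `lf_grid`.
#' @export
read_grid <- function(path, categorical = FALSE) {
  if (!file.exists(path)) {
    lf_abort(sprintf("Cannot read raster: %s", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) == 2L && grepl("^[a-zA-Z_]", toks[1])) {
      hdr[[tolower(toks[1])]] <- as.numeric(toks[2])
      body_start <- i + 1L
    } else {
      break
    }
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr))) {
    lf_abort(sprintf("Malformed ASCII grid header in %s.", path), "io")
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nc * nr) {
    lf_abort(sprintf("Expected %d values, found %d in %s.",
                     nc * nr, length(vals), path), "io")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (categorical) {
    if (!is_categorical(m)) {
      lf_abort("Categorical raster contains non-integral values.", "type")
    }
    storage.mode(m) <- "integer"
  }
  lf_grid(m, cellsize = cs, xll = xll, yll = yll, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param grid An `lf_grid` (or `lf_surface`, whose grid is written).
#' @param path Output path.
#' @param digits Significant digits for continuous values (categorical
#'   integer grids are written exactly).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, digits = 10) {
  if (inherits(grid, "lf_surface")) grid <- grid$grid
  stopifnot(inherits(grid, "lf_grid"))
  m <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", as.numeric(grid$nodata))
  )
  fmt <- function(row) {
    out <- if (is.integer(m)) format(row, trim = TRUE, scientific = FALSE)
           else format(row, trim = TRUE, digits = digits)
    out[is.na(row)] <- format(grid$nodata, trim = TRUE, scientific = FALSE)
    paste(out, collapse = " ")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    lf_abort(sprintf("Cannot open %s for writing.", path), "io")
  })
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(vapply(seq_len(nrow(m)), function(i) fmt(m[i, ]), character(1)),
             con)
  invisible(path)
}

#' Pair first- and second-grade rasters under a hierarchy
#'
#' Binds the coarse (G1) and fine (G2) grids together, enforcing the
#' vertical-consistency contract: on every valid cell the G1 code must be
#' the hierarchy parent of the G2 code. Cells that are NoData in either
#' grid are NoData in the pair.
#'
#' @param g2 `lf_grid` of child codes.
#' @param g1 `lf_grid` of parent codes, or `NULL` to derive it from `g2`.
#' @param hierarchy An `lf_hierarchy`.
#' @param on_mismatch What to do with a cell whose supplied G1 code is not
#'   `parent_of(g2)`: `"error"` (default when `g1` is supplied) stops and
#'   names the first offending cell; `"mask"` drops such cells from the
#'   valid mask; `"derive_g1"` ignores the supplied `g1` entirely and
#'   rebuilds it from `g2`.
#' @return An object of class `lf_pair`: list with `g1`, `g2`
#'   (both `lf_grid`), `hierarchy`, `valid` (logical matrix), and
#'   `observed_n` (named integer vector: subclasses of each parent present
#'   anywhere in the valid data — the `dataset` denominator for fusion
#'   weights).
#' @examples
#' h <- infer_hierarchy(c(11, 12, 21))
#' g2 <- lf_grid(matrix(c(11L, 12L, 21L, 21L), 2, 2))
#' p <- pair_rasters(g2, hierarchy = h)
#' p$g1$values
#' @export
pair_rasters <- function(g2, g1 = NULL, hierarchy,
                         on_mismatch = if (is.null(g1)) "derive_g1" else "error") {
  stopifnot(inherits(g2, "lf_grid"), inherits(hierarchy, "lf_hierarchy"))
  on_mismatch <- match.arg(on_mismatch, c("error", "mask", "derive_g1"))
  if (!is_categorical(g2$values)) {
    lf_abort("G2 grid is not categorical.", "type")
  }
  g2v <- g2$values
  storage.mode(g2v) <- "integer"
  valid <- !is.na(g2v)
  known <- matrix(TRUE, nrow(g2v), ncol(g2v))
  known[valid] <- as.character(g2v[valid]) %in% names(hierarchy$child_to_parent)
  if (any(valid & !known)) {
    bad <- unique(g2v[valid & !known])
    lf_abort(sprintf("G2 contains code(s) not in the hierarchy: %s.",
                     paste(bad, collapse = ", ")), "lookup")
  }
  derived <- matrix(NA_integer_, nrow(g2v), ncol(g2v))
  derived[valid] <- parent_of(hierarchy, g2v[valid])

  if (is.null(g1) || on_mismatch == "derive_g1") {
    g1 <- lf_grid(derived, cellsize = g2$cellsize, xll = g2$xll,
                  yll = g2$yll, nodata = g2$nodata, crs = g2$crs)
  } else {
    if (!grids_aligned(g1, g2)) {
      lf_abort("G1 and G2 grids differ in shape or transform.",
               "grid_alignment")
    }
    if (!is_categorical(g1$values)) {
      lf_abort("G1 grid is not categorical.", "type")
    }
    g1v <- g1$values
    storage.mode(g1v) <- "integer"
    valid <- valid & !is.na(g1v)
    mismatch <- valid & (g1v != derived)
    if (any(mismatch)) {
      if (on_mismatch == "error") {
        idx <- which(mismatch, arr.ind = TRUE)[1, ]
        lf_abort(
          sprintf(paste0("Vertical inconsistency at cell (row %d, col %d): ",
                         "G1 = %d but parent_of(G2 = %d) = %d."),
                  idx[1], idx[2], g1v[idx[1], idx[2]],
                  g2v[idx[1], idx[2]], derived[idx[1], idx[2]]),
          "consistency"
        )
      }
      valid <- valid & !mismatch
    }
    g1 <- lf_grid(g1v, cellsize = g1$cellsize, xll = g1$xll, yll = g1$yll,
                  nodata = g1$nodata, crs = g1$crs)
  }
  g1$values[!valid] <- NA
  g2$values[!valid] <- NA
  observed <- tapply(g2$values[valid], factor(
    parent_of(hierarchy, g2$values[valid]), levels = hierarchy$parents
  ), function(v) length(unique(v)))
  observed[is.na(observed)] <- 0L
  structure(
    list(g1 = g1, g2 = g2, hierarchy = hierarchy, valid = valid,
         observed_n = setNames(as.integer(observed),
                               as.character(hierarchy$parents))),
    class = "lf_pair"
  )
}

#' @export
print.lf_pair <- function(x, ...) {
  cat(sprintf("<lf_pair> %d x %d, %d valid cells, %d parent / %d child classes\n",
              nrow(x$g2$values), ncol(x$g2$values), sum(x$valid),
              length(unique(x$g1$values[x$valid])),
              length(unique(x$g2$values[x$valid]))))
  invisible(x)
}
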