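#' Tabulate the two-grade class composition of a set of cells
#'
#' Counts parent (G1) and child (G2) classes over the valid cells of a
#' window and forms the probabilities that drive the entropy machinery:
#' the parent proportions \eqn{p(x_i)} and the within-parent subclass
#' proportions \eqn{p(y_{ij} | x_i)}. NoData cells never enter a
#' denominator. An empty valid set is a flagged state
#' (`total_valid == 0`), not an error.
#'
#' @param pair An `lf_pair`.
#' @param cells Cells making up the window: a data frame with columns
#'   `row` and `col`, or a two-column matrix. Defaults to every cell of
#'   the raster (landscape-wide composition).
#' @return An object of class `lf_composition`: list with `total_valid`
#'   (count), `parent` (tibble: `parent`, `count`, `p`), `child` (tibble:
#'   `child`, `parent`, `count`, `p_cond` = \eqn{p(y_{ij}|x_i)}),
#'   `hierarchy`, and `observed_n` (dataset-wide subclass counts carried
#'   over from the pair).
#' @examples
#' h <- infer_hierarchy(c(11, 12, 21))
#' g2 <- lf_grid(matrix(c(rep(11L, 4), rep(12L, 4), rep(21L, 8)), 4, 4))
#' comp <- window_composition(pair_rasters(g2, hierarchy = h))
#' comp$parent
#' @export
window_composition <- function(pair, cells = NULL) {
  stopifnot(inherits(pair, "lf_pair"))
  v <- pair$g2$values
  if (is.null(cells)) {
    codes <- v[pair$valid]
  } else {
    if (is.data.frame(cells)) cells <- cbind(cells$row, cells$col)
    if (!is.matrix(cells) || ncol(cells) != 2L) {
      lf_abort("`cells` must be a data frame with row/col or a 2-column matrix.",
               "usage")
    }
    if (any(cells[, 1] < 1 | cells[, 1] > nrow(v) |
            cells[, 2] < 1 | cells[, 2] > ncol(v))) {
      lf_abort("Window cells out of raster bounds.", "usage")
    }
    codes <- v[cells]
    codes <- codes[!is.na(codes)]
  }
  new_composition(codes, pair$hierarchy, pair$observed_n)
}

# Core constructor shared by window_composition() and the window engine.
# `codes` are valid G2 cell codes.
new_composition <- function(codes, hierarchy, observed_n = NULL) {
  n <- length(codes)
  if (n == 0L) {
    return(structure(
      list(total_valid = 0L,
           parent = tibble(parent = integer(), count = integer(),
                           p = numeric()),
           child = tibble(child = integer(), parent = integer(),
                          count = integer(), p_cond = numeric()),
           hierarchy = hierarchy, observed_n = observed_n),
      class = "lf_composition"
    ))
  }
  ctab <- table(codes)
  child <- as.integer(names(ctab))
  ccount <- as.integer(ctab)
  cparent <- parent_of(hierarchy, child)
  ptab <- tapply(ccount, cparent, sum)
  pcodes <- as.integer(names(ptab))
  pcount <- as.integer(ptab)
  p_cond <- ccount / pcount[match(cparent, pcodes)]
  structure(
    list(
      total_valid = n,
      parent = tibble(parent = pcodes, count = pcount, p = pcount / n),
      child = tibble(child = child, parent = cparent, count = ccount,
                     p_cond = p_cond),
      hierarchy = hierarchy, observed_n = observed_n
    ),
    class = "lf_composition"
  )
}

#' @export
print.lf_composition <- function(x, ...) {
  cat(sprintf("<lf_composition> %d valid cells, %d parents, %d children\n",
              x$total_valid, nrow(x$parent), nrow(x$child)))
  invisible(x)
}

#' Tidy a window composition into one row per child class
#'
#' @param x An `lf_composition`.
#' @param ... Unused.
#' @return A tibble with columns `child`, `parent`, `count`, `p_cond`,
#'   `p_parent` (the parent's share of the window) and `p_child`
#'   (= `p_parent * p_cond`, the child's share of the window).
#' @exportS3Method generics::tidy
tidy.lf_composition <- function(x, ...) {
  out <- dplyr::left_join(x$child,
                          dplyr::select(x$parent, "parent", p_parent = "p"),
                          by = "parent")
  dplyr::mutate(out, p_child = .data$p_parent * .data$p_cond)
}
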