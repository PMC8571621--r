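#' Per-class Shannon-diversity components of a window
#'
#' SHDI decomposes over classes as \eqn{-p_k \ln p_k}; the window's SHDI is
#' the sum of the components. The fusion formula multiplies the
#' parent-grade components by `(1 + w_i)`.
#'
#' @param composition An `lf_composition` with `total_valid > 0`.
#' @param grade Which grade of the classification to measure: `"parent"`
#'   (G1, default) or `"child"` (G2).
#' @return A tibble of class `lf_components` with columns `class` and `li`
#'   and attributes `metric` and `grade`; `sum(li)` is the metric value.
#' @export
shdi_components <- function(composition, grade = c("parent", "child")) {
  grade <- match.arg(grade)
  check_nonempty(composition)
  p <- grade_proportions(composition, grade)
  new_components(p$class, -p$p * log(p$p), "shdi", grade)
}

#' Per-class patch-richness components of a window
#'
#' Each class present contributes 1; the total is the number of classes
#' present (PR).
#'
#' @inheritParams shdi_components
#' @return An `lf_components` tibble (see [shdi_components()]).
#' @export
pr_components <- function(composition, grade = c("parent", "child")) {
  grade <- match.arg(grade)
  check_nonempty(composition)
  p <- grade_proportions(composition, grade)
  new_components(p$class, rep(1, nrow(p)), "pr", grade)
}

grade_proportions <- function(composition, grade) {
  if (grade == "parent") {
    tibble(class = composition$parent$parent, p = composition$parent$p)
  } else {
    ch <- composition$child
    pa <- composition$parent
    tibble(class = ch$child,
           p = ch$p_cond * pa$p[match(ch$parent, pa$parent)])
  }
}

#' Per-class number-of-patches components of a window
#'
#' Counts connected same-class components among the window's valid cells.
#' Patches are delineated within the window footprint only: a patch that
#' extends beyond the window counts once per in-window fragment.
#'
#' @param pair An `lf_pair`.
#' @param cells Window cells: data frame with `row`/`col` columns or a
#'   two-column matrix. Defaults to the whole raster.
#' @param grade `"parent"` or `"child"`.
#' @param connectivity Neighbourhood rule for patch membership: `8`
#'   (default; edges and diagonals) or `4` (edges only).
#' @return An `lf_components` tibble with one row per class present;
#'   `sum(li)` is NP.
#' @export
np_components <- function(pair, cells = NULL, grade = c("parent", "child"),
                          connectivity = 8) {
  grade <- match.arg(grade)
  stopifnot(inherits(pair, "lf_pair"))
  if (!connectivity %in% c(4, 8)) {
    lf_abort("`connectivity` must be 4 or 8.", "usage")
  }
  v <- if (grade == "parent") pair$g1$values else pair$g2$values
  if (is.null(cells)) {
    idx <- which(pair$valid, arr.ind = TRUE)
  } else {
    if (is.data.frame(cells)) cells <- cbind(cells$row, cells$col)
    idx <- cells[!is.na(v[cells]), , drop = FALSE]
  }
  counts <- count_patches(idx[, 1], idx[, 2], v[idx], connectivity)
  new_components(as.integer(names(counts)), as.numeric(counts), "np", grade)
}

# Union-find patch counting over an explicit cell set (window footprint).
count_patches <- function(rows, cols, codes, connectivity = 8) {
  n <- length(rows)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  r0 <- min(rows); c0 <- min(cols)
  nr <- max(rows) - r0 + 1L
  nc <- max(cols) - c0 + 1L
  # local dense index; 0 = not in window
  loc <- matrix(0L, nr, nc)
  li <- cbind(rows - r0 + 1L, cols - c0 + 1L)
  loc[li] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- rbind(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- rbind(offs, c(1L, 1L), c(1L, -1L))
  for (k in seq_len(n)) {
    lr <- li[k, 1]; lc <- li[k, 2]
    for (o in seq_len(nrow(offs))) {
      rr <- lr + offs[o, 1]; cc <- lc + offs[o, 2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
        j <- loc[rr, cc]
        if (j > 0L && codes[j] == codes[k]) {
          a <- find(k); b <- find(j)
          if (a != b) parent[b] <- a
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tab <- table(codes[!duplicated(roots)])
  setNames(as.numeric(tab), names(tab))
}

new_components <- function(class, li, metric, grade) {
  out <- tibble(class = as.integer(class), li = as.numeric(li))
  out <- out[order(out$class), ]
  attr(out, "metric") <- metric
  attr(out, "grade") <- grade
  class(out) <- c("lf_components", class(out))
  out
}

#' Total value of a component decomposition
#'
#' @param x An `lf_components` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `metric`, `grade`, `n_classes`, `total`.
#' @exportS3Method generics::glance
glance.lf_components <- function(x, ...) {
  tibble(metric = attr(x, "metric"), grade = attr(x, "grade"),
         n_classes = nrow(x), total = sum(x$li))
}

#' Fuse parent-grade metric components with entropy weights
#'
#' The fusion step: \eqn{FLI_X = \sum_i (1 + w_i)\, LI_i}. With all
#' weights zero this reduces exactly to the unfused metric
#' \eqn{LI_X = \sum_i LI_i}; with maximal weights it reaches
#' \eqn{2\,LI_X}.
#'
#' @param components An `lf_components` tibble at parent grade.
#' @param weights An `lf_weights` tibble from [fusion_weights()]. Parents
#'   present in `weights` must each have a component; parents without a
#'   weight row contribute `w = 0`.
#' @return An object of class `lf_fused`: list with `metric`, `value`
#'   (the fused \eqn{FLI_X}), `base` (the unfused \eqn{LI_X}), and
#'   `terms` (per-parent tibble: `parent`, `li`, `w`, `contribution`).
#' @examples
#' h <- infer_hierarchy(c(11, 12, 21))
#' g2 <- lf_grid(matrix(c(rep(11L, 4), rep(12L, 4), rep(21L, 8)), 4, 4))
#' comp <- window_composition(pair_rasters(g2, hierarchy = h))
#' fuse(shdi_components(comp), fusion_weights(comp))
#' @export
fuse <- function(components, weights) {
  stopifnot(inherits(components, "lf_components"),
            inherits(weights, "lf_weights"))
  if (!identical(attr(components, "grade"), "parent")) {
    lf_abort("Fusion requires parent-grade components.", "usage")
  }
  miss <- setdiff(weights$parent, components$class)
  if (length(miss) > 0L) {
    lf_abort(sprintf("Weight given for parent(s) with no component: %s.",
                     paste(miss, collapse = ", ")), "indexing")
  }
  w <- weights$w[match(components$class, weights$parent)]
  w[is.na(w)] <- 0
  terms <- tibble(parent = components$class, li = components$li, w = w,
                  contribution = (1 + w) * components$li)
  structure(
    list(metric = attr(components, "metric"),
         value = sum(terms$contribution),
         base = sum(terms$li),
         terms = terms),
    class = "lf_fused"
  )
}

#' @export
print.lf_fused <- function(x, ...) {
  cat(sprintf("<lf_fused> %s: FLI = %.6f (base %s = %.6f)\n",
              toupper(x$metric), x$value, toupper(x$metric), x$base))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lf_fused <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.lf_fused <- function(x, ...) {
  tibble(metric = x$metric, value = x$value, base = x$base,
         uplift = x$value - x$base)
}
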