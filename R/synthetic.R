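# Run code with a private, restorable RNG state so generation is a pure
# function of `seed` and never disturbs the caller's random stream.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    lf_abort("`seed` must be a single integer.", "domain")
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Separable Gaussian smoothing with edge replication.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_cols <- function(x) {
    pad <- rbind(x[rep(1L, h), , drop = FALSE], x,
                 x[rep(nrow(x), h), , drop = FALSE])
    f <- stats::filter(pad, k, sides = 2)
    matrix(f[(h + 1):(h + nrow(x)), ], nrow(x), ncol(x))
  }
  t(smooth_cols(t(smooth_cols(m))))
}

# Symmetric-Dirichlet draw via gamma variates; `mix` is the concentration.
# mix -> 0 degenerates to a random one-hot (one dominant subclass),
# large mix approaches uniform.
draw_subclass_probs <- function(k, mix) {
  if (k == 1L) return(1)
  if (mix <= 0) {
    p <- numeric(k)
    p[sample.int(k, 1L)] <- 1
    return(p)
  }
  g <- rgamma(k, shape = mix)
  if (sum(g) == 0) {  # underflow guard for very small mix
    g[sample.int(k, 1L)] <- 1
  }
  g / sum(g)
}

synthetic_hierarchy <- function(n_parents, subclasses_per_parent) {
  map <- do.call(rbind, lapply(seq_len(n_parents), function(i) {
    data.frame(child = i * 10L + seq_len(subclasses_per_parent[i]),
               parent = i)
  }))
  class_hierarchy(map)
}

#' Generate a synthetic two-grade nested landscape
#'
#' Builds a clumped first-grade mosaic by thresholding a smoothed Gaussian
#' random field into `n_parents` classes of roughly equal area, then draws
#' each cell's second-grade subclass from its parent's subclass
#' distribution (a symmetric-Dirichlet draw with concentration `mix`).
#' Parent codes are `1..n_parents`; child codes follow the decimal rule
#' (`parent * 10 + j`). The pair is vertically consistent by construction
#' and bit-identical across runs with the same arguments and seed.
#'
#' @param rows,cols Grid size in cells.
#' @param n_parents Number of first-grade classes.
#' @param subclasses_per_parent Subclasses per parent: a single count or a
#'   vector of length `n_parents`, each in `1..9`.
#' @param clump Spatial autocorrelation of the parent mosaic in `[0, 1]`:
#'   0 is cell-wise noise; larger values smooth the underlying field with
#'   a Gaussian kernel of standard deviation `5 * clump` cells.
#' @param mix Subclass concentration: near 0 one subclass dominates each
#'   parent (fusion weights near 0); large values give near-uniform
#'   subclass mixes (weights near 1).
#' @param cellsize Cell size in map units.
#' @param seed Integer seed; all randomness flows from it.
#' @return An `lf_pair` with attribute `subclass_probs` (the drawn
#'   per-parent subclass distributions, a named list).
#' @examples
#' p <- generate_landscape(32, 32, n_parents = 2,
#'                         subclasses_per_parent = 2, seed = 1)
#' @export
generate_landscape <- function(rows, cols, n_parents = 3,
                               subclasses_per_parent = 3, clump = 0.5,
                               mix = 1, cellsize = 1, seed) {
  check_synth_args(rows, cols, n_parents, subclasses_per_parent, clump)
  subclasses_per_parent <- rep_len(subclasses_per_parent, n_parents)
  h <- synthetic_hierarchy(n_parents, subclasses_per_parent)
  with_local_seed(seed, {
    g1 <- parent_mosaic(rows, cols, n_parents, clump)
    probs <- lapply(seq_len(n_parents), function(i) {
      setNames(draw_subclass_probs(subclasses_per_parent[i], mix),
               h$subclass_sets[[as.character(i)]])
    })
    names(probs) <- as.character(seq_len(n_parents))
    g2 <- draw_children(g1, probs)
    finish_pair(g2, h, cellsize, probs)
  })
}

#' Generate a landscape with an ecotone band of maximal vertical structure
#'
#' Same parent mosaic as [generate_landscape()], but the subclass mixing
#' differs inside and outside a horizontal band of rows: outside the band
#' each parent is nearly mono-subclass (`mix_outside` small), inside it
#' subclasses are nearly uniform (`mix_inside` large). The band therefore
#' concentrates the vertical (subclass) heterogeneity that fusion
#' responds to, emulating an ecological transition zone.
#'
#' The default mosaic is deliberately fine-grained (`clump = 0.1`): with
#' parent patches small relative to any realistic analysis window, the
#' horizontal structure (which classes are present) is the same
#' everywhere and the band contrast isolates the vertical structure that
#' the fixture exists to exhibit. A coarse mosaic would confound the
#' comparison with ordinary richness variation.
#'
#' @inheritParams generate_landscape
#' @param band Integer vector `c(first_row, last_row)` of the band;
#'   default is the middle third of the grid.
#' @param mix_outside,mix_inside Subclass concentrations outside/inside
#'   the band.
#' @return A list with `pair` (`lf_pair`, carrying `subclass_probs` with
#'   `$inside` and `$outside` components) and `band_mask` (logical
#'   matrix, `TRUE` inside the band).
#' @export
generate_ecotone_landscape <- function(rows, cols, n_parents = 3,
                                       subclasses_per_parent = 3,
                                       clump = 0.1, band = NULL,
                                       mix_outside = 0.1, mix_inside = 25,
                                       cellsize = 1, seed) {
  check_synth_args(rows, cols, n_parents, subclasses_per_parent, clump)
  subclasses_per_parent <- rep_len(subclasses_per_parent, n_parents)
  if (is.null(band)) {
    band <- c(floor(rows / 3) + 1L, floor(2 * rows / 3))
  }
  band <- as.integer(band)
  if (length(band) != 2L || band[1] > band[2] || band[1] < 1L ||
      band[2] > rows) {
    lf_abort("`band` must be c(first_row, last_row) within the grid.",
             "domain")
  }
  h <- synthetic_hierarchy(n_parents, subclasses_per_parent)
  with_local_seed(seed, {
    g1 <- parent_mosaic(rows, cols, n_parents, clump)
    draw_set <- function(mix) {
      p <- lapply(seq_len(n_parents), function(i) {
        setNames(draw_subclass_probs(subclasses_per_parent[i], mix),
                 h$subclass_sets[[as.character(i)]])
      })
      names(p) <- as.character(seq_len(n_parents))
      p
    }
    probs_out <- draw_set(mix_outside)
    probs_in <- draw_set(mix_inside)
    band_mask <- matrix(FALSE, rows, cols)
    band_mask[band[1]:band[2], ] <- TRUE
    g2 <- matrix(NA_integer_, rows, cols)
    for (region in c("inside", "outside")) {
      mask <- if (region == "inside") band_mask else !band_mask
      probs <- if (region == "inside") probs_in else probs_out
      sub <- draw_children(ifelse(mask, g1, NA_integer_), probs)
      g2[mask] <- sub[mask]
    }
    pair <- finish_pair(g2, h, cellsize,
                        list(inside = probs_in, outside = probs_out))
    list(pair = pair, band_mask = band_mask)
  })
}

check_synth_args <- function(rows, cols, n_parents, subclasses_per_parent,
                             clump) {
  if (rows < 1 || cols < 1 || n_parents < 1) {
    lf_abort("Grid size and `n_parents` must be positive.", "domain")
  }
  if (any(subclasses_per_parent < 1) || any(subclasses_per_parent > 9)) {
    lf_abort("`subclasses_per_parent` must be in 1..9.", "domain")
  }
  if (clump < 0 || clump > 1) {
    lf_abort("`clump` must be in [0, 1].", "domain")
  }
}

parent_mosaic <- function(rows, cols, n_parents, clump) {
  field <- matrix(rnorm(rows * cols), rows, cols)
  field <- smooth_field(field, sigma = 5 * clump)
  if (n_parents == 1L) return(matrix(1L, rows, cols))
  br <- stats::quantile(field, probs = seq_len(n_parents - 1) / n_parents)
  matrix(findInterval(field, br) + 1L, rows, cols)
}

draw_children <- function(g1, probs) {
  g2 <- matrix(NA_integer_, nrow(g1), ncol(g1))
  for (p in names(probs)) {
    cells <- which(!is.na(g1) & g1 == as.integer(p))
    if (length(cells) == 0L) next
    pr <- probs[[p]]
    codes <- as.integer(names(pr))
    g2[cells] <- if (length(codes) == 1L) codes
                 else sample(codes, length(cells), replace = TRUE, prob = pr)
  }
  g2
}

finish_pair <- function(g2, h, cellsize, probs) {
  pair <- pair_rasters(lf_grid(g2, cellsize = cellsize), hierarchy = h)
  attr(pair, "subclass_probs") <- probs
  pair
}
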