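#' Quantize a metric surface to integer symbols
#'
#' Min-max normalizes the valid cells to `[0, 1]` (a constant surface
#' normalizes to all zeros) and keeps the first `decimals` decimal places
#' by round-half-up, giving symbols in `0 .. 10^decimals`. This is the
#' lossy front end of the information-volume measure.
#'
#' @param surface An `lf_surface` (or bare `lf_grid`).
#' @param decimals Number of decimal places kept (default 4).
#' @return An integer matrix of symbols, `NA` where the surface is NoData.
#' @export
quantize_surface <- function(surface, decimals = 4) {
  g <- if (inherits(surface, "lf_surface")) surface$grid else surface
  stopifnot(inherits(g, "lf_grid"))
  if (decimals <= 0 || decimals != round(decimals)) {
    lf_abort("`decimals` must be a positive integer.", "domain")
  }
  v <- g$values
  val <- v[!is.na(v)]
  if (length(val) == 0L) {
    lf_abort("Surface has no valid cells.", "undefined_input")
  }
  lo <- min(val); hi <- max(val)
  sym <- matrix(NA_integer_, nrow(v), ncol(v))
  if (hi > lo) {
    norm <- (v - lo) / (hi - lo)
    # round half up (not banker's rounding)
    sym[!is.na(v)] <- as.integer(floor(norm[!is.na(v)] * 10^decimals + 0.5))
  } else {
    sym[!is.na(v)] <- 0L
  }
  sym
}

#' Optimal binary prefix code for a symbol frequency profile
#'
#' Builds a Huffman tree: repeatedly merges the two least-frequent nodes,
#' with ties broken deterministically by (weight, smallest contained
#' symbol) ascending. A single-symbol alphabet gets code length 1 by
#' convention. For two or more symbols the code lengths satisfy the Kraft
#' equality \eqn{\sum 2^{-len} = 1} and the mean length lies within one
#' bit of the base-2 entropy of the frequencies.
#'
#' @param counts Named numeric vector: names are symbol values, entries
#'   positive frequencies (zero-count symbols are dropped).
#' @return A tibble of class `lf_codebook` with columns `symbol`,
#'   `count`, and `code_length` (bits).
#' @examples
#' huffman_codebook(c(`0` = 2, `1` = 1, `2` = 1))  # lengths 1, 2, 2
#' @export
huffman_codebook <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    lf_abort("No symbols with positive counts.", "domain")
  }
  symbols <- as.integer(names(counts))
  if (anyNA(symbols)) {
    lf_abort("`counts` must be named by integer symbol values.", "usage")
  }
  ord <- order(symbols)
  symbols <- symbols[ord]
  counts <- as.numeric(counts[ord])
  n <- length(symbols)
  if (n == 1L) {
    out <- tibble(symbol = symbols, count = counts, code_length = 1L)
    class(out) <- c("lf_codebook", class(out))
    return(out)
  }
  # node arrays: leaves 1..n, internal nodes appended
  n_nodes <- 2L * n - 1L
  weight <- c(counts, rep(NA_real_, n - 1L))
  key <- c(symbols, rep(NA_integer_, n - 1L))  # smallest symbol in subtree
  up <- integer(n_nodes)                       # parent pointer (0 = root)
  active <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    # two minima by (weight, key) ascending
    o <- act[order(weight[act], key[act])[1:2]]
    new <- n + m
    weight[new] <- weight[o[1]] + weight[o[2]]
    key[new] <- min(key[o])
    up[o] <- new
    active[o] <- FALSE
    active[new] <- TRUE
  }
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (up[j] != 0L) { j <- up[j]; d <- d + 1L }
    depth[i] <- d
  }
  out <- tibble(symbol = symbols, count = counts, code_length = depth)
  class(out) <- c("lf_codebook", class(out))
  out
}

#' Information volume of a metric surface
#'
#' Quantizes the surface, builds its own Huffman codebook from the symbol
#' frequencies, and charges every valid cell the code length of its
#' symbol. The total is the number of bits a lossless optimal binary
#' prefix code needs for the quantized surface — the package's proxy for
#' the spatial information content of the indicator.
#'
#' @inheritParams quantize_surface
#' @return An object of class `lf_infovol`: list with `per_cell_bits`
#'   (`lf_grid`), `total_bits`, `mean_bits_per_cell`, `n_valid`,
#'   `codebook` (`lf_codebook`), and `entropy_bits` (base-2 entropy of
#'   the symbol frequencies, the Huffman lower bound).
#' @export
info_volume <- function(surface, decimals = 4) {
  sym <- quantize_surface(surface, decimals)
  g <- if (inherits(surface, "lf_surface")) surface$grid else surface
  counts <- table(sym[!is.na(sym)])
  cb <- huffman_codebook(setNames(as.numeric(counts), names(counts)))
  len <- setNames(cb$code_length, cb$symbol)
  bits <- matrix(NA_real_, nrow(sym), ncol(sym))
  bits[!is.na(sym)] <- len[as.character(sym[!is.na(sym)])]
  freq <- cb$count / sum(cb$count)
  structure(
    list(
      per_cell_bits = lf_grid(bits, cellsize = g$cellsize, xll = g$xll,
                              yll = g$yll, nodata = g$nodata, crs = g$crs),
      total_bits = sum(bits, na.rm = TRUE),
      mean_bits_per_cell = mean(bits, na.rm = TRUE),
      n_valid = sum(!is.na(sym)),
      codebook = cb,
      entropy_bits = -sum(freq * log2(freq))
    ),
    class = "lf_infovol"
  )
}

#' @export
print.lf_infovol <- function(x, ...) {
  cat(sprintf(
    "<lf_infovol> %d cells, %d symbols, %.0f bits total (%.4f bits/cell; H2 = %.4f)\n",
    x$n_valid, nrow(x$codebook), x$total_bits, x$mean_bits_per_cell,
    x$entropy_bits))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.lf_infovol <- function(x, ...) {
  tibble(n_valid = x$n_valid, n_symbols = nrow(x$codebook),
         total_bits = x$total_bits,
         mean_bits_per_cell = x$mean_bits_per_cell,
         entropy_bits = x$entropy_bits)
}

shared_valid <- function(a, b, what = "Surfaces") {
  ga <- if (inherits(a, "lf_surface")) a$grid else a
  gb <- if (inherits(b, "lf_surface")) b$grid else b
  if (!identical(dim(ga$values), dim(gb$values))) {
    lf_abort(sprintf("%s differ in shape.", what), "grid_alignment")
  }
  list(ga = ga, gb = gb, mask = !is.na(ga$values) & !is.na(gb$values))
}

#' Degree of changes between a fused and an unfused surface
#'
#' Both surfaces are min-max normalized independently over their shared
#' valid cells (a constant surface normalizes to 0); the result is the
#' absolute difference of the normalized surfaces, a `[0, 1]` map of
#' where fusion changed the indicator most — large where the window's
#' vertical (subclass) structure is strongest.
#'
#' @param fli,g1li Two `lf_surface`s of the same shape (conventionally
#'   the fused and unfused variant of one metric at one radius).
#' @return An `lf_grid` with values in `[0, 1]`.
#' @export
degree_of_changes <- function(fli, g1li) {
  s <- shared_valid(fli, g1li)
  norm01 <- function(v, mask) {
    val <- v[mask]
    rng <- range(val)
    out <- matrix(NA_real_, nrow(v), ncol(v))
    out[mask] <- if (rng[2] > rng[1]) (val - rng[1]) / (rng[2] - rng[1]) else 0
    out
  }
  d <- abs(norm01(s$ga$values, s$mask) - norm01(s$gb$values, s$mask))
  lf_grid(d, cellsize = s$ga$cellsize, xll = s$ga$xll, yll = s$ga$yll,
          nodata = s$ga$nodata, crs = s$ga$crs)
}

#' Pearson correlation between two metric surfaces
#'
#' Product-moment correlation over the cells valid in both surfaces.
#'
#' @param a,b Two `lf_surface`s (or `lf_grid`s) of the same shape.
#' @return A single number in `[-1, 1]`, or `NA` (with a warning) when
#'   either surface has zero variance on the shared cells.
#' @export
surface_correlation <- function(a, b) {
  s <- shared_valid(a, b)
  va <- s$ga$values[s$mask]
  vb <- s$gb$values[s$mask]
  if (length(va) < 2L) {
    lf_abort("Need at least two shared valid cells.", "undefined_input")
  }
  if (sd(va) == 0 || sd(vb) == 0) {
    warn("Correlation undefined: a surface has zero variance.",
         class = "landfuse_undefined_correlation")
    return(NA_real_)
  }
  cor(va, vb)
}

#' Compare the information volume of two surfaces cell by cell
#'
#' Given the per-cell information volumes of two surfaces (typically a
#' fused indicator `x` against its unfused counterpart `y`), computes the
#' difference map and the summary statistics used to argue that fusion
#' adds information: the area share where `x` carries more bits and the
#' share of the absolute difference that is positive.
#'
#' @param x,y Two `lf_infovol` results on the same geometry.
#' @return An object of class `lf_iv_comparison`: list with `div`
#'   (`lf_grid`, per-cell bits of `x` minus `y`), `ra` (fraction of valid
#'   cells with positive difference), `rv` (positive difference over
#'   total absolute difference; `NA` when the surfaces carry identical
#'   per-cell bits), and `totals_ratio` (`x$total_bits / y$total_bits`).
#' @export
compare_info_volume <- function(x, y) {
  stopifnot(inherits(x, "lf_infovol"), inherits(y, "lf_infovol"))
  s <- shared_valid(x$per_cell_bits, y$per_cell_bits,
                    "Information-volume grids")
  d <- matrix(NA_real_, nrow(s$ga$values), ncol(s$ga$values))
  d[s$mask] <- s$ga$values[s$mask] - s$gb$values[s$mask]
  dv <- d[s$mask]
  rv <- if (all(dv == 0)) {
    warn("All per-cell differences are zero; RV is undefined.",
         class = "landfuse_undefined_rv")
    NA_real_
  } else {
    sum(dv[dv > 0]) / sum(abs(dv))
  }
  structure(
    list(
      div = lf_grid(d, cellsize = s$ga$cellsize, xll = s$ga$xll,
                    yll = s$ga$yll, nodata = s$ga$nodata, crs = s$ga$crs),
      ra = mean(dv > 0),
      rv = rv,
      totals_ratio = x$total_bits / y$total_bits
    ),
    class = "lf_iv_comparison"
  )
}

#' @export
print.lf_iv_comparison <- function(x, ...) {
  cat(sprintf("<lf_iv_comparison> RA = %.4f, RV = %s, totals ratio = %.4f\n",
              x$ra, ifelse(is.na(x$rv), "undefined", sprintf("%.4f", x$rv)),
              x$totals_ratio))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.lf_iv_comparison <- function(x, ...) {
  tibble(ra = x$ra, rv = x$rv, totals_ratio = x$totals_ratio)
}
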