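surface_from <- function(values, nrowv = 1) {
  lf_grid(matrix(values, nrow = nrowv))
}

test_that("quantization normalizes, rounds half up, and handles constants", {
  expect_equal(as.vector(quantize_surface(surface_from(c(0, 5, 10)))),
               c(0L, 5000L, 10000L))
  expect_equal(as.vector(quantize_surface(surface_from(rep(3.7, 5)))),
               rep(0L, 5))
  # 0.00005 at d = 4 rounds up to symbol 1
  sym <- quantize_surface(surface_from(c(0, 0.00005, 1)))
  expect_equal(as.vector(sym), c(0L, 1L, 10000L))
  expect_error(quantize_surface(surface_from(1:3), decimals = 0),
               class = "landfuse_domain")
  na <- surface_from(c(NA, 1, 2))
  expect_true(is.na(quantize_surface(na)[1, 1]))
})

test_that("the codebook solves the classic {2,1,1} and balanced cases", {
  cb <- huffman_codebook(c(`0` = 2, `1` = 1, `2` = 1))
  expect_equal(cb$code_length, c(1L, 2L, 2L))
  expect_equal(sum(cb$count * cb$code_length), 6)
  cb4 <- huffman_codebook(setNames(rep(5, 4), 0:3))
  expect_equal(cb4$code_length, rep(2L, 4))
  expect_equal(huffman_codebook(c(`7` = 3))$code_length, 1L)
  expect_error(huffman_codebook(numeric()), class = "landfuse_domain")
})

test_that("codebooks satisfy Kraft equality and the entropy bound", {
  set.seed(55)
  for (rep in 1:100) {
    k <- sample(2:40, 1)
    counts <- setNames(sample(1:50, k, replace = TRUE), sample.int(10000, k))
    cb <- huffman_codebook(counts)
    expect_equal(sum(2^(-cb$code_length)), 1, tolerance = 1e-12)
    freq <- cb$count / sum(cb$count)
    h2 <- -sum(freq * log2(freq))
    mean_len <- sum(freq * cb$code_length)
    expect_gte(mean_len, h2 - 1e-9)
    expect_lt(mean_len, h2 + 1)
  }
})

test_that("no shuffled-tree prefix code beats the codebook", {
  # adversary: code lengths from a random (non-frequency-sorted) full
  # binary tree over the same symbols
  random_tree_lengths <- function(k) {
    sizes <- rep(1L, k)
    depths <- vector("list", k)
    for (i in seq_len(k)) depths[[i]] <- 0L
    while (length(sizes) > 1L) {
      pick <- sample(length(sizes), 2)
      a <- min(pick); b <- max(pick)
      merged <- c(depths[[a]] + 1L, depths[[b]] + 1L)
      depths[[a]] <- merged
      depths[b] <- NULL
      sizes[a] <- sizes[a] + sizes[b]
      sizes <- sizes[-b]
    }
    depths[[1]]
  }
  set.seed(66)
  for (rep in 1:30) {
    k <- sample(3:15, 1)
    counts <- setNames(sample(1:30, k, replace = TRUE), seq_len(k))
    cb <- huffman_codebook(counts)
    huff_cost <- sum(cb$count * cb$code_length)
    for (adv in 1:5) {
      lens <- random_tree_lengths(k)
      # adversary assigns its lengths to symbols sorted by count (its best case)
      cost <- sum(sort(as.numeric(counts)) * sort(lens, decreasing = TRUE))
      expect_lte(huff_cost, cost + 1e-9)
    }
  }
})

test_that("information volume charges each cell its code length", {
  # values quantizing to counts {2, 1, 1} -> 2*1 + 1*2 + 1*2 = 6 bits
  iv <- info_volume(surface_from(c(0, 0, 0.5, 1)))
  expect_equal(iv$total_bits, 6)
  expect_equal(iv$per_cell_bits$values[1, 1:2], c(1, 1))
  # constant surface: single symbol, 1 bit per cell
  ivc <- info_volume(surface_from(rep(2.5, 7)))
  expect_equal(ivc$total_bits, 7)
  # 4 equally frequent symbols: 2 bits per cell
  iv4 <- info_volume(surface_from(rep(c(0, 0.25, 0.75, 1), 5)))
  expect_equal(iv4$total_bits, 40)
  expect_gte(iv$mean_bits_per_cell, iv$entropy_bits - 1e-9)
})

test_that("information volume is invariant under affine rescaling", {
  set.seed(77)
  base <- surface_from(runif(64), nrowv = 8)
  iv0 <- info_volume(base)
  for (scale in c(2, 4, 0.5)) {
    shifted <- surface_from(base$values * scale + 3, nrowv = 8)
    expect_equal(info_volume(shifted)$total_bits, iv0$total_bits)
  }
})

test_that("degree of changes is a symmetric [0,1] map with known cases", {
  a <- surface_from(c(1, 2, 3, 4))
  expect_true(all(degree_of_changes(a, a)$values == 0))
  # constant second argument: result equals the first's normalized values
  b <- surface_from(rep(9, 4))
  expect_equal(as.vector(degree_of_changes(a, b)$values),
               c(0, 1, 2, 3) / 3)
  # two-cell antithetical surfaces normalize to {1, 1}
  expect_equal(as.vector(degree_of_changes(surface_from(c(0, 1)),
                                           surface_from(c(1, 0)))$values),
               c(1, 1))
  # symmetry
  set.seed(88)
  x <- surface_from(runif(20)); y <- surface_from(runif(20))
  expect_equal(degree_of_changes(x, y)$values,
               degree_of_changes(y, x)$values)
  expect_error(degree_of_changes(a, surface_from(1:6)),
               class = "landfuse_grid_alignment")
})

test_that("surface correlation matches the textbook formula", {
  a <- surface_from(c(1, 2, 3, 4))
  b <- surface_from(c(1, 2, 3, 5))
  expect_equal(surface_correlation(a, a), 1)
  neg <- surface_from(-c(1, 2, 3, 4))
  expect_equal(surface_correlation(a, neg), -1)
  expect_equal(surface_correlation(a, b), 6.5 / sqrt(5 * 8.75),
               tolerance = 1e-12)
  expect_equal(surface_correlation(a, b), 0.982708, tolerance = 1e-6)
  expect_warning(r <- surface_correlation(a, surface_from(rep(1, 4))),
                 class = "landfuse_undefined_correlation")
  expect_true(is.na(r))
})

test_that("information-volume comparison reports DIV, RA and RV", {
  iv_of <- function(vals) info_volume(surface_from(vals, nrowv = 2))
  x <- iv_of(c(0, 0, 0.3, 0.5, 0.7, 1, 1, 1))
  expect_warning(same <- compare_info_volume(x, x),
                 class = "landfuse_undefined_rv")
  expect_equal(same$ra, 0)
  expect_true(all(same$div$values == 0))
  expect_true(is.na(same$rv))
  expect_equal(same$totals_ratio, 1)
  # strict dominance: four balanced symbols (2 bits/cell) vs constant (1)
  x4 <- iv_of(rep(c(0, 0.25, 0.75, 1), 2))
  y <- iv_of(rep(0, 8))
  dom <- compare_info_volume(x4, y)
  expect_equal(dom$ra, 1)
  expect_equal(dom$rv, 1)
  # hand-built DIV {+2, -1, +1, 0}
  mk <- function(bits) {
    structure(list(per_cell_bits = surface_from(bits),
                   total_bits = sum(bits)), class = "lf_infovol")
  }
  cmp <- compare_info_volume(mk(c(3, 1, 3, 2)), mk(c(1, 2, 2, 2)))
  expect_equal(cmp$ra, 0.5)
  expect_equal(cmp$rv, 3 / 4)
})
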