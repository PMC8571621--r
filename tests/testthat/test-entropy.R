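test_that("the worked 16-cell window yields the textbook entropy values", {
  comp <- window_composition(w1_pair())
  expect_equal(comp$total_valid, 16L)
  expect_equal(comp$parent$p, c(0.5, 0.5))
  expect_equal(comp$child$p_cond, c(0.5, 0.5, 1))
  expect_equal(entropy_global(comp), log(2), tolerance = 1e-12)
  expect_equal(conditional_entropy(comp), 0.5 * log(2), tolerance = 1e-12)
  expect_equal(class_conditional_entropy(comp, 1), 0.5 * log(2),
               tolerance = 1e-12)
  expect_equal(class_conditional_entropy(comp, 2), 0)
  w <- fusion_weights(comp)
  expect_equal(w$w, c(0.5, 0))
})

test_that("degenerate compositions behave: certainty, uniformity, emptiness", {
  h <- infer_hierarchy(c(11, 12, 21))
  one <- window_composition(pair_rasters(lf_grid(matrix(11L, 3, 3)),
                                         hierarchy = h))
  expect_equal(entropy_global(one), 0)
  expect_equal(conditional_entropy(one), 0)
  expect_equal(fusion_weights(one)$w, 0)

  h4 <- infer_hierarchy(c(11, 21, 31, 41))
  four <- window_composition(pair_rasters(
    lf_grid(matrix(c(11L, 21L, 31L, 41L), 2, 2)), hierarchy = h4))
  expect_equal(entropy_global(four), log(4), tolerance = 1e-12)

  # one parent with two equal subclasses: H(Y|X) = ln 2, w = 1
  h2 <- infer_hierarchy(c(11, 12))
  two <- window_composition(pair_rasters(
    lf_grid(matrix(c(11L, 12L), 2, 4)), hierarchy = h2))
  expect_equal(conditional_entropy(two), log(2), tolerance = 1e-12)
  expect_equal(fusion_weights(two)$w, 1)

  empty <- window_composition(pair_rasters(
    lf_grid(matrix(NA_integer_, 2, 2)), hierarchy = h))
  expect_equal(empty$total_valid, 0L)
  expect_error(entropy_global(empty), class = "landfuse_undefined_input")
  expect_error(fusion_weights(empty), class = "landfuse_undefined_input")
})

test_that("a 0.4-share parent with a 75/25 subclass split matches closed form", {
  # 40 cells of parent 1 (30 of 11, 10 of 12), 60 cells of parent 2 (21)
  h <- infer_hierarchy(c(11, 12, 21))
  codes <- c(rep(11L, 30), rep(12L, 10), rep(21L, 60))
  comp <- window_composition(pair_rasters(lf_grid(matrix(codes, 10, 10)),
                                          hierarchy = h))
  expected <- 0.4 * (-0.75 * log(0.75) - 0.25 * log(0.25))
  expect_equal(class_conditional_entropy(comp, 1), expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.224934, tolerance = 1e-6)
  expect_error(class_conditional_entropy(comp, 9), class = "landfuse_lookup")
})

test_that("n_source selects the weight denominator", {
  # scheme has 4 subclasses of parent 2; data observe 2; window holds 1
  h <- infer_hierarchy(c(11, 12, 21, 22, 23, 24))
  g2 <- lf_grid(matrix(c(rep(11L, 2), rep(12L, 2), rep(21L, 3), 22L), 2, 4))
  pair <- pair_rasters(g2, hierarchy = h)
  window <- window_composition(pair, cells = cbind(1L, 1:2))  # 11, 12
  expect_equal(fusion_weights(window, "window")$n_used, 2L)
  expect_equal(fusion_weights(window, "dataset")$n_used, 2L)
  expect_equal(fusion_weights(window, "scheme")$n_used, 2L)
  full <- window_composition(pair)
  expect_equal(fusion_weights(full, "scheme")$n_used, c(2L, 4L))
  # single observed subclass with a 4-subclass scheme: 0 / ln 4 = 0
  mono <- window_composition(pair, cells = cbind(c(1, 2, 1), c(3, 3, 4)))
  w <- fusion_weights(mono, "scheme")
  expect_equal(w$n_used[w$parent == 2], 4L)
  expect_equal(w$w[w$parent == 2], 0)
})

test_that("conditional entropy decomposes over parents (Eq-2/Eq-3 consistency)", {
  set.seed(101)
  for (rep in 1:200) {
    case <- rand_composition_case()
    total <- sum(vapply(case$comp$parent$parent, function(i) {
      class_conditional_entropy(case$comp, i)
    }, numeric(1)))
    expect_equal(conditional_entropy(case$comp), total, tolerance = 1e-12)
  }
})

test_that("entropy operations agree with the brute-force oracle", {
  set.seed(202)
  for (rep in 1:200) {
    case <- rand_composition_case()
    comp <- case$comp
    expect_equal(entropy_global(comp), o_entropy_global(case$parents),
                 tolerance = 1e-9)
    expect_equal(conditional_entropy(comp),
                 o_conditional_entropy(case$children, case$parents),
                 tolerance = 1e-9)
    w <- fusion_weights(comp)
    expect_equal(w$w,
                 unname(o_weights(case$children, case$parents)),
                 tolerance = 1e-9)
    ws <- fusion_weights(comp, "scheme")
    expect_equal(ws$w,
                 unname(o_weights(case$children, case$parents, "scheme",
                                  scheme_n = case$scheme_n)),
                 tolerance = 1e-9)
  }
})

test_that("weights are bounded: 0 <= w_i <= p(x_i) <= 1 under window n", {
  set.seed(303)
  for (rep in 1:100) {
    case <- rand_composition_case()
    w <- fusion_weights(case$comp)
    expect_true(all(w$w >= 0))
    expect_true(all(w$w <= w$p + 1e-12))
    expect_true(all(w$w <= 1))
    # w_i = 0 exactly where one subclass is present
    mono <- w$n_used == 1L
    expect_true(all(w$w[mono] == 0))
  }
})

test_that("merging two subclasses never increases a parent's H_i'", {
  set.seed(404)
  for (rep in 1:50) {
    case <- rand_composition_case()
    comp <- case$comp
    # merge the two most frequent subclasses of the first multi-subclass parent
    ch <- comp$child
    multi <- names(which(table(ch$parent) >= 2))
    if (length(multi) == 0) next
    i <- as.integer(multi[1])
    kids <- ch$child[ch$parent == i]
    merged <- case$children
    merged[merged == kids[2]] <- kids[1]
    h_before <- o_hprime(case$children, case$parents, i)
    h_after <- o_hprime(merged, case$parents, i)
    expect_lte(h_after, h_before + 1e-12)
  }
})
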