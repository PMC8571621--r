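# Brute-force oracles: every function here loops over raw cell lists and
# shares no code with the package implementation.

o_entropy_global <- function(parents) {
  n <- length(parents)
  h <- 0
  for (x in unique(parents)) {
    p <- sum(parents == x) / n
    h <- h - p * log(p)
  }
  h
}

o_hprime <- function(children, parents, i) {
  n <- length(parents)
  px <- sum(parents == i) / n
  kids <- children[parents == i]
  acc <- 0
  for (y in unique(kids)) {
    pyx <- sum(kids == y) / length(kids)
    acc <- acc - pyx * log(pyx)
  }
  px * acc
}

o_conditional_entropy <- function(children, parents) {
  s <- 0
  for (i in unique(parents)) s <- s + o_hprime(children, parents, i)
  s
}

o_weights <- function(children, parents, n_source = "window",
                      scheme_n = NULL, dataset_children = NULL,
                      dataset_parents = NULL) {
  ps <- sort(unique(parents))
  w <- numeric(length(ps))
  for (k in seq_along(ps)) {
    i <- ps[k]
    ni <- switch(n_source,
      window = length(unique(children[parents == i])),
      dataset = length(unique(dataset_children[dataset_parents == i])),
      scheme = scheme_n[[as.character(i)]]
    )
    w[k] <- if (ni <= 1) 0 else o_hprime(children, parents, i) / log(ni)
  }
  names(w) <- ps
  w
}

o_shdi <- function(codes) o_entropy_global(codes)

o_pr <- function(codes) length(unique(codes))

# BFS flood fill, O(n^2) adjacency scan: per-class patch counts.
o_np_by_class <- function(rows, cols, codes, connectivity = 8) {
  n <- length(rows)
  visited <- rep(FALSE, n)
  counts <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    cls <- as.character(codes[s])
    counts[cls] <- if (is.na(counts[cls])) 1L else counts[cls] + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue) > 0) {
      a <- queue[1]
      queue <- queue[-1]
      for (b in seq_len(n)) {
        if (visited[b] || codes[b] != codes[a]) next
        dr <- abs(rows[a] - rows[b])
        dc <- abs(cols[a] - cols[b])
        touching <- if (connectivity == 4) dr + dc == 1
                    else max(dr, dc) == 1
        if (touching) {
          visited[b] <- TRUE
          queue <- c(queue, b)
        }
      }
    }
  }
  counts
}

o_np <- function(rows, cols, codes, connectivity = 8) {
  sum(o_np_by_class(rows, cols, codes, connectivity))
}

# FLI = sum_i (1 + w_i) * li_i, matched by parent name.
o_fli <- function(li, w) {
  stopifnot(all(names(li) %in% c(names(w), names(li))))
  wv <- w[names(li)]
  wv[is.na(wv)] <- 0
  sum((1 + wv) * li)
}

# One window's metric value, recomputed from the raw raster (independent of
# the package's sweep engine). Returns NA under the same validity contract.
o_surface_value <- function(pair, r, c, metric, variant, radius_cells,
                            min_frac = 0.5, connectivity = 8) {
  g1 <- pair$g1$values
  g2 <- pair$g2$values
  if (is.na(g2[r, c])) return(NA_real_)
  rad <- floor(radius_cells)
  rows <- c(); cols <- c(); noff <- 0L
  for (dr in -rad:rad) {
    for (dc in -rad:rad) {
      if (dr * dr + dc * dc <= radius_cells^2 + 1e-9) {
        noff <- noff + 1L
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(g2) && cc >= 1 && cc <= ncol(g2) &&
            !is.na(g2[rr, cc])) {
          rows <- c(rows, rr); cols <- c(cols, cc)
        }
      }
    }
  }
  n <- length(rows)
  if (n == 0L || n < min_frac * noff) return(NA_real_)
  kids <- g2[cbind(rows, cols)]
  pars <- g1[cbind(rows, cols)]
  if (variant == "g2li") {
    return(switch(metric,
                  shdi = o_shdi(kids),
                  pr = o_pr(kids),
                  np = o_np(rows, cols, kids, connectivity)))
  }
  li <- switch(metric,
    shdi = {
      ps <- sort(unique(pars))
      v <- vapply(ps, function(i) {
        p <- sum(pars == i) / n
        -p * log(p)
      }, numeric(1))
      names(v) <- ps
      v
    },
    pr = {
      ps <- sort(unique(pars))
      setNames(rep(1, length(ps)), ps)
    },
    np = {
      cnt <- o_np_by_class(rows, cols, pars, connectivity)
      setNames(as.numeric(cnt), names(cnt))
    }
  )
  if (variant == "g1li") return(sum(li))
  o_fli(li, o_weights(kids, pars))
}

# A random two-grade composition realized as a 1-row raster pair, plus the
# raw child/parent cell vectors for the oracles.
rand_composition_case <- function() {
  n_parents <- sample(2:4, 1)
  kmax <- sample(2:4, 1)
  scheme <- lapply(seq_len(n_parents), function(i) i * 10L + seq_len(kmax))
  names(scheme) <- seq_len(n_parents)
  all_children <- unlist(scheme)
  n <- sample(20:150, 1)
  kids <- sample(all_children, n, replace = TRUE,
                 prob = rexp(length(all_children)))
  h <- class_hierarchy(data.frame(child = all_children,
                                  parent = rep(seq_len(n_parents),
                                               each = kmax)))
  pair <- pair_rasters(lf_grid(matrix(kids, nrow = 1)), hierarchy = h)
  list(pair = pair, comp = window_composition(pair),
       children = kids, parents = kids %/% 10L,
       scheme_n = setNames(as.list(rep(kmax, n_parents)),
                           seq_len(n_parents)))
}

# A small random raster pair for spatial (NP, window-sweep) checks.
rand_pair <- function(rows = 6, cols = 6, n_parents = 2, k = 2,
                      nodata_frac = 0) {
  children <- as.vector(outer(seq_len(k), seq_len(n_parents) * 10L, `+`))
  m <- matrix(sample(children, rows * cols, replace = TRUE), rows, cols)
  if (nodata_frac > 0) {
    drop <- sample(length(m), ceiling(nodata_frac * length(m)))
    m[drop] <- NA_integer_
  }
  pair_rasters(lf_grid(m), hierarchy = infer_hierarchy(children))
}

# The worked 16-cell window: parent 1 = {11 x4, 12 x4}, parent 2 = {21 x8}.
w1_pair <- function() {
  h <- infer_hierarchy(c(11, 12, 21))
  g2 <- lf_grid(matrix(c(rep(11L, 4), rep(12L, 4), rep(21L, 8)), 4, 4))
  pair_rasters(g2, hierarchy = h)
}
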