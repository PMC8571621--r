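#' Shannon entropy of the first-grade composition
#'
#' \eqn{H(X) = -\sum_i p(x_i)\,\ln p(x_i)} over the parent classes present
#' in the window, in nats.
#'
#' @param composition An `lf_composition` with `total_valid > 0`.
#' @return A single non-negative number (nats), at most
#'   `log(number of parents present)`.
#' @export
entropy_global <- function(composition) {
  check_nonempty(composition)
  p <- composition$parent$p
  -sum(p * log(p))
}

#' Conditional entropy of subclasses given parent classes
#'
#' \eqn{H(Y|X) = -\sum_i p(x_i) \sum_j p(y_{ij}|x_i)\,\ln p(y_{ij}|x_i)},
#' in nats. Equals the sum over parents of [class_conditional_entropy()].
#'
#' @inheritParams entropy_global
#' @return A single non-negative number (nats).
#' @export
conditional_entropy <- function(composition) {
  check_nonempty(composition)
  sum(hprime_all(composition)$h_prime)
}

#' One parent's contribution to the conditional entropy
#'
#' \eqn{H_i' = -p(x_i) \sum_j p(y_{ij}|x_i)\,\ln p(y_{ij}|x_i)}: the
#' entropy of parent i's subclass mix, weighted by the parent's share of
#' the window. Zero when the parent has a single subclass present.
#'
#' @inheritParams entropy_global
#' @param parent A parent code present in the window.
#' @return A single number in `[0, p(x_i) * log(n_i)]` (nats).
#' @export
class_conditional_entropy <- function(composition, parent) {
  check_nonempty(composition)
  hp <- hprime_all(composition)
  i <- match(parent, hp$parent)
  if (is.na(i)) {
    lf_abort(sprintf("Parent %s not present in this window.", parent),
             "lookup")
  }
  hp$h_prime[i]
}

# H_i' for every parent present, vectorized over the child table.
hprime_all <- function(composition) {
  ch <- composition$child
  pa <- composition$parent
  n <- composition$total_valid
  # -(count_ij / N) * ln p(y_ij | x_i), summed within parent
  contrib <- -(ch$count / n) * log(ch$p_cond)
  agg <- tapply(contrib, factor(ch$parent, levels = pa$parent), sum)
  tibble(parent = pa$parent, h_prime = as.numeric(agg))
}

#' Conditional-entropy fusion weights
#'
#' The vertical-structure weight of each parent class present in the
#' window: \eqn{w_i = H_i' / \ln n_i}, the realized subclass entropy as a
#' fraction of its maximum. \eqn{w_i} is defined as 0 when \eqn{n_i = 1}
#' (no substructure, and the 0/0 limit of the formula).
#'
#' @inheritParams entropy_global
#' @param n_source Where the subclass count \eqn{n_i} comes from:
#'   `"window"` (default) counts subclasses of parent i present in this
#'   window; `"dataset"` counts subclasses present anywhere in the raster
#'   pair; `"scheme"` uses the number defined in the classification
#'   hierarchy.
#' @return A tibble of class `lf_weights` with one row per parent present:
#'   columns `parent`, `p` (parent share), `h_prime` (nats), `n_used`,
#'   and `w`.
#' @examples
#' h <- infer_hierarchy(c(11, 12, 21))
#' g2 <- lf_grid(matrix(c(rep(11L, 4), rep(12L, 4), rep(21L, 8)), 4, 4))
#' comp <- window_composition(pair_rasters(g2, hierarchy = h))
#' fusion_weights(comp)  # w = 0.5 for parent 1, 0 for parent 2
#' @export
fusion_weights <- function(composition, n_source = c("window", "dataset", "scheme")) {
  check_nonempty(composition)
  n_source <- match.arg(n_source)
  hp <- hprime_all(composition)
  ch <- composition$child
  n_window <- as.integer(table(factor(ch$parent, levels = hp$parent)))
  n_used <- switch(
    n_source,
    window = n_window,
    dataset = {
      if (is.null(composition$observed_n)) {
        lf_abort("Composition carries no dataset-level subclass counts.",
                 "usage")
      }
      as.integer(composition$observed_n[as.character(hp$parent)])
    },
    scheme = {
      key <- as.character(hp$parent)
      if (any(!key %in% names(composition$hierarchy$scheme_n))) {
        lf_abort("Parent missing from the hierarchy scheme.", "lookup")
      }
      as.integer(composition$hierarchy$scheme_n[key])
    }
  )
  w <- ifelse(n_used <= 1L, 0, hp$h_prime / log(n_used))
  out <- tibble(parent = hp$parent,
                p = composition$parent$p,
                h_prime = hp$h_prime,
                n_used = n_used, w = w)
  class(out) <- c("lf_weights", class(out))
  out
}

check_nonempty <- function(composition) {
  stopifnot(inherits(composition, "lf_composition"))
  if (composition$total_valid == 0L) {
    lf_abort("Composition has no valid cells; entropy is undefined.",
             "undefined_input")
  }
  invisible(composition)
}
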