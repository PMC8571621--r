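#' Build a two-grade class hierarchy from a child/parent mapping table
#'
#' A class hierarchy links every second-grade (child) land-cover code to
#' exactly one first-grade (parent) code. It is the vertical backbone of the
#' fusion method: the subclass sets \eqn{Y_i} and their scheme sizes
#' \eqn{n_i} come from here.
#'
#' @param mapping A data frame with integer columns `child` and `parent`
#'   (extra columns are ignored). Each row declares one child code and the
#'   parent it is subordinate to. Duplicated consistent rows are collapsed.
#' @return An object of class `lf_hierarchy`: a list with elements
#'   `parents` (sorted integer vector), `children` (sorted integer vector),
#'   `child_to_parent` (named integer vector keyed by child code),
#'   `subclass_sets` (list of integer vectors keyed by parent code), and
#'   `scheme_n` (named integer vector: children per parent in the scheme).
#' @examples
#' h <- class_hierarchy(data.frame(child = c(11, 12, 21), parent = c(1, 1, 2)))
#' parent_of(h, 12)
#' tidy(h)
#' @export
class_hierarchy <- function(mapping) {
  if (!is.data.frame(mapping)) {
    lf_abort("`mapping` must be a data frame with columns `child` and `parent`.",
             "usage")
  }
  if (!all(c("child", "parent") %in% names(mapping))) {
    lf_abort("`mapping` must have columns `child` and `parent`.", "usage")
  }
  mapping <- unique(mapping[, c("child", "parent")])
  if (nrow(mapping) == 0L) {
    lf_abort("Hierarchy mapping table is empty.", "empty_input")
  }
  child <- mapping$child
  parent <- mapping$parent
  if (any(child != round(child)) || any(parent != round(parent))) {
    lf_abort("Class codes must be integers.", "usage")
  }
  child <- as.integer(child)
  parent <- as.integer(parent)
  dup <- unique(child[duplicated(child)])
  if (length(dup) > 0L) {
    lf_abort(
      sprintf("Child code(s) %s mapped to more than one parent.",
              paste(dup, collapse = ", ")),
      "hierarchy_conflict"
    )
  }
  ord <- order(child)
  child <- child[ord]
  parent <- parent[ord]
  parents <- sort(unique(parent))
  subclass_sets <- split(child, factor(parent, levels = parents))
  names(subclass_sets) <- as.character(parents)
  structure(
    list(
      parents = parents,
      children = child,
      child_to_parent = setNames(parent, child),
      subclass_sets = subclass_sets,
      scheme_n = setNames(lengths(subclass_sets), as.character(parents))
    ),
    class = "lf_hierarchy"
  )
}

#' Infer a hierarchy from child codes by the decimal-prefix rule
#'
#' Many national land-cover schemes encode subordination numerically: child
#' code 23 belongs to parent 2. This convenience derives the mapping table
#' as `parent = child %/% 10` and delegates to [class_hierarchy()].
#'
#' @param child_codes Integer vector of second-grade codes, all `>= 10`.
#' @param rule Inference rule; only `"decimal"` is defined.
#' @return An `lf_hierarchy`.
#' @examples
#' infer_hierarchy(c(21, 22, 23, 24))
#' @export
infer_hierarchy <- function(child_codes, rule = "decimal") {
  rule <- match.arg(rule, "decimal")
  child_codes <- unique(as.integer(child_codes))
  if (length(child_codes) == 0L) {
    lf_abort("No child codes supplied.", "empty_input")
  }
  if (any(child_codes < 10L)) {
    lf_abort(
      sprintf("Decimal-prefix rule needs codes >= 10; got %s.",
              paste(child_codes[child_codes < 10L], collapse = ", ")),
      "rule_inapplicable"
    )
  }
  class_hierarchy(data.frame(child = child_codes,
                             parent = child_codes %/% 10L))
}

#' Look up the parent of one or more child codes
#'
#' @param hierarchy An `lf_hierarchy`.
#' @param child Integer vector of child codes.
#' @return Integer vector of parent codes, same length as `child`.
#' @export
parent_of <- function(hierarchy, child) {
  stopifnot(inherits(hierarchy, "lf_hierarchy"))
  key <- as.character(as.integer(child))
  missing <- !(key %in% names(hierarchy$child_to_parent))
  if (any(missing)) {
    lf_abort(
      sprintf("Unknown child code(s): %s.",
              paste(unique(child[missing]), collapse = ", ")),
      "lookup"
    )
  }
  unname(hierarchy$child_to_parent[key])
}

#' Read a hierarchy mapping from a two-column CSV
#'
#' Expects a header `child,parent`.
#'
#' @param path Path to a CSV file.
#' @return An `lf_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) {
    lf_abort(sprintf("Hierarchy file not found: %s", path), "io")
  }
  class_hierarchy(read.csv(path))
}

#' @export
print.lf_hierarchy <- function(x, ...) {
  cat(sprintf("<lf_hierarchy> %d parent classes, %d child classes\n",
              length(x$parents), length(x$children)))
  for (p in as.character(x$parents)) {
    cat(sprintf("  %s <- {%s}\n", p,
                paste(x$subclass_sets[[p]], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a class hierarchy back into its mapping table
#'
#' @param x An `lf_hierarchy`.
#' @param ... Unused.
#' @return A tibble with columns `child` and `parent`; round-trips through
#'   [class_hierarchy()].
#' @exportS3Method generics::tidy
tidy.lf_hierarchy <- function(x, ...) {
  tibble(child = x$children,
         parent = unname(x$child_to_parent[as.character(x$children)]))
}
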