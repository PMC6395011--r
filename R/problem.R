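# Alignment problems: two or more source trees plus cross-source RCC-5
# articulations and reasoning options.

#' Options controlling problem semantics
#'
#' @param enforce_sibling_disjointness If `TRUE` (default), children of the
#'   same parent are pairwise disjoint regions, so each tree partitions its
#'   parents. Switch off for non-tree classifications with overlapping
#'   sibling groups (substantially more expensive to reason over).
#' @param materialize_nc_regions If `TRUE` (default), every coverage-relaxed
#'   parent gains an explicit nonempty `nc_` residue child that participates
#'   in the MIR like any other concept. If `FALSE`, relaxation is modeled as
#'   a possibly-empty anonymous residue that is not a concept.
#' @return A list of class `rcc5_options`.
#' @export
rcc5_options <- function(enforce_sibling_disjointness = TRUE,
                         materialize_nc_regions = TRUE) {
  structure(
    list(
      enforce_sibling_disjointness = isTRUE(enforce_sibling_disjointness),
      materialize_nc_regions = isTRUE(materialize_nc_regions)
    ),
    class = "rcc5_options"
  )
}

#' Construct an alignment problem
#'
#' Bundles two or more source trees with a list of cross-source RCC-5
#' articulations. Articulations are given as a data frame with columns
#' `left`, `relation`, `right`, where `left`/`right` are source-qualified
#' labels (`"<tag>.<name>"`) from different trees and `relation` is a token
#' or disjunction accepted by [rcc5_relset()].
#'
#' @param trees List of [source_tree()] objects with distinct tags.
#' @param articulations Data frame (`left`, `relation`, `right`), or `NULL`.
#' @param options An [rcc5_options()] record.
#' @return An object of class `rcc5_problem`.
#' @export
#' @examples
#' t1 <- source_tree("A", data.frame(parent = "P", child = c("a", "b")))
#' t2 <- source_tree("B", data.frame(parent = "Q", child = c("x", "y")))
#' alignment_problem(list(t1, t2),
#'   data.frame(left = "A.P", relation = "==", right = "B.Q"))
alignment_problem <- function(trees, articulations = NULL,
                              options = rcc5_options()) {
  stopifnot(is.list(trees), length(trees) >= 2L)
  tags <- vapply(trees, function(t) t$tag, character(1))
  if (anyDuplicated(tags)) stop("source tags must be distinct", call. = FALSE)
  names(trees) <- tags
  if (options$materialize_nc_regions) {
    trees <- lapply(trees, materialize_nc)
  }
  arts <- normalize_articulations(articulations, trees)
  structure(
    list(trees = trees, articulations = arts, options = options),
    class = "rcc5_problem"
  )
}

normalize_articulations <- function(articulations, trees) {
  empty <- tibble::tibble(
    left_tag = character(0), left_name = character(0),
    relation = integer(0),
    right_tag = character(0), right_name = character(0)
  )
  if (is.null(articulations) || NROW(articulations) == 0L) return(empty)
  a <- as.data.frame(articulations, stringsAsFactors = FALSE)
  if (all(c("left", "relation", "right") %in% names(a))) {
    lv <- split_label(as.character(a$left))
    rv <- split_label(as.character(a$right))
    a <- data.frame(
      left_tag = lv$tag, left_name = lv$name,
      relation = as.character(a$relation),
      right_tag = rv$tag, right_name = rv$name,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("left_tag", "left_name", "relation", "right_tag", "right_name") %in% names(a)))
  rel <- if (is.numeric(a$relation)) {
    vapply(a$relation, function(r) as.integer(rcc5_relset(r)), integer(1))
  } else {
    vapply(as.character(a$relation), function(r) as.integer(rcc5_relset(r)), integer(1))
  }
  if (any(rel == 0L)) stop("articulation with empty relation set is unsatisfiable by construction", call. = FALSE)
  for (i in seq_len(nrow(a))) {
    lt <- a$left_tag[i]; rt <- a$right_tag[i]
    if (!lt %in% names(trees)) stop("unknown source tag in articulation: ", lt, call. = FALSE)
    if (!rt %in% names(trees)) stop("unknown source tag in articulation: ", rt, call. = FALSE)
    if (lt == rt) {
      stop("same-source articulation not allowed: ", lt, ".", a$left_name[i],
           " / ", rt, ".", a$right_name[i], call. = FALSE)
    }
    if (!a$left_name[i] %in% trees[[lt]]$concepts) {
      stop("articulation references unknown concept ", lt, ".", a$left_name[i], call. = FALSE)
    }
    if (!a$right_name[i] %in% trees[[rt]]$concepts) {
      stop("articulation references unknown concept ", rt, ".", a$right_name[i], call. = FALSE)
    }
  }
  tibble::tibble(
    left_tag = a$left_tag, left_name = a$left_name,
    relation = unname(rel),
    right_tag = a$right_tag, right_name = a$right_name
  )
}

#' @export
print.rcc5_problem <- function(x, ...) {
  tags <- names(x$trees)
  sizes <- vapply(x$trees, function(t) length(t$concepts), integer(1))
  cat("<rcc5 alignment problem>\n")
  cat("  trees: ", paste0(tags, " (", sizes, " concepts)", collapse = ", "), "\n", sep = "")
  cat("  articulations: ", nrow(x$articulations), "\n", sep = "")
  cat("  sibling disjointness: ", x$options$enforce_sibling_disjointness,
      "; materialize nc: ", x$options$materialize_nc_regions, "\n", sep = "")
  invisible(x)
}

#' Concept labels of a problem
#'
#' @param problem An `rcc5_problem`.
#' @return Tibble with columns `tag`, `name`, `label`, `is_nc_region`,
#'   `is_terminal`.
#' @export
problem_concepts <- function(problem) {
  purrr::map_dfr(problem$trees, function(tr) {
    tibble::tibble(
      tag = tr$tag,
      name = tr$concepts,
      label = paste0(tr$tag, ".", tr$concepts),
      is_nc_region = tr$concepts %in% tr$nc_concepts,
      is_terminal = !tr$concepts %in% names(tr$children)
    )
  })
}
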