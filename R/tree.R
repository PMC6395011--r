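# Source trees: one concept hierarchy per source (tag), assembled from
# parent/child (is_a) edges, with a per-parent coverage flag. Concepts are
# name tokens unique within the tree; the full label of a concept is
# "<tag>.<name>".

#' Construct a source concept tree
#'
#' A source tree is a rooted hierarchy of taxonomic/phylogenomic concepts
#' from a single source. Every parent with children carries a coverage
#' flag: under coverage the parent region equals the union of its children;
#' parents listed in `nocoverage` are relaxed and may extend beyond their
#' explicitly sampled children.
#'
#' @param tag Short source identifier, e.g. `"2015"` or `"Class2015"`.
#' @param edges Data frame with character columns `parent` and `child`, one
#'   row per is_a edge; may be `NULL` for a single-concept tree when `root`
#'   is given.
#' @param nocoverage Character vector of parent names whose coverage
#'   constraint is relaxed.
#' @param root Concept name for a tree consisting of a single (childless)
#'   concept; ignored when `edges` has rows.
#' @return An object of class `rcc5_tree`.
#' @export
#' @examples
#' source_tree("2015", data.frame(parent = c("P", "P"), child = c("a", "b")))
source_tree <- function(tag, edges, nocoverage = character(0), root = NULL) {
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  if (grepl("[^A-Za-z0-9_]", tag)) {
    stop("source tag must be a token of letters, digits and underscores", call. = FALSE)
  }
  if ((is.null(edges) || NROW(edges) == 0L)) {
    if (is.null(root)) stop("tree '", tag, "' has no concepts", call. = FALSE)
    if (length(nocoverage)) stop("nocoverage needs children", call. = FALSE)
    return(structure(
      list(tag = tag, root = root, concepts = root,
           parent_of = stats::setNames(character(0), character(0)),
           children = list(), covered = stats::setNames(logical(0), character(0)),
           nc_concepts = character(0)),
      class = "rcc5_tree"))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent", "child") %in% names(edges)))
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  bad <- grepl("[^A-Za-z0-9_]", c(parent, child))
  if (any(bad)) {
    stop("concept names must be tokens of letters, digits and underscores: ",
         paste(unique(c(parent, child)[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(child)) {
    dup <- unique(child[duplicated(child)])
    stop("concept has more than one parent in tree '", tag, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  concepts <- unique(c(parent, child))
  roots <- setdiff(parent, child)
  if (length(concepts) == 0L) stop("tree '", tag, "' has no concepts", call. = FALSE)
  if (length(roots) != 1L) {
    stop("tree '", tag, "' must have exactly one root, found: ",
         paste(sort(roots), collapse = ", "), call. = FALSE)
  }
  parent_of <- stats::setNames(parent, child)
  # cycle check: walk up from every concept
  for (cn in concepts) {
    seen <- character(0)
    cur <- cn
    while (!is.na(parent_of[cur])) {
      if (cur %in% seen) stop("cycle detected in tree '", tag, "' at ", cur, call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      if (!cur %in% concepts) break
    }
  }
  parents_with_children <- unique(parent)
  unknown_nc <- setdiff(nocoverage, parents_with_children)
  if (length(unknown_nc)) {
    stop("nocoverage names are not parents in tree '", tag, "': ",
         paste(unknown_nc, collapse = ", "), call. = FALSE)
  }
  covered <- stats::setNames(!(parents_with_children %in% nocoverage),
                             parents_with_children)
  children <- split(child, factor(parent, levels = parents_with_children))
  structure(
    list(
      tag = tag,
      root = roots,
      concepts = c(roots, child),      # root first, then insertion order
      parent_of = parent_of,
      children = children,
      covered = covered,
      nc_concepts = character(0)       # filled by materialize_nc()
    ),
    class = "rcc5_tree"
  )
}

#' @export
print.rcc5_tree <- function(x, ...) {
  cat("<rcc5 source tree> tag=", x$tag,
      " concepts=", length(x$concepts),
      " terminals=", length(tree_terminals(x)),
      " relaxed=", sum(!x$covered), "\n", sep = "")
  invisible(x)
}

tree_terminals <- function(tree) {
  setdiff(tree$concepts, names(tree$children))
}

tree_children <- function(tree, concept) {
  ch <- tree$children[[concept]]
  if (is.null(ch)) character(0) else ch
}

tree_ancestors <- function(tree, concept, include_self = FALSE) {
  out <- if (include_self) concept else character(0)
  cur <- concept
  while (!is.na(tree$parent_of[cur])) {
    cur <- tree$parent_of[[cur]]
    out <- c(out, cur)
  }
  out
}

tree_descendants <- function(tree, concept, include_self = TRUE) {
  out <- character(0)
  stack <- concept
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, cur)
    stack <- c(tree_children(tree, cur), stack)
  }
  if (include_self) out else setdiff(out, concept)
}

# Terminal concepts subtending a concept (the concept itself if terminal).
tree_terminal_descendants <- function(tree, concept) {
  desc <- tree_descendants(tree, concept)
  desc[!desc %in% names(tree$children)]
}

#' Materialize "no coverage" residue regions
#'
#' For every coverage-relaxed parent, adds an auxiliary child concept named
#' `nc_<parent>` standing for the residue region "parent minus the union of
#' its explicitly sampled children". The residue is an ordinary (nonempty)
#' concept: with it in place the parent is again exactly covered by its
#' children, which is how local relaxation lets differentially sampled
#' parents attain congruence.
#'
#' @param tree An `rcc5_tree`.
#' @return The tree with one `nc_` child added per relaxed parent.
#' @export
materialize_nc <- function(tree) {
  relaxed <- names(tree$covered)[!tree$covered]
  relaxed <- setdiff(relaxed, vapply(tree$nc_concepts, function(nc) {
    unname(tree$parent_of[nc])
  }, character(1)))
  for (p in relaxed) {
    nc <- paste0("nc_", p)
    if (nc %in% tree$concepts) {
      stop("cannot materialize residue region: concept '", nc,
           "' already exists in tree '", tree$tag, "'", call. = FALSE)
    }
    tree$children[[p]] <- c(tree$children[[p]], nc)
    tree$parent_of[nc] <- p
    tree$concepts <- c(tree$concepts, nc)
    tree$nc_concepts <- c(tree$nc_concepts, nc)
  }
  tree
}

full_labels <- function(tree) paste0(tree$tag, ".", tree$concepts)

split_label <- function(x) {
  dot <- regexpr(".", x, fixed = TRUE)
  if (any(dot < 0L)) stop("expected source-qualified label '<tag>.<name>': ",
                          paste(x[dot < 0L], collapse = ", "), call. = FALSE)
  list(tag = substr(x, 1L, dot - 1L),
       name = substr(x, dot + 1L, nchar(x)))
}
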