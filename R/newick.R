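# Newick ingestion and deterministic clade-label generation for unlabeled
# internal nodes.

#' Clade label generation policy
#'
#' Unlabeled internal nodes receive `"<nearest labeled ancestor>_Clade<k>"`.
#' Numbering starts at the most immediate unlabeled child of a labeled
#' node and proceeds depth-first through unlabeled descendants before
#' continuing with sibling sections; among unlabeled siblings the
#' next-lowest number goes to the sibling whose alphabetically first
#' labeled subtree name sorts first. Generated labels do not themselves
#' act as ancestors for further numbering (children of `X_Clade1` become
#' `X_Clade2`, not `X_Clade1_Clade1`).
#'
#' @param suffix_base Literal suffix stem, `"_Clade"`.
#' @param root_label Label given to an unlabeled root on ingestion.
#' @return A list of class `rcc5_label_policy`.
#' @export
clade_label_policy <- function(suffix_base = "_Clade", root_label = "Root") {
  structure(list(suffix_base = suffix_base, root_label = root_label,
                 traversal = "depth-first", sibling_order = "alphabetical-first-child"),
            class = "rcc5_label_policy")
}

#' Generate labels for unlabeled internal nodes
#'
#' @param tree A `phylo` tree; internal nodes with empty, missing, or
#'   purely numeric labels (support values) are considered unlabeled.
#' @param policy A [clade_label_policy()].
#' @return The tree with every internal node labeled; deterministic for a
#'   given topology and label set.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((a,b),c)r;")
#' generate_clade_labels(tr)$node.label
generate_clade_labels <- function(tree, policy = clade_label_policy()) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", nnode)
  labs[is.na(labs)] <- ""
  labs[grepl("^[0-9.]+$", labs)] <- ""   # support values are not names
  root <- ntip + 1L
  if (labs[root - ntip] == "") {
    stop("root must be labeled", call. = FALSE)
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  node_label <- function(nd) if (nd <= ntip) tree$tip.label[nd] else labs[nd - ntip]
  is_unlabeled <- function(nd) nd > ntip && labs[nd - ntip] == ""

  # alphabetically first original label in the subtree of nd
  subtree_key <- function(nd) {
    best <- NULL
    stack <- nd
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      lb <- node_label(cur)
      if (nzchar(lb)) best <- if (is.null(best)) lb else min(best, lb)
      ch <- kids[[as.character(cur)]]
      if (!is.null(ch)) stack <- c(stack, ch)
    }
    if (is.null(best)) "~" else best
  }

  existing <- c(tree$tip.label, labs[nzchar(labs)])
  labeled_nodes <- c(root, setdiff(which(nzchar(labs)) + ntip, root))
  # also labeled nodes discovered in order; process every originally
  # labeled internal node
  for (L in sort(labeled_nodes)) {
    base <- labs[L - ntip]
    counter <- 1L
    assign_next <- function(nd) {
      repeat {
        cand <- paste0(base, policy$suffix_base, counter)
        counter <<- counter + 1L
        if (!cand %in% existing) break
      }
      labs[nd - ntip] <<- cand
      existing <<- c(existing, cand)
    }
    walk <- function(nd) {
      ch <- kids[[as.character(nd)]]
      if (is.null(ch)) return(invisible(NULL))
      un <- ch[vapply(ch, is_unlabeled, logical(1))]
      if (!length(un)) return(invisible(NULL))
      un <- un[order(vapply(un, subtree_key, character(1)))]
      for (u in un) {
        assign_next(u)
        walk(u)   # depth-first within the unlabeled section
      }
      invisible(NULL)
    }
    walk(L)
  }
  tree$node.label <- labs
  tree
}

#' Ingest a rooted Newick tree as a source tree
#'
#' Reads a rooted Newick string (or file), labels unlabeled internal
#' nodes by the clade-label policy (an unlabeled root receives
#' `policy$root_label`), discards branch lengths and support values, and
#' assembles the parent/child concept hierarchy.
#'
#' @param newick Newick string (containing `";"`) or path to a file.
#' @param tag Source tag for the resulting tree.
#' @param policy A [clade_label_policy()].
#' @return An `rcc5_tree`.
#' @export
#' @examples
#' ingest_newick("((a,b)x,c)r;", tag = "2015")
ingest_newick <- function(newick, tag, policy = clade_label_policy()) {
  tr <- if (grepl(";", newick)) ape::read.tree(text = newick) else ape::read.tree(newick)
  if (is.null(tr)) stop("could not parse newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) stop("multi-root input: expected a single tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  ntip <- length(tr$tip.label)
  if (ntip < 2L) stop("tree needs at least two leaves", call. = FALSE)
  if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
  if (is.na(tr$node.label[1]) || tr$node.label[1] == "" ||
      grepl("^[0-9.]+$", tr$node.label[1])) {
    tr$node.label[1] <- policy$root_label
  }
  tr <- generate_clade_labels(tr, policy)
  node_name <- function(nd) if (nd <= ntip) tr$tip.label[nd] else tr$node.label[nd - ntip]
  edges <- data.frame(
    parent = vapply(tr$edge[, 1], node_name, character(1)),
    child = vapply(tr$edge[, 2], node_name, character(1)),
    stringsAsFactors = FALSE
  )
  source_tree(tag, edges)
}
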