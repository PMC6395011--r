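# Rooted-bipartition concordance/conflict annotation between two trees,
# in the style of supertree-synthesis conflict analysis: each internal
# edge of a rooted tree defines a bipartition S_in | S_out of the shared
# tip set, and edges of the primary tree are labeled concordant or
# conflicting against the alternative tree by subset containment vs
# reciprocal overlap of the tip sets.

strip_source_prefix <- function(x) sub("^[A-Za-z0-9_]+\\.", "", x)

#' Rooted bipartitions of a tree
#'
#' One entry per internal edge (edge subtending an internal node): the
#' ingroup is the set of descendant tips restricted to `shared_tips`, the
#' outgroup its complement within `shared_tips`. Edges whose restricted
#' ingroup is empty, a singleton, or the whole shared tip set carry no
#' grouping information and are marked uninformative.
#'
#' @param tree A rooted `phylo` tree (ape).
#' @param shared_tips Character vector of tip labels to restrict to;
#'   defaults to all tips.
#' @return Tibble with columns `node`, `label`, `s_in`, `s_out` (list
#'   columns), `informative`.
#' @export
bipartitions <- function(tree, shared_tips = NULL) {
  stopifnot(inherits(tree, "phylo"))
  # the basal node of the newick string is taken as the root; a basal
  # polytomy (which ape reports as unrooted) simply contributes no
  # informative edge of its own
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("duplicate tip labels", call. = FALSE)
  if (is.null(shared_tips)) shared_tips <- tips
  shared_tips <- intersect(tips, shared_tips)
  if (!length(shared_tips)) stop("no shared tips", call. = FALSE)
  ntip <- length(tips)
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  desc <- lapply(internal, function(nd) {
    tips[intersect(phangorn_descendants(tree, nd), seq_len(ntip))]
  })
  s_in <- lapply(desc, intersect, y = shared_tips)
  s_out <- lapply(s_in, function(si) setdiff(shared_tips, si))
  lab <- if (!is.null(tree$node.label)) {
    tree$node.label[internal - ntip]
  } else rep(NA_character_, length(internal))
  tibble::tibble(
    node = internal,
    label = lab,
    s_in = s_in,
    s_out = s_out,
    informative = vapply(s_in, length, integer(1)) >= 2L &
      vapply(s_out, length, integer(1)) >= 1L
  )
}

# tips + internal nodes below a node (iterative, no extra deps)
phangorn_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    out <- c(out, cur)
    ch <- kids[[as.character(cur)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

#' Annotate edge concordance/conflict between two rooted trees
#'
#' For every informative internal edge of `primary`, compares its rooted
#' bipartition (restricted to the shared tips) with every informative
#' edge of `alternative`: the edge is concordant with an alternative edge
#' whose ingroup and outgroup are both contained in its own (identical
#' restricted bipartitions count as concordant), and conflicting with an
#' alternative edge with which it has reciprocal overlap (ingroup level
#' intersection plus crossing intersections all nonempty). An edge may be
#' concordant with one alternative edge and conflicting with another; both
#' flags are reported, and the summary `status` lets conflict take
#' precedence.
#'
#' Tip names are matched by exact string equality after stripping a
#' source prefix (`"2014."` etc.). Optionally, tips of `primary` missing
#' from `alternative` are grafted into the alternative below their
#' nearest containing named ancestor found in `taxonomy` (off by
#' default): this mimics taxonomy-based placement of unsampled tips and
#' typically induces the inconsistencies it is meant to illustrate.
#'
#' @param primary,alternative Rooted `phylo` trees.
#' @param taxonomy Optional rooted `phylo` tree with named internal nodes
#'   used for grafting.
#' @param graft Graft unmatched primary tips into the alternative via
#'   `taxonomy`.
#' @return Tibble: `node`, `label`, `concordant`, `conflicting`, `status`
#'   (`"concordant"`, `"conflicting"` or `"neither"`).
#' @export
annotate_conflict <- function(primary, alternative, taxonomy = NULL,
                              graft = FALSE) {
  p <- primary; a <- alternative
  p$tip.label <- strip_source_prefix(p$tip.label)
  a$tip.label <- strip_source_prefix(a$tip.label)
  if (graft) {
    if (is.null(taxonomy)) stop("grafting requires a taxonomy tree", call. = FALSE)
    a <- graft_tips(a, setdiff(p$tip.label, a$tip.label), taxonomy)
  }
  shared <- intersect(p$tip.label, a$tip.label)
  if (!length(shared)) stop("no shared tips", call. = FALSE)
  bp <- bipartitions(p, shared)
  ba <- bipartitions(a, shared)
  ba <- ba[ba$informative, , drop = FALSE]

  conc <- logical(nrow(bp)); conf <- logical(nrow(bp))
  for (i in seq_len(nrow(bp))) {
    if (!bp$informative[i]) next
    A_in <- bp$s_in[[i]]; A_out <- bp$s_out[[i]]
    for (j in seq_len(nrow(ba))) {
      B_in <- ba$s_in[[j]]; B_out <- ba$s_out[[j]]
      if (all(B_in %in% A_in) && all(B_out %in% A_out)) conc[i] <- TRUE
      else if (length(intersect(A_in, B_in)) && length(intersect(A_in, B_out)) &&
               length(intersect(B_in, A_out))) conf[i] <- TRUE
      if (conc[i] && conf[i]) break
    }
  }
  tibble::tibble(
    node = bp$node, label = bp$label,
    informative = bp$informative,
    concordant = conc, conflicting = conf,
    status = ifelse(!bp$informative, "neither",
             ifelse(conf, "conflicting",
             ifelse(conc, "concordant", "neither")))
  )
}

# attach each unmatched tip as a child of its nearest named taxonomy
# ancestor that names an internal node (or tip) of the target tree
graft_tips <- function(target, tips, taxonomy) {
  tax_tips <- strip_source_prefix(taxonomy$tip.label)
  tax_nodes <- strip_source_prefix(
    if (is.null(taxonomy$node.label)) character(0) else taxonomy$node.label)
  for (tp in tips) {
    pos <- match(tp, tax_tips)
    if (is.na(pos)) next
    # walk up taxonomy ancestors
    cur <- pos
    attach_label <- NA_character_
    repeat {
      anc <- taxonomy$edge[taxonomy$edge[, 2] == cur, 1]
      if (!length(anc)) break
      lab <- tax_nodes[anc - length(taxonomy$tip.label)]
      if (!is.na(lab) && nzchar(lab) &&
          lab %in% c(target$node.label, target$tip.label)) {
        attach_label <- lab
        break
      }
      cur <- anc
    }
    if (is.na(attach_label)) next
    target <- bind_tip_at(target, tp, attach_label)
  }
  target
}

# minimal tip-binding (as a new child of the node carrying `label`)
bind_tip_at <- function(tree, tip, label) {
  ntip <- length(tree$tip.label)
  node <- if (label %in% tree$tip.label) {
    match(label, tree$tip.label)
  } else {
    ntip + match(label, tree$node.label)
  }
  if (node <= ntip) {
    # attaching below a tip: make the tip an internal node with two children
    txt <- sprintf("(%s,%s)%s;", label, tip, paste0(label, "_grafted"))
    sub <- ape::read.tree(text = txt)
    return(bind_replace_tip(tree, label, sub))
  }
  # easiest robust route is newick surgery: insert ",tip" just before the
  # closing parenthesis of the labeled clade (ape writes the label
  # immediately after it)
  nw <- ape::write.tree(tree)
  pat <- paste0(")", label)
  hit <- regexpr(pat, nw, fixed = TRUE)
  if (hit < 0) return(tree)
  nw2 <- paste0(substr(nw, 1, hit - 1), ",", tip, substr(nw, hit, nchar(nw)))
  ape::read.tree(text = nw2)
}

bind_replace_tip <- function(tree, tip, subtree) {
  nw <- ape::write.tree(tree)
  sw <- sub(";\\s*$", "", ape::write.tree(subtree))
  nw2 <- sub(paste0("(?<![A-Za-z0-9_])", tip, "(?![A-Za-z0-9_])"), sw, nw, perl = TRUE)
  ape::read.tree(text = nw2)
}

#' Compare bipartition conflict annotation with RCC-5 overlaps
#'
#' Cross-checks the edge-based concordance/conflict labels against the
#' MIR: a concept whose MIR entries contain an exact overlap should map
#' to a conflicting edge. Mapped concepts where the two methods disagree
#' are reported: `false_positive` = MIR overlap not recovered as edge
#' conflict; `false_negative` = edge conflict where the MIR shows no
#' overlap (e.g. a congruent refinement penalized for differential
#' sampling).
#'
#' @param annotations Output of [annotate_conflict()].
#' @param mir MIR tibble.
#' @param concept_edge_map Named character vector: source-qualified
#'   concept label -> edge label in `annotations`.
#' @return Tibble: `concept`, `edge_label`, `edge_status`, `mir_overlap`,
#'   `category` (`"agree"`, `"false_positive"`, `"false_negative"`).
#' @export
compare_with_rcc5 <- function(annotations, mir, concept_edge_map) {
  ov_concepts <- unique(c(mir$left[mir$mask == REL_OV], mir$right[mir$mask == REL_OV]))
  out <- list()
  for (concept in names(concept_edge_map)) {
    lab <- concept_edge_map[[concept]]
    row <- match(lab, annotations$label)
    if (is.na(row)) {
      warning("edge label not found, skipped: ", lab, call. = FALSE)
      next
    }
    st <- annotations$status[row]
    has_ov <- concept %in% ov_concepts
    category <- if (has_ov && st != "conflicting") "false_positive"
    else if (!has_ov && st == "conflicting") "false_negative"
    else "agree"
    out[[length(out) + 1L]] <- tibble::tibble(
      concept = concept, edge_label = lab, edge_status = st,
      mir_overlap = has_ov, category = category
    )
  }
  if (!length(out)) {
    return(tibble::tibble(concept = character(0), edge_label = character(0),
                          edge_status = character(0), mir_overlap = logical(0),
                          category = character(0)))
  }
  dplyr::bind_rows(out)
}
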