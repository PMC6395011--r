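# Independent brute-force oracles used to validate the reasoner and the
# frozen relation algebra. These deliberately avoid the package's atom
# encoding: regions are explicit bitmask subsets of a small universe and
# every constraint is evaluated directly.

oracle_base_relation <- function(a, b) {
  # a, b: nonzero integer bitmasks
  inter <- bitwAnd(a, b)
  if (a == b) "=="
  else if (inter == b) ">"
  else if (inter == a) "<"
  else if (inter == 0L) "!"
  else "><"
}

# Recompute the RCC-5 composition table by brute force over all triples
# of nonempty subsets of a u-point universe.
oracle_compose_table <- function(u = 6L) {
  subsets <- seq_len(2^u - 1L)
  m <- length(subsets)
  R <- matrix("", m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) R[i, j] <- oracle_base_relation(subsets[i], subsets[j])
  }
  rels <- c("==", ">", "<", "><", "!")
  out <- list()
  for (r1 in rels) {
    for (r2 in rels) {
      acc <- character(0)
      for (j in seq_len(m)) {
        is1 <- which(R[, j] == r1)
        if (!length(is1)) next
        ks <- which(R[j, ] == r2)
        if (!length(ks)) next
        acc <- union(acc, unique(as.vector(R[is1, ks, drop = FALSE])))
        if (length(acc) == 5L) break
      }
      out[[paste(r1, r2)]] <- sort(acc)
    }
  }
  out
}

# Direct witness-assignment oracle: enumerate every assignment of a
# nonempty subset of a u-point universe to every concept, keep the
# assignments satisfying all constraints, and report consistency, the
# distinct world signatures, and the realized cross-source relations.
# Only feasible for a handful of concepts.
oracle_direct <- function(problem, u = 3L) {
  info <- problem_concepts(problem)
  labs <- info$label
  n <- length(labs)
  subsets <- seq_len(2^u - 1L)
  stopifnot(length(subsets)^n <= 2e6)
  grid <- do.call(expand.grid, c(rep(list(subsets), n), list(KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- labs
  keep <- rep(TRUE, nrow(grid))

  for (tr in problem$trees) {
    lab <- function(nm) paste0(tr$tag, ".", nm)
    for (p in names(tr$children)) {
      ch <- tr$children[[p]]
      pv <- grid[[lab(p)]]
      for (cn in ch) {
        cv <- grid[[lab(cn)]]
        keep <- keep & bitwAnd(cv, pv) == cv
      }
      if (problem$options$enforce_sibling_disjointness && length(ch) > 1L) {
        for (i in seq_len(length(ch) - 1L)) {
          for (j in seq(i + 1L, length(ch))) {
            keep <- keep & bitwAnd(grid[[lab(ch[i])]], grid[[lab(ch[j])]]) == 0L
          }
        }
      }
      covered <- tr$covered[[p]] || any(ch %in% tr$nc_concepts)
      uni <- Reduce(bitwOr, lapply(ch, function(cn) grid[[lab(cn)]]), 0L)
      if (covered) keep <- keep & uni == pv
    }
  }
  a <- problem$articulations
  if (nrow(a)) {
    for (k in seq_len(nrow(a))) {
      lv <- grid[[paste0(a$left_tag[k], ".", a$left_name[k])]]
      rv <- grid[[paste0(a$right_tag[k], ".", a$right_name[k])]]
      inter <- bitwAnd(lv, rv)
      bit <- ifelse(lv == rv, 1L,
             ifelse(inter == rv, 2L,
             ifelse(inter == lv, 4L,
             ifelse(inter == 0L, 16L, 8L))))
      keep <- keep & bitwAnd(bit, a$relation[k]) != 0L
    }
  }
  sub <- grid[keep, , drop = FALSE]
  pairs <- expand.grid(l = seq_len(n), r = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  sig <- apply(sub, 1, function(row) {
    paste(mapply(function(i, j) oracle_base_relation(row[[i]], row[[j]]),
                 pairs$l, pairs$r), collapse = "")
  })
  list(consistent = nrow(sub) > 0L, n_assignments = nrow(sub),
       n_worlds = length(unique(sig)), assignments = sub)
}

oracle_mir_masks <- function(problem, u = 3L) {
  orc <- oracle_direct(problem, u)
  t1 <- problem$trees[[1]]; t2 <- problem$trees[[2]]
  pairs <- expand.grid(left = paste0(t1$tag, ".", t1$concepts),
                       right = paste0(t2$tag, ".", t2$concepts),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bits <- c(`==` = 1L, `>` = 2L, `<` = 4L, `><` = 8L, `!` = 16L)
  masks <- integer(nrow(pairs))
  if (nrow(orc$assignments)) {
    for (k in seq_len(nrow(pairs))) {
      lv <- orc$assignments[[pairs$left[k]]]
      rv <- orc$assignments[[pairs$right[k]]]
      rels <- unique(mapply(oracle_base_relation, lv, rv))
      masks[k] <- sum(bits[rels])
    }
  }
  pairs$mask <- masks
  pairs
}

# small helpers shared by tests
toy_two_trees <- function(rel = NULL) {
  t1 <- source_tree("A", data.frame(parent = "P", child = c("a", "b")))
  t2 <- source_tree("B", data.frame(parent = "Q", child = c("x", "y")))
  arts <- if (is.null(rel)) NULL else data.frame(left = "A.P", relation = rel, right = "B.Q")
  alignment_problem(list(t1, t2), arts)
}

one_concept_pair <- function(rel = NULL) {
  u1 <- source_tree("A", NULL, root = "r1")
  u2 <- source_tree("B", NULL, root = "r2")
  arts <- if (is.null(rel)) NULL else data.frame(left = "A.r1", relation = rel, right = "B.r2")
  alignment_problem(list(u1, u2), arts)
}

mir_entry <- function(mir, left, right) {
  mir$relation[mir$left == left & mir$right == right]
}
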