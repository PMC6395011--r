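# Rooted-bipartition concordance/conflict comparison between trees.

test_that("bipartitions expose ingroup/outgroup tip sets per internal edge", {
  tr <- ape::read.tree(text = "((a,b),c);")
  bp <- bipartitions(tr)
  inner <- bp[vapply(bp$s_in, length, integer(1)) == 2L, ]
  expect_identical(nrow(inner), 1L)
  expect_setequal(inner$s_in[[1]], c("a", "b"))
  expect_setequal(inner$s_out[[1]], "c")
  expect_true(inner$informative)

  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_identical(nrow(bipartitions(star)), 0L)
})

test_that("bipartitions commute with tip-set restriction", {
  set.seed(31)
  for (k in 1:3) {
    tr <- ape::rtree(12)
    shared <- sample(tr$tip.label, 8)
    direct <- bipartitions(tr, shared)
    full <- bipartitions(tr)
    for (i in seq_len(nrow(full))) {
      expect_setequal(direct$s_in[[i]], intersect(full$s_in[[i]], shared))
      expect_setequal(direct$s_out[[i]], setdiff(shared, full$s_in[[i]]))
    }
  }
})

test_that("identical bipartitions are concordant, crossing ones conflict", {
  a <- ape::read.tree(text = "((a,b),(c,d));")
  same <- annotate_conflict(a, ape::read.tree(text = "((a,b),(c,d));"))
  expect_true(all(same$status[same$informative] == "concordant"))
  crossed <- annotate_conflict(a, ape::read.tree(text = "((b,c),(a,d));"))
  expect_true(all(crossed$status[crossed$informative] == "conflicting"))
  # an edge is never both concordant and conflicting with the same
  # alternative edge: against a single-edge alternative the flags are
  # mutually exclusive
  alt <- ape::read.tree(text = "((a,b),c,d);")
  ann <- annotate_conflict(a, alt)
  expect_false(any(ann$concordant & ann$conflicting))
})

test_that("conflict annotation is invariant under tip relabeling", {
  set.seed(7)
  t1 <- ape::rtree(8); t2 <- ape::rtree(8)
  t2$tip.label <- sample(t1$tip.label)
  base <- annotate_conflict(t1, t2)
  perm <- stats::setNames(paste0("sp", 1:8), t1$tip.label)
  r1 <- t1; r1$tip.label <- unname(perm[t1$tip.label])
  r2 <- t2; r2$tip.label <- unname(perm[t2$tip.label])
  expect_identical(annotate_conflict(r1, r2)$status, base$status)
})

test_that("source prefixes are stripped before matching tips", {
  a <- ape::read.tree(text = "((X2015.a,X2015.b),(X2015.c,X2015.d));")
  b <- ape::read.tree(text = "((X2014.a,X2014.b),(X2014.c,X2014.d));")
  ann <- annotate_conflict(a, b)
  expect_true(all(ann$status[ann$informative] == "concordant"))
})

test_that("taxonomy grafting of unsampled tips can manufacture conflict", {
  # dense primary; sparse alternative lacking tip b
  primary <- ape::read.tree(text = "((a,b)ab,(c,d)cd)r;")
  alternative <- ape::read.tree(text = "((a,c)ac,d)r;")
  taxonomy <- ape::read.tree(text = "((a,b)ab,(c,d)cd)r;")
  plain <- annotate_conflict(primary, alternative)
  # without b the primary's (a,b) edge carries no grouping information
  expect_identical(plain$status[plain$label == "ab"], "neither")
  grafted <- annotate_conflict(primary, alternative, taxonomy = taxonomy,
                               graft = TRUE)
  # grafted high (taxonomy's 'ab' is absent from the alternative, so b
  # attaches at the root), the same edge now reads as conflicting
  expect_identical(grafted$status[grafted$label == "ab"], "conflicting")
})

test_that("edge annotations can be reconciled against the MIR", {
  # congruent toy pair: empty discrepancy report
  a <- ape::read.tree(text = "((a,b)x,(c,d)y)r;")
  b <- ape::read.tree(text = "((a,b)x,(c,d)y)r;")
  ann <- annotate_conflict(a, b)
  term <- c("a", "b", "c", "d")
  ta <- source_tree("A", data.frame(parent = c("r", "r", "x", "x", "y", "y"),
                                    child = c("x", "y", term)))
  tb <- source_tree("B", data.frame(parent = c("r", "r", "x", "x", "y", "y"),
                                    child = c("x", "y", term)))
  p <- alignment_problem(list(ta, tb),
                         data.frame(left = paste0("A.", term), relation = "==",
                                    right = paste0("B.", term)))
  mir <- infer_mir(p)
  rep0 <- compare_with_rcc5(ann, mir, c(A.x = "x", A.y = "y"))
  expect_true(all(rep0$category == "agree"))

  # differential sampling plus taxonomy grafting: the dense tree's edge x
  # is flagged conflicting, although the RCC-5 alignment resolves it as a
  # congruent refinement of the sparse root (false negative)
  dense <- ape::read.tree(text = "((a,(b,e)x2)x,(c,d)y)r;")
  sparse <- ape::read.tree(text = "(a,(c,d)q)r;")
  taxo <- ape::read.tree(text = "((a,b)p,(c,d,e)q)r;")
  ann2 <- annotate_conflict(dense, sparse, taxonomy = taxo, graft = TRUE)
  expect_identical(ann2$status[ann2$label == "x"], "conflicting")
  td <- source_tree("A", data.frame(
    parent = c("r", "r", "x", "x", "x2", "x2", "y", "y"),
    child = c("x", "y", "a", "x2", "b", "e", "c", "d")))
  ts <- source_tree("B", data.frame(parent = c("r", "r", "q", "q"),
                                    child = c("a", "q", "c", "d")),
                    nocoverage = "r")
  arts <- data.frame(left = paste0("A.", c("a", "c", "d")), relation = "==",
                     right = paste0("B.", c("a", "c", "d")))
  arts <- rbind(arts,
                data.frame(left = c("A.b", "A.e"), relation = "<", right = "B.r"))
  p2 <- alignment_problem(list(td, ts), arts)
  mir2 <- infer_mir(p2)
  expect_identical(mir_entry(mir2, "A.x", "B.r"), "<")
  rep2 <- compare_with_rcc5(ann2, mir2, c(A.x = "x"))
  expect_identical(rep2$category, "false_negative")

  # a genuine overlap is recovered by both methods
  a3 <- ape::read.tree(text = "(((a,b)ab,c)abc,d)r;")
  b3 <- ape::read.tree(text = "(((b,c)bc,a)bca,d)r;")
  ann3 <- annotate_conflict(a3, b3)
  expect_identical(ann3$status[ann3$label == "ab"], "conflicting")
  ta3 <- source_tree("A", data.frame(parent = c("r", "r", "abc", "abc", "ab", "ab"),
                                     child = c("abc", "d", "ab", "c", "a", "b")))
  tb3 <- source_tree("B", data.frame(parent = c("r", "r", "bca", "bca", "bc", "bc"),
                                     child = c("bca", "d", "bc", "a", "b", "c")))
  arts3 <- data.frame(left = paste0("A.", c("a", "b", "c", "d")), relation = "==",
                      right = paste0("B.", c("a", "b", "c", "d")))
  mir3 <- infer_mir(alignment_problem(list(ta3, tb3), arts3))
  expect_identical(mir_entry(mir3, "A.ab", "B.bc"), "><")
  rep3 <- compare_with_rcc5(ann3, mir3, c(A.ab = "ab"))
  expect_identical(rep3$category, "agree")
})
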