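# Region graphs and whole- vs split-concept resolution of overlaps.

zoom_alignment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- align_concepts(fixture_neoaves_zoom())
    cache
  }
})

test_that("congruent-only alignments produce no split regions", {
  p <- toy_two_trees("==")
  al <- align_concepts(p)
  rs <- build_regions(p, al$mir, al$consistency$witness, resolution = "split")
  expect_identical(sum(rs$regions$kind == "split_product"), 0L)
  cen <- split_label_census(al$mir, rs)
  expect_identical(cen$total_labels, 0L)
})

test_that("split products of every overlapping pair partition the pair's union", {
  for (seed in c(4, 12, 18)) {
    g <- generate_problem(seed, n_left = 11, n_right = 9, overlap_rate = 0.8)
    al <- align_concepts(g$problem)
    ov <- al$mir[al$mir$mask == rcc5align:::REL_OV, ]
    w <- al$consistency$witness$extension
    if (!nrow(ov)) next
    for (i in seq_len(nrow(ov))) {
      ea <- w[[ov$left[i]]]; eb <- w[[ov$right[i]]]
      parts <- list(intersect(ea, eb), setdiff(ea, eb), setdiff(eb, ea))
      expect_true(all(lengths(parts) > 0L))
      expect_setequal(unlist(parts), union(ea, eb))
      expect_identical(sum(lengths(parts)), length(union(ea, eb)))
    }
  }
})

test_that("region inclusion edges are acyclic and transitively reduced", {
  al <- zoom_alignment()
  rg <- build_regions(al$problem, al$mir, al$consistency$witness, "whole")
  inc <- rg$edges[rg$edges$type == "inclusion", ]
  n <- nrow(rg$regions)
  adj <- matrix(FALSE, n, n)
  adj[cbind(inc$from, inc$to)] <- TRUE
  # acyclic: repeated squaring never puts TRUE on the diagonal
  reach <- adj
  for (k in seq_len(ceiling(log2(n)) + 1L)) {
    reach <- reach | (reach %*% reach) > 0
  }
  expect_false(any(diag(reach)))
  # reduced: no edge is implied by a two-step path
  for (e in seq_len(nrow(inc))) {
    expect_false(any(adj[inc$from[e], ] & adj[, inc$to[e]]))
  }
})

test_that("whole- and split-resolution graphs share their congruent clusters", {
  al <- zoom_alignment()
  rw <- build_regions(al$problem, al$mir, al$consistency$witness, "whole")
  rs <- build_regions(al$problem, al$mir, al$consistency$witness, "split")
  key <- function(r) sort(vapply(r$regions$labels[r$regions$kind == "congruent"],
                                 function(ls) paste(sort(ls), collapse = "|"),
                                 character(1)))
  expect_identical(key(rw), key(rs))
})

test_that("the conflict-region fixture yields the published split census", {
  al <- zoom_alignment()
  rs <- build_regions(al$problem, al$mir, al$consistency$witness, "split")
  cen <- split_label_census(al$mir, rs)
  expect_identical(cen$total_labels, 78L)
  expect_identical(cen$synonym_labels, 57L)
  expect_identical(cen$novel_regions, 15L)
  expect_identical(cen$novel_unique, 11L)
  expect_identical(cen$novel_redundant, 4L)
  expect_identical(cen$novel_labels, 21L)
  # overlap edges only under whole-concept resolution
  rw <- build_regions(al$problem, al$mir, al$consistency$witness, "whole")
  expect_identical(sum(rw$edges$type == "overlap"), 26L)
  expect_identical(sum(rs$edges$type == "overlap"), 0L)
})

test_that("congruent region clusters count maximal EQ-connected groups", {
  # all-exclusive strict alignment: none
  expect_identical(count_congruent_regions(infer_mir(fixture_psittaciformes("strict"))), 0L)
  # relaxed alignment: the order- and family-level pairs coincide
  # extensionally (single-child chains), leaving two maximal clusters
  expect_identical(count_congruent_regions(infer_mir(fixture_psittaciformes("relaxed"))), 2L)
  expect_identical(count_congruent_regions(zoom_alignment()$mir), 13L)
  # self-alignment of a relabeled copy: one cluster per concept
  g <- generate_problem(3, n_left = 7, n_right = 7, overlap_rate = 0)
  t1 <- g$problem$trees[[1]]
  t2 <- t1; t2$tag <- "C"
  term <- rcc5align:::tree_terminals(t1)
  arts <- data.frame(left = paste0("L.", term), relation = "==",
                     right = paste0("C.", term))
  p <- alignment_problem(list(t1, t2), arts)
  mir <- infer_mir(p)
  expect_identical(count_congruent_regions(mir), length(t1$concepts))
})

test_that("an overlap whose products match input regions needs no new labels", {
  # the single overlap between the two land-bird subclades: the shared
  # product region is the congruent Coracornithia pair, and the two
  # one-parent products are the Australaves and Accipitri- pairs, so
  # split-concept resolution is wholly redundant here
  t15 <- source_tree("2015", data.frame(
    parent = c("Telluraves", "Telluraves", "Eutelluraves", "Eutelluraves"),
    child = c("Accipitriformes", "Eutelluraves", "Australaves", "Coracornithia")))
  t14 <- source_tree("2014", data.frame(
    parent = c("Telluraves", "Telluraves", "Afroaves", "Afroaves"),
    child = c("Afroaves", "Australaves", "Accipitrimorphae", "Coracornithia")))
  arts <- data.frame(
    left = paste0("2015.", c("Accipitriformes", "Australaves", "Coracornithia",
                             "Accipitriformes", "Accipitriformes", "Australaves",
                             "Australaves", "Coracornithia", "Coracornithia")),
    relation = c("==", "==", "==", "!", "!", "!", "!", "!", "!"),
    right = paste0("2014.", c("Accipitrimorphae", "Australaves", "Coracornithia",
                              "Australaves", "Coracornithia", "Accipitrimorphae",
                              "Coracornithia", "Accipitrimorphae", "Australaves")))
  p <- alignment_problem(list(t15, t14), arts)
  al <- align_concepts(p)
  expect_identical(mir_entry(al$mir, "2015.Eutelluraves", "2014.Afroaves"), "><")
  expect_identical(sum(al$mir$mask == rcc5align:::REL_OV), 1L)
  rs <- build_regions(p, al$mir, al$consistency$witness, "split")
  cen <- split_label_census(al$mir, rs)
  expect_identical(cen$total_labels, 3L)
  expect_identical(cen$novel_regions, 0L)
  expect_identical(cen$synonym_labels, 3L)
  w <- al$consistency$witness$extension
  expect_setequal(intersect(w[["2015.Eutelluraves"]], w[["2014.Afroaves"]]),
                  w[["2015.Coracornithia"]])
  expect_setequal(setdiff(w[["2015.Eutelluraves"]], w[["2014.Afroaves"]]),
                  w[["2015.Australaves"]])
  expect_setequal(setdiff(w[["2014.Afroaves"]], w[["2015.Eutelluraves"]]),
                  w[["2014.Accipitrimorphae"]])
})
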