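# Parsing/serialization of the problem dialect, Newick ingestion, clade
# label generation, and the deterministic writers.

test_that("minimal problems parse and materialize nc regions", {
  p <- parse_problem(c(
    "# two tiny taxonomies",
    "taxonomy 2015",
    "(P a b)",
    "taxonomy 2014",
    "(Q x y)",
    "articulation 2015-2014",
    "[2015.P == 2014.Q]"))
  expect_s3_class(p, "rcc5_problem")
  expect_identical(nrow(p$articulations), 1L)
  expect_setequal(p$trees[["2015"]]$concepts, c("P", "a", "b"))

  p2 <- parse_problem(c(
    "taxonomy 2014",
    "(Psittaciformes Psittacidae)",
    "(Psittacidae s1 s2)",
    "nocoverage Psittacidae",
    "taxonomy 2015",
    "(P a)"))
  tr <- p2$trees[["2014"]]
  expect_true("nc_Psittacidae" %in% tr$concepts)
  expect_identical(unname(tr$parent_of["nc_Psittacidae"]), "Psittacidae")
  expect_true("nc_Psittacidae" %in% tr$nc_concepts)
  # without materialization the residue concept is not created
  p3 <- parse_problem(c(
    "taxonomy 2014",
    "(Psittaciformes Psittacidae)",
    "(Psittacidae s1 s2)",
    "nocoverage Psittacidae",
    "taxonomy 2015",
    "(P a)"), options = rcc5_options(materialize_nc_regions = FALSE))
  expect_false("nc_Psittacidae" %in% p3$trees[["2014"]]$concepts)
})

test_that("parse errors carry line numbers", {
  base <- c("taxonomy A", "(P a b)", "taxonomy B", "(Q x y)")
  expect_error(parse_problem(c(base, "(P")), "line 5.*unterminated")
  expect_error(parse_problem(c("taxonomy A", "(P a b)", "(R a c)", "taxonomy B", "(Q x)")),
               "more than one parent")
  expect_error(parse_problem(c(base, "articulation A-B", "[A.P ~~ B.Q]")),
               "line 6")
  expect_error(parse_problem(c(base, "articulation A-B", "[A.P == B.zz]")),
               "unknown concept")
  expect_error(parse_problem(c(base, "articulation A-A", "[A.P == A.a]")),
               "same-source")
  expect_error(parse_problem(c("nocoverage P", base)), "outside a taxonomy block")
  expect_error(parse_problem(c(base, "nocoverage zz")), "not parents")
})

test_that("serialize/parse round-trips are order-normalized identities", {
  fixtures <- list(
    fixture_psittaciformes("strict"),
    fixture_psittaciformes("relaxed"),
    fixture_neoaves_zoom()
  )
  for (p in fixtures) {
    expect_true(rcc5align:::problem_equal(p, parse_problem(serialize_problem(p))))
  }
  for (seed in 1:5) {
    g <- generate_problem(seed, n_left = 11, n_right = 7, nc_left = 1,
                          overlap_rate = 0.5)
    expect_true(rcc5align:::problem_equal(g$problem,
                                          parse_problem(serialize_problem(g$problem))))
  }
})

test_that("clade labels follow the depth-first, alphabetical-sibling policy", {
  # two unlabeled siblings: the one whose subtree contains the
  # alphabetically first name gets the lower number
  tr <- ape::read.tree(text = "((((Aequornithia,Phaethontimorphae)Ardeae,Telluraves),(Cursorimorphae,Opisthocomiformes)),(Caprimulgimorphae,Otidimorphae))Passerea;")
  labs <- generate_clade_labels(tr)$node.label
  expect_identical(labs[1], "Passerea")
  # the child subtree holding Ardeae outranks the Cursorimorphae side
  get_children_labels <- function(t, lab) {
    nd <- which(c(t$tip.label, t$node.label) == lab)
    ch <- t$edge[t$edge[, 1] == nd, 2]
    vapply(ch, function(x) c(t$tip.label, t$node.label)[x], character(1))
  }
  out <- tr; out$node.label <- labs
  expect_setequal(get_children_labels(out, "Passerea"),
                  c("Passerea_Clade1", "Passerea_Clade4"))
  expect_setequal(get_children_labels(out, "Passerea_Clade1"),
                  c("Passerea_Clade2", "Passerea_Clade3"))
  expect_true("Ardeae" %in% get_children_labels(out, "Passerea_Clade2"))
  expect_true("Cursorimorphae" %in% get_children_labels(out, "Passerea_Clade3"))

  # root-to-tip chains number depth-first
  tr2 <- ape::read.tree(text = "(Strisores,(Columbaves,(Gruiformes,(Aequorlitornithes,Inopinaves))))Neoaves;")
  expect_identical(generate_clade_labels(tr2)$node.label,
                   c("Neoaves", "Neoaves_Clade1", "Neoaves_Clade2", "Neoaves_Clade3"))

  # fully labeled trees are untouched
  tr3 <- ape::read.tree(text = "((a,b)x,c)r;")
  expect_identical(generate_clade_labels(tr3)$node.label, c("r", "x"))
  # unlabeled root is an error
  tr4 <- ape::read.tree(text = "((a,b)x,c);")
  expect_error(generate_clade_labels(tr4), "root must be labeled")
})

test_that("newick ingestion yields unique nonempty labels and valid trees", {
  st <- ingest_newick("((a,b)x,c)r;", tag = "T")
  expect_identical(st$root, "r")
  expect_setequal(rcc5align:::tree_children(st, "r"), c("x", "c"))

  set.seed(11)
  for (k in 1:3) {
    tr <- ape::rtree(20)
    tr$node.label <- NULL
    st <- ingest_newick(ape::write.tree(tr), tag = "R")
    expect_identical(anyDuplicated(st$concepts), 0L)
    expect_true(all(nzchar(st$concepts)))
    expect_identical(length(st$concepts), 39L)  # 20 tips + 19 internals
  }
  expect_error(ingest_newick("((a,b),(a,c))r;", tag = "T"), "duplicate leaf")
})

test_that("MIR CSV and DOT writers are deterministic and styled", {
  p <- toy_two_trees("==")
  mir <- infer_mir(p)
  csv <- write_mir_csv(mir)
  expect_match(csv, "left,right,relation\n")
  expect_match(csv, "A.P,B.Q,==", fixed = TRUE)
  expect_identical(csv, write_mir_csv(infer_mir(p)))

  al <- align_concepts(fixture_neoaves_zoom())
  regions <- build_regions(al$problem, al$mir, al$consistency$witness,
                           resolution = "whole")
  dot <- write_dot(regions)
  expect_match(dot, "rounded,filled", fixed = TRUE)     # congruent clusters
  expect_match(dot, "style=dashed, color=blue", fixed = TRUE)  # overlap edges
  expect_match(dot, "octagon", fixed = TRUE)
  split <- build_regions(al$problem, al$mir, al$consistency$witness,
                         resolution = "split")
  dot2 <- write_dot(split)
  expect_match(dot2, "salmon", fixed = TRUE)            # novel split regions
  expect_no_match(dot2, "dashed")
})

test_that("round-tripping a MIR through CSV preserves it", {
  mir <- infer_mir(fixture_psittaciformes("relaxed"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mir_csv(mir, path)
  back <- read_mir_csv(path)
  m1 <- mir[order(mir$left, mir$right), c("left", "right", "mask")]
  m2 <- back[order(back$left, back$right), c("left", "right", "mask")]
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})
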