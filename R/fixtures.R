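# Deterministic fixtures reconstructing the neoavian-explosion use case
# from the published supra-ordinal concept tables and figure narratives,
# plus a seeded random generator of alignment problems with known ground
# truth.

#' Parrot (Psittaciformes) example alignment
#'
#' Two differentially sampled parrot concept hierarchies: the 2015 source
#' samples six species in six genera (18 concepts), the 2014 source two
#' species in two genera (6 concepts); no species-level concept is shared.
#'
#' The `strict` variant applies coverage globally and asserts the eight
#' species-level exclusion articulations (each species excluded from the
#' other source's order-level concept), which propagates exclusion all the
#' way up: the two order-level concepts come out disjoint. The `relaxed`
#' variant relaxes coverage at the two family-level and two genus-level
#' parents (materializing four `nc_` residue regions), includes each of the
#' eight species in the matching other-source parent, and asserts the three
#' higher-level congruences (order, family, genus Nestor), modeling
#' intensionally defined parent concepts that are congruent despite wholly
#' incongruent child sampling.
#'
#' Species sampled by only one source and not named in the use-case
#' narrative are synthesized placeholders (`Psittacidae_gen1` ...,
#' `Psittacidae_gen1_sp1` ...); the named exemplars (Probosciger_aterrimus,
#' Psittacus_erithacus, Melopsittacus_undulatus, Nestor_meridionalis,
#' Nestor_notabilis) are real.
#'
#' @param variant `"strict"` (global coverage) or `"relaxed"` (local
#'   relaxation).
#' @return An `rcc5_problem`.
#' @export
#' @examples
#' fixture_psittaciformes("strict")
fixture_psittaciformes <- function(variant = c("strict", "relaxed")) {
  variant <- match.arg(variant)
  # 2015 tree: 18 concepts (order, family, 4 unnamed family-level clades,
  # 6 genera, 6 species)
  sp2015 <- c("Nestor_meridionalis", "Probosciger_aterrimus", "Psittacus_erithacus",
              "Psittacidae_gen1_sp1", "Psittacidae_gen2_sp1", "Psittacidae_gen3_sp1")
  gen2015 <- c("Nestor", "Probosciger", "Psittacus",
               "Psittacidae_gen1", "Psittacidae_gen2", "Psittacidae_gen3")
  e2015 <- rbind(
    data.frame(parent = "Psittaciformes", child = "Psittacidae"),
    data.frame(parent = "Psittacidae", child = c("Nestor", "Psittacidae_Clade1")),
    data.frame(parent = "Psittacidae_Clade1", child = c("Probosciger", "Psittacidae_Clade2")),
    data.frame(parent = "Psittacidae_Clade2", child = c("Psittacus", "Psittacidae_Clade3")),
    data.frame(parent = "Psittacidae_Clade3", child = c("Psittacidae_gen1", "Psittacidae_Clade4")),
    data.frame(parent = "Psittacidae_Clade4", child = c("Psittacidae_gen2", "Psittacidae_gen3")),
    data.frame(parent = gen2015, child = sp2015)
  )
  # 2014 tree: 6 concepts (order, family, 2 genera, 2 species)
  sp2014 <- c("Nestor_notabilis", "Melopsittacus_undulatus")
  e2014 <- rbind(
    data.frame(parent = "Psittaciformes", child = "Psittacidae"),
    data.frame(parent = "Psittacidae", child = c("Nestor", "Melopsittacus")),
    data.frame(parent = c("Nestor", "Melopsittacus"), child = sp2014)
  )
  if (variant == "strict") {
    t15 <- source_tree("2015", e2015)
    t14 <- source_tree("2014", e2014)
    arts <- rbind(
      data.frame(left = paste0("2015.", sp2015), relation = "!",
                 right = "2014.Psittaciformes"),
      data.frame(left = paste0("2014.", sp2014), relation = "!",
                 right = "2015.Psittaciformes")
    )
  } else {
    t15 <- source_tree("2015", e2015, nocoverage = c("Psittacidae", "Nestor"))
    t14 <- source_tree("2014", e2014, nocoverage = c("Psittacidae", "Nestor"))
    arts <- rbind(
      # memberships of the eight species in other-source parents
      data.frame(left = "2015.Nestor_meridionalis", relation = "<", right = "2014.Nestor"),
      data.frame(left = paste0("2015.", setdiff(sp2015, "Nestor_meridionalis")),
                 relation = "<", right = "2014.Psittacidae"),
      data.frame(left = "2014.Nestor_notabilis", relation = "<", right = "2015.Nestor"),
      data.frame(left = "2014.Melopsittacus_undulatus", relation = "<", right = "2015.Psittacidae"),
      # three congruence assertions
      data.frame(left = paste0("2015.", c("Psittaciformes", "Psittacidae", "Nestor")),
                 relation = "==",
                 right = paste0("2014.", c("Psittaciformes", "Psittacidae", "Nestor")))
    )
  }
  alignment_problem(list(t15, t14), arts)
}

# Supra-ordinal concept table of the 2015 source: parent -> children.
# Row 17's printed child list duplicates row 15's (an apparent erratum that
# would give Mesitornithiformes two parents); the corrected list follows
# the 2014 analogue and the conflict-region narrative.
edges_2015_supraordinal <- function(p17 = c("corrected", "printed")) {
  p17 <- match.arg(p17)
  ch <- list(
    Neornithes = c("Palaeognathae", "Neognathae"),
    Palaeognathae = c("Notopalaeognathae", "Struthioniformes"),
    Notopalaeognathae = c("Novaeratitae", "Rheiformes"),
    Novaeratitae = c("Apterygiformes", "Novaeratitae_Clade1"),
    Novaeratitae_Clade1 = c("Casuariiformes", "Tinamiformes"),
    Neognathae = c("Galloanserae", "Neoaves"),
    Galloanserae = c("Anseriformes", "Galliformes"),
    Neoaves = c("Strisores", "Neoaves_Clade1"),
    Strisores = c("Caprimulgidae", "Strisores_Clade1"),
    Strisores_Clade1 = c("Nyctibiidae", "Steatornithidae", "Strisores_Clade2"),
    Strisores_Clade2 = c("Apodiformes", "Aegothelidae", "Podargidae"),
    Neoaves_Clade1 = c("Columbaves", "Neoaves_Clade2"),
    Columbaves = c("Columbimorphae", "Otidimorphae"),
    Columbimorphae = c("Columbiformes", "Columbimorphae_Clade1"),
    Columbimorphae_Clade1 = c("Mesitornithiformes", "Pterocliformes"),
    Otidimorphae = c("Musophagiformes", "Otidimorphae_Clade1"),
    Otidimorphae_Clade1 = if (p17 == "corrected") c("Cuculiformes", "Otidiformes")
                          else c("Mesitornithiformes", "Ptercoclidiformes"),
    Neoaves_Clade2 = c("Gruiformes", "Neoaves_Clade3"),
    Neoaves_Clade3 = c("Aequorlitornithes", "Inopinaves"),
    Aequorlitornithes = c("Aequorlitornithes_Clade1", "Ardeae"),
    Aequorlitornithes_Clade1 = c("Charadriiformes", "Phoenicopterimorphae"),
    Phoenicopterimorphae = c("Phoenicopteriformes", "Podicipediformes"),
    Ardeae = c("Aequornithia", "Phaethontimorphae"),
    Aequornithia = c("Aequornithia_Clade1", "Gaviiformes"),
    Aequornithia_Clade1 = c("Pelecanimorphae", "Procellariimorphae"),
    Pelecanimorphae = c("Ciconiiformes", "Pelecanimorphae_Clade1"),
    Pelecanimorphae_Clade1 = c("Pelecaniformes", "Suliformes"),
    Procellariimorphae = c("Procellariiformes", "Sphenisciformes"),
    Phaethontimorphae = c("Eurypygiformes", "Phaethontiformes"),
    Inopinaves = c("Opisthocomiformes", "Telluraves"),
    Telluraves = c("Accipitriformes", "Eutelluraves"),
    Eutelluraves = c("Australaves", "Coracornithia"),
    Australaves = c("Cariamiformes", "Eufalconimorphae"),
    Eufalconimorphae = c("Falconiformes", "Passerimorphae"),
    Passerimorphae = c("Passeriformes", "Psittaciformes"),
    Coracornithia = c("Coraciimorphae", "Strigiformes"),
    Coraciimorphae = c("Coliiformes", "Eucavitaves"),
    Eucavitaves = c("Cavitaves", "Leptosomiformes"),
    Cavitaves = c("Picocoraciae", "Trogoniformes"),
    Picocoraciae = c("Bucerotiformes", "Picodynastornithes"),
    Picodynastornithes = c("Coraciiformes", "Piciformes")
  )
  do.call(rbind, lapply(names(ch), function(p) {
    data.frame(parent = p, child = ch[[p]], stringsAsFactors = FALSE)
  }))
}

edges_2014_supraordinal <- function() {
  ch <- list(
    Neornithes = c("Palaeognathae", "Neognathae"),
    Palaeognathae = c("Struthioniformes", "Tinamiformes"),
    Neognathae = c("Galloanseres", "Neoaves"),
    Galloanseres = c("Anseriformes", "Galliformes"),
    Neoaves = c("Columbea", "Passerea"),
    Columbea = c("Columbimorphae", "Phoenicopterimorphae"),
    Columbimorphae = c("Columbiformes", "Columbimorphae_Clade1"),
    Columbimorphae_Clade1 = c("Mesitornithiformes", "Pterocliformes"),
    Phoenicopterimorphae = c("Phoenicopteriformes", "Podicipediformes"),
    Passerea = c("Passerea_Clade1", "Passerea_Clade4"),
    Passerea_Clade1 = c("Passerea_Clade2", "Passerea_Clade3"),
    Passerea_Clade2 = c("Ardeae", "Telluraves"),
    Ardeae = c("Aequornithia", "Phaethontimorphae"),
    Aequornithia = c("Aequornithia_Clade1", "Gaviimorphae"),
    Aequornithia_Clade1 = c("Pelecanimorphae", "Procellariimorphae"),
    Pelecanimorphae = "Pelecaniformes",
    Procellariimorphae = c("Procellariiformes", "Sphenisciformes"),
    Gaviimorphae = "Gaviiformes",
    Phaethontimorphae = c("Eurypygiformes", "Phaethontiformes"),
    Telluraves = c("Afroaves", "Australaves"),
    Afroaves = c("Accipitrimorphae", "Coracornithia"),
    Accipitrimorphae = "Accipitriformes",
    Coracornithia = c("Coraciimorphae", "Strigiformes"),
    Coraciimorphae = c("Coliiformes", "Eucavitaves"),
    Eucavitaves = c("Cavitates", "Leptosomiformes"),
    Cavitates = c("Picocoraciae", "Trogoniformes"),
    Picocoraciae = c("Bucerotiformes", "Picodynastornithes"),
    Picodynastornithes = c("Coraciiformes", "Piciformes"),
    Australaves = c("Cariamiformes", "Eufalconimorphae"),
    Eufalconimorphae = c("Falconiformes", "Passerimorphae"),
    Passerimorphae = c("Passeriformes", "Psittaciformes"),
    Passerea_Clade3 = c("Cursorimorphae", "Opisthocomiformes"),
    Cursorimorphae = c("Charadriiformes", "Gruiformes"),
    Passerea_Clade4 = c("Caprimulgimorphae", "Otidimorphae"),
    Caprimulgimorphae = "Caprimulgiformes",
    Otidimorphae = c("Cuculiformes", "Otidimorphae_Clade1"),
    Otidimorphae_Clade1 = c("Musophagiformes", "Otidiformes")
  )
  do.call(rbind, lapply(names(ch), function(p) {
    data.frame(parent = p, child = ch[[p]], stringsAsFactors = FALSE)
  }))
}

#' Supra-ordinal source trees of the two bird phylogenies
#'
#' The two supra-ordinal concept hierarchies (41 and 37 labeled
#' supra-ordinal concepts, tagged `2015` and `2014`), with the order-level
#' concepts named as their children appearing as terminals.
#'
#' One row of the 2015 table as printed assigns `Otidimorphae_Clade1` the
#' same two children already listed under `Columbimorphae_Clade1`, which
#' cannot form a tree (a concept would need two parents) and contradicts
#' both the 2014 analogue and the conflict-region narrative; it is treated
#' as an erratum. `p17 = "corrected"` (default) uses children
#' `Cuculiformes, Otidiformes`; `p17 = "printed"` reproduces the printed
#' row and therefore raises the duplicate-parent error.
#'
#' @param p17 `"corrected"` or `"printed"`.
#' @return Named list with elements `tree_2015` and `tree_2014`.
#' @export
fixture_tables_1_2 <- function(p17 = c("corrected", "printed")) {
  p17 <- match.arg(p17)
  list(
    tree_2015 = source_tree("2015", edges_2015_supraordinal(p17)),
    tree_2014 = source_tree("2014", edges_2014_supraordinal())
  )
}

#' The zoomed-in Neoaves conflict-region alignment
#'
#' Restriction of the two supra-ordinal bird hierarchies to the region
#' below and including Neoaves, down to the ordinal level: 21 concepts per
#' source. Articulations assert, for every cross-source pair of terminal
#' regions, either congruence (the eleven pairs named congruent in the
#' use-case narrative, e.g. Strisores sec. 2015 with Caprimulgimorphae
#' sec. 2014) or exclusion. Coverage applies globally, so the 26 instances
#' of higher-level overlap in this region are genuine topological
#' conflict, not sampling artifacts.
#'
#' @return An `rcc5_problem` (21 x 21 concepts, single possible world).
#' @export
fixture_neoaves_zoom <- function() {
  e15 <- edges_2015_supraordinal("corrected")
  e14 <- edges_2014_supraordinal()
  # keep the subtree below Neoaves, truncated at the ordinal level: the
  # terminals of the zoom are the lowest concepts retained per source
  keep15 <- c("Neoaves", "Strisores", "Neoaves_Clade1", "Columbaves",
              "Columbimorphae", "Otidimorphae", "Musophagiformes",
              "Otidimorphae_Clade1", "Cuculiformes", "Otidiformes",
              "Neoaves_Clade2", "Gruiformes", "Neoaves_Clade3",
              "Aequorlitornithes", "Aequorlitornithes_Clade1",
              "Charadriiformes", "Phoenicopterimorphae", "Ardeae",
              "Inopinaves", "Opisthocomiformes", "Telluraves")
  keep14 <- c("Neoaves", "Columbea", "Columbimorphae", "Phoenicopterimorphae",
              "Passerea", "Passerea_Clade1", "Passerea_Clade2", "Ardeae",
              "Telluraves", "Passerea_Clade3", "Cursorimorphae",
              "Charadriiformes", "Gruiformes", "Opisthocomiformes",
              "Passerea_Clade4", "Caprimulgimorphae", "Otidimorphae",
              "Cuculiformes", "Otidimorphae_Clade1", "Musophagiformes",
              "Otidiformes")
  sub15 <- e15[e15$parent %in% keep15 & e15$child %in% keep15, ]
  sub14 <- e14[e14$parent %in% keep14 & e14$child %in% keep14, ]
  t15 <- source_tree("2015", sub15)
  t14 <- source_tree("2014", sub14)
  term15 <- tree_terminals(t15)
  term14 <- tree_terminals(t14)
  congruent <- c(
    Strisores = "Caprimulgimorphae",
    Columbimorphae = "Columbimorphae",
    Musophagiformes = "Musophagiformes",
    Cuculiformes = "Cuculiformes",
    Otidiformes = "Otidiformes",
    Gruiformes = "Gruiformes",
    Charadriiformes = "Charadriiformes",
    Phoenicopterimorphae = "Phoenicopterimorphae",
    Ardeae = "Ardeae",
    Opisthocomiformes = "Opisthocomiformes",
    Telluraves = "Telluraves"
  )
  stopifnot(setequal(names(congruent), term15), setequal(congruent, term14))
  grid <- expand.grid(l = term15, r = term14, stringsAsFactors = FALSE)
  rel <- ifelse(!is.na(congruent[grid$l]) & congruent[grid$l] == grid$r, "==", "!")
  arts <- data.frame(left = paste0("2015.", grid$l), relation = rel,
                     right = paste0("2014.", grid$r), stringsAsFactors = FALSE)
  alignment_problem(list(t15, t14), arts)
}

#' Generate a random alignment problem with known ground truth
#'
#' Draws a hidden universe of points, builds one random hierarchical
#' interval partition of it per source (optionally hiding part of a
#' parent behind a relaxed-coverage residue), derives the two concept
#' trees, and asserts the true base relation for sampled pairs of visible
#' terminal regions. The hidden interpretation is returned as the ground
#' truth witness, so the generated problem is consistent by construction
#' and every MIR entry must contain the ground-truth relation of its pair.
#'
#' @param seed Integer seed; the output is fully reproducible from it.
#' @param n_left,n_right Total concept counts per tree, including
#'   materialized `nc_` residue concepts.
#' @param overlap_rate Probability that a split boundary in the right tree
#'   ignores the left tree's boundaries (higher values produce more
#'   cross-source overlap); in `[0, 1]`.
#' @param nc_rate Fraction of internal concepts per tree given relaxed
#'   coverage (rounded down), unless exact counts are supplied.
#' @param nc_left,nc_right Exact numbers of relaxed-coverage residues per
#'   tree; override `nc_rate` when non-`NULL`.
#' @param articulation_rate Fraction of visible cross-source terminal
#'   pairs whose true relation is asserted as an input articulation.
#' @return List of class `rcc5_generated` with elements `problem`,
#'   `ground_truth` (named list of concept extensions over the hidden
#'   universe), and `seed`.
#' @export
#' @examples
#' g <- generate_problem(1, n_left = 9, n_right = 7)
#' check_consistency(g$problem)$consistent
generate_problem <- function(seed, n_left, n_right, overlap_rate = 0.2,
                             nc_rate = 0, nc_left = NULL, nc_right = NULL,
                             articulation_rate = 1) {
  stopifnot(n_left >= 1, n_right >= 1)
  if (overlap_rate < 0 || overlap_rate > 1 || nc_rate < 0 || nc_rate > 1 ||
      articulation_rate < 0 || articulation_rate > 1) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  plan_tree <- function(n, nc_n) {
    # binary splits give 2t-1 concepts for t terminals; each relaxed
    # parent adds one residue concept; an odd deficit is absorbed by
    # making the root trifurcating
    n <- as.integer(n); nc_n <- as.integer(nc_n)
    m <- n - nc_n                       # concepts before residues
    if (m < 1L) stop("tree too small for requested residue count", call. = FALSE)
    if (m == 2L) stop("a two-concept tree (single-child chain) is not generated", call. = FALSE)
    if (m %% 2L == 1L) {
      list(t = (m + 1L) %/% 2L, trifurcate = FALSE, nc = nc_n)
    } else {
      # one trifurcation absorbs the even concept count: 2t - 2 concepts
      list(t = (m + 2L) %/% 2L, trifurcate = TRUE, nc = nc_n)
    }
  }
  nc_l <- if (!is.null(nc_left)) nc_left else floor(nc_rate * (n_left %/% 2))
  nc_r <- if (!is.null(nc_right)) nc_right else floor(nc_rate * (n_right %/% 2))
  pl <- plan_tree(n_left, nc_l)
  pr <- plan_tree(n_right, nc_r)
  n_points <- 2L * max(pl$t + pl$nc, pr$t + pr$nc) + 4L

  build_tree <- function(tag, plan, n_points, snap_points) {
    t_target <- plan$t
    # grow a random tree shape: nodes are intervals [lo, hi]
    nodes <- list(list(id = 1L, lo = 1L, hi = n_points, children = integer(0),
                       nc = FALSE))
    leaves <- 1L
    n_leaves <- 1L
    while (n_leaves < t_target) {
      # pick a splittable leaf (enough points for 2 leaves + reserve)
      cand <- leaves[vapply(leaves, function(i) nodes[[i]]$hi - nodes[[i]]$lo + 1L >= 2L, logical(1))]
      if (!length(cand)) stop("universe too small", call. = FALSE)
      k <- if (length(cand) == 1L) cand else sample(cand, 1L)
      nd <- nodes[[k]]
      nway <- if (plan$trifurcate && k == 1L && length(nodes) == 1L) 3L else 2L
      nway <- min(nway, nd$hi - nd$lo + 1L)
      inner <- seq(nd$lo, nd$hi - 1L)
      snaps <- intersect(inner, snap_points)
      pick_cut <- function(avail) {
        use_snap <- length(snaps_avail <- intersect(avail, snaps)) > 0 &&
          stats::runif(1) > overlap_rate
        if (use_snap) sample_one(snaps_avail) else sample_one(avail)
      }
      cuts <- integer(0)
      avail <- inner
      for (j in seq_len(nway - 1L)) {
        if (!length(avail)) break
        ct <- pick_cut(avail)
        cuts <- c(cuts, ct)
        avail <- setdiff(avail, ct)
      }
      cuts <- sort(unique(cuts))
      bounds <- c(nd$lo - 1L, cuts, nd$hi)
      ids <- integer(0)
      for (j in seq_len(length(bounds) - 1L)) {
        nid <- length(nodes) + 1L
        nodes[[nid]] <- list(id = nid, lo = bounds[j] + 1L, hi = bounds[j + 1L],
                             children = integer(0), nc = FALSE)
        ids <- c(ids, nid)
      }
      nodes[[k]]$children <- ids
      leaves <- c(setdiff(leaves, k), ids)
      n_leaves <- n_leaves + length(ids) - 1L
    }
    # relax coverage at random internal nodes (reserving one point each)
    internal <- which(vapply(nodes, function(nd) length(nd$children) > 0L, logical(1)))
    nc_nodes <- integer(0)
    if (plan$nc > 0L) {
      ok <- internal[vapply(internal, function(i) {
        ch <- nodes[[i]]$children
        any(vapply(ch, function(j) length(nodes[[j]]$children) == 0L &&
                     nodes[[j]]$hi > nodes[[j]]$lo, logical(1)))
      }, logical(1))]
      if (length(ok) < plan$nc) stop("not enough relaxable parents", call. = FALSE)
      nc_nodes <- if (length(ok) == plan$nc) ok else sample(ok, plan$nc)
      for (i in nc_nodes) {
        # shave one point off a multi-point terminal child into the residue
        ch <- nodes[[i]]$children
        donor <- ch[vapply(ch, function(j) length(nodes[[j]]$children) == 0L &&
                             nodes[[j]]$hi > nodes[[j]]$lo, logical(1))][1]
        res_pt <- nodes[[donor]]$hi
        nodes[[donor]]$hi <- nodes[[donor]]$hi - 1L
        nodes[[i]]$nc <- TRUE
        nodes[[i]]$nc_points <- res_pt
      }
    }
    # name concepts and emit edges + ground truth extensions
    nm <- function(id) if (id == 1L) paste0(tag, "_root") else paste0("n", id)
    edges <- NULL
    nocov <- character(0)
    ext <- list()
    terminals <- character(0)
    for (nd in nodes) {
      label <- nm(nd$id)
      pts <- seq(nd$lo, nd$hi)
      if (isTRUE(nd$nc)) {
        # children no longer cover the parent: residue point(s) held back
        nocov <- c(nocov, label)
        ext[[paste0("nc_", label)]] <- nd$nc_points
      }
      ext[[label]] <- pts
      if (length(nd$children)) {
        edges <- rbind(edges, data.frame(parent = label,
                                         child = vapply(nd$children, nm, character(1)),
                                         stringsAsFactors = FALSE))
      } else {
        terminals <- c(terminals, label)
      }
    }
    # residues were shaved after extensions of ancestors were fixed by lo/hi,
    # so parent extensions still include them; terminal extensions exclude them
    list(tree = source_tree(tag, edges, nocoverage = nocov), ext = ext,
         terminals = terminals,
         boundaries = sort(unique(vapply(nodes, function(nd) nd$hi, integer(1)))))
  }

  left <- build_tree("L", pl, n_points, snap_points = integer(0))
  right <- build_tree("R", pr, n_points, snap_points = left$boundaries)

  stopifnot(length(left$tree$concepts) + pl$nc == n_left,
            length(right$tree$concepts) + pr$nc == n_right)

  # true base relations among visible terminal regions
  grid <- expand.grid(l = left$terminals, r = right$terminals,
                      stringsAsFactors = FALSE)
  if (articulation_rate < 1) {
    keep <- stats::runif(nrow(grid)) < articulation_rate
    grid <- grid[keep, , drop = FALSE]
  }
  arts <- if (nrow(grid)) {
    rel <- mapply(function(l, r) base_relation_of_sets(left$ext[[l]], right$ext[[r]]),
                  grid$l, grid$r)
    data.frame(left = paste0("L.", grid$l), relation = unname(rel),
               right = paste0("R.", grid$r), stringsAsFactors = FALSE)
  } else NULL

  problem <- alignment_problem(list(left$tree, right$tree), arts)
  ground_truth <- c(
    stats::setNames(left$ext, paste0("L.", names(left$ext))),
    stats::setNames(right$ext, paste0("R.", names(right$ext)))
  )
  if (!witness_satisfies(problem, ground_truth)) {
    stop("internal: generated ground truth does not satisfy the problem")
  }
  structure(list(problem = problem, ground_truth = ground_truth,
                 seed = as.integer(seed)),
            class = "rcc5_generated")
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
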