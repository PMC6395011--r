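# Constraint encoding over "atoms".
#
# After residue materialization every parent region is the union of the
# terminal regions below it (ordinary terminals, nc_ residue concepts, and
# anonymous possibly-empty residues of non-materialized relaxed parents).
# A set-interpretation of the whole problem is therefore determined by
# which cells of the product grid
#
#     (terminal slots of tree 1 + "outside") x (slots of tree 2 + "outside") ...
#
# are nonempty: each nonempty cell contributes one anonymous point of the
# universe. Under sibling disjointness a point lies in at most one slot per
# tree, which is what makes the grid a faithful basis; with disjointness
# switched off the per-tree coordinate ranges over subsets of slots instead.
#
# Every problem constraint then reduces to either "these atoms are empty"
# (inclusions, exclusions, congruences) or "at least one of these atoms is
# nonempty" (concept nonemptiness, proper-inclusion residues, overlap
# witnesses). Such a system is satisfiable iff the maximal assignment
# (all non-forced atoms nonempty) satisfies every at-least-one set, which
# gives sound and complete consistency checking in linear time per query.

encode_problem <- function(problem) {
  trees <- problem$trees
  disjoint <- problem$options$enforce_sibling_disjointness

  per_tree <- lapply(trees, function(tr) {
    terminals <- tree_terminals(tr)
    hidden <- if (!problem$options$materialize_nc_regions) {
      names(tr$covered)[!tr$covered]
    } else {
      # relaxed parents whose residue was already materialized have coverage
      # restored through the nc child; any remaining relaxed parent (e.g.
      # after pruning) gets an anonymous residue slot
      relaxed <- names(tr$covered)[!tr$covered]
      mat <- vapply(tr$nc_concepts, function(nc) unname(tr$parent_of[nc]), character(1))
      setdiff(relaxed, mat)
    }
    slots <- c(terminals, if (length(hidden)) paste0(".res_", hidden))
    slot_owner <- c(terminals, hidden)  # concept the slot hangs below
    k <- length(slots)
    # concept -> slot index set (terminal descendants + residues below)
    concept_slots <- lapply(tr$concepts, function(cn) {
      desc <- tree_descendants(tr, cn)
      idx <- which(slot_owner %in% desc)
      sort(idx)
    })
    names(concept_slots) <- tr$concepts
    list(tag = tr$tag, slots = slots, k = k, concept_slots = concept_slots,
         terminals = terminals, hidden = hidden)
  })

  # per-tree coordinate alternatives: slot-set carried by an atom
  alts <- lapply(per_tree, function(pt) {
    if (disjoint) {
      c(list(integer(0)), lapply(seq_len(pt$k), identity))
    } else {
      if (pt$k > 12L) {
        stop("non-disjoint sibling mode is limited to 12 terminal regions per tree",
             call. = FALSE)
      }
      subs <- list(integer(0))
      for (s in seq_len(pt$k)) {
        subs <- c(subs, lapply(subs, function(x) c(x, s)))
      }
      subs
    }
  })

  grid <- do.call(expand.grid, c(lapply(alts, seq_along), list(KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- names(trees)
  # drop the everywhere-outside atom (alt index 1 = empty set in every tree)
  all_out <- rowSums(grid != 1L) == 0L
  grid <- grid[!all_out, , drop = FALSE]
  n_atoms <- nrow(grid)

  # membership of each alternative in each concept, per tree
  alt_in_concept <- lapply(seq_along(trees), function(i) {
    pt <- per_tree[[i]]
    m <- matrix(FALSE, nrow = length(alts[[i]]), ncol = length(pt$concept_slots),
                dimnames = list(NULL, names(pt$concept_slots)))
    for (j in seq_along(pt$concept_slots)) {
      sl <- pt$concept_slots[[j]]
      m[, j] <- vapply(alts[[i]], function(a) any(a %in% sl), logical(1))
    }
    m
  })

  concept_atoms <- list()
  for (i in seq_along(trees)) {
    tag <- names(trees)[i]
    for (cn in trees[[i]]$concepts) {
      concept_atoms[[paste0(tag, ".", cn)]] <-
        alt_in_concept[[i]][grid[[i]], cn]
    }
  }

  structure(
    list(problem = problem, per_tree = per_tree, alts = alts, grid = grid,
         n_atoms = n_atoms, concept_atoms = concept_atoms,
         tags = names(trees)),
    class = "rcc5_enc"
  )
}

enc_in <- function(enc, tag, name) enc$concept_atoms[[paste0(tag, ".", name)]]

# Decompose one base-relation articulation into forced-empty atoms and
# at-least-one-nonempty sets.
art_constraints <- function(enc, left_tag, left_name, rel_bit, right_tag, right_name) {
  inl <- enc_in(enc, left_tag, left_name)
  inr <- enc_in(enc, right_tag, right_name)
  forced <- rep(FALSE, enc$n_atoms)
  atleast <- list()
  if (rel_bit == REL_EQ) {
    forced <- xor(inl, inr)
  } else if (rel_bit == REL_GT) {        # left properly includes right
    forced <- inr & !inl
    atleast <- list(which(inl & !inr))
  } else if (rel_bit == REL_LT) {
    forced <- inl & !inr
    atleast <- list(which(inr & !inl))
  } else if (rel_bit == REL_OV) {
    atleast <- list(which(inl & inr), which(inl & !inr), which(inr & !inl))
  } else if (rel_bit == REL_EX) {
    forced <- inl & inr
  } else {
    stop("internal: not a base relation bit: ", rel_bit)
  }
  list(forced = forced, atleast = atleast)
}

# nonemptiness sets for every concept (as atom index vectors)
enc_nonempty_sets <- function(enc) {
  lapply(enc$concept_atoms, which)
}

# All combinations of base-relation choices for the input articulations.
# Returns a matrix (combos x articulations) of relation bits, or NULL when
# the combination count exceeds `limit`.
articulation_combos <- function(problem, limit = 4096L) {
  a <- problem$articulations
  if (nrow(a) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  bit_lists <- lapply(a$relation, relset_bits)
  n_comb <- prod(vapply(bit_lists, length, numeric(1)))
  if (n_comb > limit) return(NULL)
  g <- do.call(expand.grid, c(bit_lists, list(KEEP.OUT.ATTRS = FALSE)))
  as.matrix(g)
}

# Consistency of the problem under one fixed choice of base relations,
# optionally with extra (query) articulations. Returns the allowed-atom
# vector (maximal witness) or NULL.
consistency_for_combo <- function(enc, combo_bits, extra = NULL,
                                  nonempty = enc_nonempty_sets(enc),
                                  arts = enc$problem$articulations) {
  a <- arts
  forced <- rep(FALSE, enc$n_atoms)
  atleast <- nonempty
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      cc <- art_constraints(enc, a$left_tag[i], a$left_name[i], combo_bits[i],
                            a$right_tag[i], a$right_name[i])
      forced <- forced | cc$forced
      atleast <- c(atleast, cc$atleast)
    }
  }
  if (!is.null(extra)) {
    for (e in extra) {
      cc <- art_constraints(enc, e$left_tag, e$left_name, e$rel_bit,
                            e$right_tag, e$right_name)
      forced <- forced | cc$forced
      atleast <- c(atleast, cc$atleast)
    }
  }
  allowed <- !forced
  for (s in atleast) {
    if (!any(allowed[s])) return(NULL)
  }
  allowed
}

# Build an explicit witness model (one anonymous point per nonempty atom).
witness_from_pattern <- function(enc, pattern) {
  pts <- which(pattern)
  ext <- lapply(enc$concept_atoms, function(v) which(pattern & v))
  structure(list(universe = seq_along(pts), atom_ids = pts,
                 extension = lapply(ext, function(ix) match(ix, pts))),
            class = "rcc5_witness")
}

#' @export
print.rcc5_witness <- function(x, ...) {
  cat("<rcc5 witness model> ", length(x$universe), " points, ",
      length(x$extension), " concept extensions\n", sep = "")
  invisible(x)
}

# Relation matrix (signature) realized by a pattern, over all concepts.
signature_from_pattern <- function(enc, pattern) {
  labs <- names(enc$concept_atoms)
  ext <- lapply(enc$concept_atoms, function(v) which(pattern & v))
  n <- length(labs)
  sig <- matrix("", n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sig[i, j] <- base_relation_of_sets(ext[[i]], ext[[j]])
    }
  }
  sig
}

# Evaluate whether an explicit witness satisfies the problem directly
# (used to validate generated ground truths and reasoner output).
witness_satisfies <- function(problem, extensions) {
  trees <- problem$trees
  get <- function(tag, name) extensions[[paste0(tag, ".", name)]]
  for (tr in trees) {
    for (cn in tr$concepts) {
      e <- get(tr$tag, cn)
      if (length(e) == 0L) return(FALSE)
    }
    for (p in names(tr$children)) {
      ep <- get(tr$tag, p)
      ch <- tree_children(tr, p)
      for (cn in ch) {
        if (!all(get(tr$tag, cn) %in% ep)) return(FALSE)
      }
      if (problem$options$enforce_sibling_disjointness && length(ch) > 1L) {
        for (i in seq_len(length(ch) - 1L)) {
          for (j in seq(i + 1L, length(ch))) {
            if (length(intersect(get(tr$tag, ch[i]), get(tr$tag, ch[j])))) return(FALSE)
          }
        }
      }
      if (tr$covered[[p]] || length(tr$nc_concepts) && any(ch %in% tr$nc_concepts)) {
        u <- sort(unique(unlist(lapply(ch, function(cn) get(tr$tag, cn)))))
        if (!identical(sort(unique(ep)), u)) return(FALSE)
      }
    }
  }
  a <- problem$articulations
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      r <- base_relation_of_sets(get(a$left_tag[i], a$left_name[i]),
                                 get(a$right_tag[i], a$right_name[i]))
      if (!bitwAnd(as.integer(rcc5_relset(r)), a$relation[i])) return(FALSE)
    }
  }
  TRUE
}
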