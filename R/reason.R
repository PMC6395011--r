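# Consistency checking, possible-world enumeration, and inference of the
# Maximally Informative Relations (MIR).

#' Check joint consistency of an alignment problem
#'
#' Determines whether the trees, coverage constraints, sibling
#' disjointness, and articulations jointly admit at least one possible
#' world, i.e. one set-interpretation of every concept region satisfying
#' all constraints. Disjunctive articulations are handled by branching
#' over their base-relation choices.
#'
#' @param problem An `rcc5_problem`.
#' @param diagnose_limit When inconsistent and the articulation count is at
#'   most this, a minimal conflicting articulation subset is computed by
#'   deletion-based minimization.
#' @param combo_limit Maximum number of disjunction branch combinations to
#'   explore before declaring the check undecided.
#' @return A list of class `rcc5_consistency` with elements `consistent`
#'   (`TRUE`, `FALSE`, or `NA` for "undecided (limit)"), `witness` (a
#'   witness model when consistent), and `conflict` (tibble of a minimal
#'   conflicting articulation subset, when computed).
#' @export
#' @examples
#' t1 <- source_tree("A", data.frame(parent = "P", child = c("a", "b")))
#' t2 <- source_tree("B", data.frame(parent = "Q", child = c("x", "y")))
#' pr <- alignment_problem(list(t1, t2),
#'   data.frame(left = "A.P", relation = "==", right = "B.Q"))
#' check_consistency(pr)$consistent
check_consistency <- function(problem, diagnose_limit = 30L, combo_limit = 4096L) {
  enc <- encode_problem(problem)
  combos <- articulation_combos(problem, limit = combo_limit)
  if (is.null(combos)) {
    return(structure(list(consistent = NA, witness = NULL, conflict = NULL,
                          reason = "undecided (limit): too many disjunction branches"),
                     class = "rcc5_consistency"))
  }
  nonempty <- enc_nonempty_sets(enc)
  for (k in seq_len(nrow(combos))) {
    allowed <- consistency_for_combo(enc, combos[k, ], nonempty = nonempty)
    if (!is.null(allowed)) {
      return(structure(list(consistent = TRUE,
                            witness = witness_from_pattern(enc, allowed),
                            pattern = allowed, enc = enc,
                            combo = combos[k, ], conflict = NULL),
                       class = "rcc5_consistency"))
    }
  }
  conflict <- NULL
  a <- problem$articulations
  if (nrow(a) > 0L && nrow(a) <= diagnose_limit) {
    subset_consistent <- function(keep) {
      sub <- problem
      sub$articulations <- a[keep, , drop = FALSE]
      cc <- articulation_combos(sub, limit = combo_limit)
      if (is.null(cc)) return(NA)
      for (k in seq_len(nrow(cc))) {
        if (!is.null(consistency_for_combo(enc, cc[k, ], nonempty = nonempty,
                                           arts = sub$articulations))) return(TRUE)
      }
      FALSE
    }
    core <- seq_len(nrow(a))
    i <- 1L
    while (i <= length(core)) {
      cand <- core[-i]
      res <- subset_consistent(cand)
      if (isFALSE(res)) core <- cand else i <- i + 1L
    }
    conflict <- a[core, , drop = FALSE]
  }
  structure(list(consistent = FALSE, witness = NULL, conflict = conflict),
            class = "rcc5_consistency")
}

#' @export
print.rcc5_consistency <- function(x, ...) {
  if (is.na(x$consistent)) {
    cat("<rcc5 consistency> undecided (limit)\n")
  } else if (x$consistent) {
    cat("<rcc5 consistency> consistent;", length(x$witness$universe),
        "points in witness\n")
  } else {
    cat("<rcc5 consistency> inconsistent\n")
    if (!is.null(x$conflict)) {
      cat("minimal conflicting articulations:\n")
      print(tibble::as_tibble(x$conflict))
    }
  }
  invisible(x)
}

#' Enumerate possible worlds
#'
#' Enumerates the distinct possible worlds of a consistent problem. Two
#' worlds are the same iff their signatures - the matrix of realized base
#' relations over all concept pairs, within and across sources - are
#' equal.
#'
#' @param problem An `rcc5_problem`.
#' @param limit Maximum number of distinct worlds to return (must be >= 1).
#' @return List with `signatures` (list of relation matrices), `count`, and
#'   `truncated` (`TRUE` when more worlds exist than `limit`, in which case
#'   `count` is a lower bound).
#' @export
enumerate_worlds <- function(problem, limit = 100L) {
  if (!is.numeric(limit) || limit < 1L) stop("limit must be at least 1", call. = FALSE)
  limit <- as.integer(limit)
  enc <- encode_problem(problem)
  combos <- articulation_combos(problem)
  if (is.null(combos)) stop("undecided (limit): too many disjunction branches", call. = FALSE)
  nonempty <- enc_nonempty_sets(enc)

  sigs <- new.env(parent = emptyenv())
  sig_list <- list()
  truncated <- FALSE

  add_pattern <- function(pattern) {
    sig <- signature_from_pattern(enc, pattern)
    key <- paste(sig, collapse = "")
    if (is.null(sigs[[key]])) {
      if (length(sig_list) >= limit) {
        truncated <<- TRUE
        return(FALSE)
      }
      sigs[[key]] <- TRUE
      sig_list[[length(sig_list) + 1L]] <<- sig
    }
    TRUE
  }

  for (k in seq_len(nrow(combos))) {
    a <- enc$problem$articulations
    forced <- rep(FALSE, enc$n_atoms)
    atleast <- nonempty
    if (nrow(a)) {
      for (i in seq_len(nrow(a))) {
        cc <- art_constraints(enc, a$left_tag[i], a$left_name[i], combos[k, i],
                              a$right_tag[i], a$right_name[i])
        forced <- forced | cc$forced
        atleast <- c(atleast, cc$atleast)
      }
    }
    free <- which(!forced)
    sets <- lapply(atleast, function(s) match(intersect(s, free), free))
    if (any(vapply(sets, length, integer(1)) == 0L)) next
    f <- length(free)
    if (f > 30L) {
      stop("undecided (limit): possible-world space too large to enumerate",
           call. = FALSE)
    }

    # depth-first enumeration over free-atom emptiness patterns; a branch
    # dies as soon as some at-least-one set can no longer be hit
    state <- logical(f)
    recurse <- function(pos) {
      if (truncated) return(invisible(NULL))
      if (pos > f) {
        pattern <- rep(FALSE, enc$n_atoms)
        pattern[free[state]] <- TRUE
        add_pattern(pattern)
        return(invisible(NULL))
      }
      for (val in c(TRUE, FALSE)) {
        state[pos] <<- val
        ok <- TRUE
        if (!val) {
          for (s in sets) {
            if (!any(state[s[s <= pos]]) && !any(s > pos)) { ok <- FALSE; break }
          }
        }
        if (ok) recurse(pos + 1L)
        if (truncated) break
      }
      state[pos] <<- FALSE
      invisible(NULL)
    }
    if (f == 0L) add_pattern(rep(FALSE, enc$n_atoms)) else recurse(1L)
    if (truncated) break
  }
  list(signatures = sig_list, count = length(sig_list), truncated = truncated)
}

# ---- MIR ------------------------------------------------------------------

#' Infer the Maximally Informative Relations
#'
#' For every cross-source concept pair (of consecutive sources, first
#' source listed first), computes the set of base relations realizable in
#' at least one possible world; equivalently, relation `r` is in the entry
#' iff the problem extended with "left r right" remains consistent. The
#' MIR covers every pair, including materialized `nc_` residue regions, so
#' for a two-tree problem it has exactly `|C_A| * |C_B|` entries.
#'
#' @param problem An `rcc5_problem`.
#' @param backend `"auto"` picks a fast counting path for two-tree
#'   problems with sibling disjointness and non-disjunctive input
#'   articulations, and falls back to per-query propagation otherwise;
#'   `"query"` forces the generic path; `"exhaustive"` enumerates every
#'   emptiness pattern of the atom space and collects realized relations
#'   directly (reference oracle; only feasible for small problems).
#' @return A tibble of class `rcc5_mir` with columns `left`, `right`,
#'   `relation` (canonical token string) and `mask` (integer bitmask).
#' @export
infer_mir <- function(problem, backend = c("auto", "query", "exhaustive")) {
  backend <- match.arg(backend)
  enc <- encode_problem(problem)
  a <- problem$articulations
  singleton_arts <- !nrow(a) || all(vapply(a$relation, function(m) length(relset_bits(m)), integer(1)) == 1L)
  eligible_fast <- length(problem$trees) == 2L &&
    problem$options$enforce_sibling_disjointness && singleton_arts

  masks <- switch(backend,
    auto = if (eligible_fast) mir_fast(enc) else mir_query(enc),
    query = mir_query(enc),
    exhaustive = mir_exhaustive(enc)
  )
  mir_as_tibble(enc, masks)
}

mir_pairs <- function(enc) {
  tags <- enc$tags
  out <- list()
  for (i in seq_len(length(tags) - 1L)) {
    t1 <- enc$problem$trees[[tags[i]]]
    t2 <- enc$problem$trees[[tags[i + 1L]]]
    out[[i]] <- expand.grid(left_name = t1$concepts, right_name = t2$concepts,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out[[i]]$left_tag <- tags[i]
    out[[i]]$right_tag <- tags[i + 1L]
  }
  do.call(rbind, out)
}

mir_as_tibble <- function(enc, masks) {
  pairs <- mir_pairs(enc)
  stopifnot(nrow(pairs) == length(masks))
  prob <- enc$problem
  nc_of <- function(tag, nm) nm %in% prob$trees[[tag]]$nc_concepts
  out <- tibble::tibble(
    left = paste0(pairs$left_tag, ".", pairs$left_name),
    right = paste0(pairs$right_tag, ".", pairs$right_name),
    relation = format_relset(masks),
    mask = as.integer(masks),
    left_nc = mapply(nc_of, pairs$left_tag, pairs$left_name, USE.NAMES = FALSE),
    right_nc = mapply(nc_of, pairs$right_tag, pairs$right_name, USE.NAMES = FALSE)
  )
  class(out) <- c("rcc5_mir", class(out))
  attr(out, "tags") <- enc$tags
  attr(out, "tree_sizes") <- unname(vapply(prob$trees, function(t) length(t$concepts), integer(1)))
  out
}

#' @export
print.rcc5_mir <- function(x, ...) {
  sizes <- attr(x, "tree_sizes")
  cat("<MIR> ", nrow(x), " entries (",
      paste(sizes, collapse = " x "), " concepts); ",
      sum(x$mask == REL_OV), " overlap, ",
      sum(x$mask == REL_EQ), " congruent\n", sep = "")
  NextMethod()
}

# generic per-query path: 5 entailment queries per pair against the
# monotone constraint system, branching over input disjunctions
mir_query <- function(enc) {
  problem <- enc$problem
  combos <- articulation_combos(problem)
  if (is.null(combos)) stop("undecided (limit): too many disjunction branches", call. = FALSE)
  nonempty <- enc_nonempty_sets(enc)
  a <- problem$articulations

  # precompute constraint decomposition per combo
  combo_cons <- lapply(seq_len(nrow(combos)), function(k) {
    forced <- rep(FALSE, enc$n_atoms)
    atleast <- list()
    if (nrow(a)) {
      for (i in seq_len(nrow(a))) {
        cc <- art_constraints(enc, a$left_tag[i], a$left_name[i], combos[k, i],
                              a$right_tag[i], a$right_name[i])
        forced <- forced | cc$forced
        atleast <- c(atleast, cc$atleast)
      }
    }
    list(forced = forced, atleast = c(nonempty, atleast))
  })
  combo_cons <- Filter(function(cc) {
    all(vapply(cc$atleast, function(s) any(!cc$forced[s]), logical(1)))
  }, combo_cons)
  if (!length(combo_cons)) stop("problem is inconsistent; MIR undefined", call. = FALSE)

  pairs <- mir_pairs(enc)
  masks <- integer(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    m <- 0L
    for (bit in unname(REL_BITS)) {
      q <- art_constraints(enc, pairs$left_tag[p], pairs$left_name[p], bit,
                           pairs$right_tag[p], pairs$right_name[p])
      ok <- FALSE
      for (cc in combo_cons) {
        forced <- cc$forced | q$forced
        sets <- c(cc$atleast, q$atleast)
        good <- TRUE
        for (s in sets) {
          if (!any(!forced[s])) { good <- FALSE; break }
        }
        if (good) { ok <- TRUE; break }
      }
      if (ok) m <- bitwOr(m, bit)
    }
    masks[p] <- m
  }
  masks
}

# exhaustive reference backend: enumerate every emptiness pattern of the
# atom space, check each constraint by direct evaluation on the witness
# sets, and collect the relations realized across all surviving patterns
mir_exhaustive <- function(enc) {
  worlds <- exhaustive_patterns(enc)
  if (!length(worlds)) stop("problem is inconsistent; MIR undefined", call. = FALSE)
  pairs <- mir_pairs(enc)
  masks <- integer(nrow(pairs))
  for (pat in worlds) {
    ext <- lapply(enc$concept_atoms, function(v) which(pat & v))
    for (p in seq_len(nrow(pairs))) {
      r <- base_relation_of_sets(ext[[paste0(pairs$left_tag[p], ".", pairs$left_name[p])]],
                                 ext[[paste0(pairs$right_tag[p], ".", pairs$right_name[p])]])
      masks[p] <- bitwOr(masks[p], as.integer(rcc5_relset(r)))
    }
  }
  masks
}

# all satisfying emptiness patterns, by direct evaluation (no constraint
# decomposition): feasible for atom spaces up to ~18 atoms
exhaustive_patterns <- function(enc, max_atoms = 18L) {
  m <- enc$n_atoms
  if (m > max_atoms) {
    stop("exhaustive backend limited to ", max_atoms, " atoms (problem has ",
         m, "); use the default backend", call. = FALSE)
  }
  pats <- 0:(2^m - 1)
  cmask <- vapply(enc$concept_atoms, function(v) as.integer(sum(2^(which(v) - 1L))), integer(1))
  keep <- rep(TRUE, length(pats))
  for (cm in cmask) {
    keep <- keep & bitwAnd(pats, cm) != 0
  }
  a <- enc$problem$articulations
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      ml <- cmask[[paste0(a$left_tag[i], ".", a$left_name[i])]]
      mr <- cmask[[paste0(a$right_tag[i], ".", a$right_name[i])]]
      pl <- bitwAnd(pats, ml); pr <- bitwAnd(pats, mr)
      inter <- bitwAnd(pl, pr)
      relbit <- ifelse(pl == pr, REL_EQ,
                ifelse(inter == pr, REL_GT,
                ifelse(inter == pl, REL_LT,
                ifelse(inter == 0, REL_EX, REL_OV))))
      keep <- keep & bitwAnd(relbit, a$relation[i]) != 0
    }
  }
  lapply(pats[keep], function(p) {
    as.logical(bitwAnd(p, 2^(seq_len(m) - 1L)) != 0)
  })
}

# fast counting path for two-tree problems with sibling disjointness and
# single-base input articulations; mathematically equivalent to the
# per-query path (asserted in the test suite)
mir_fast <- function(enc) {
  problem <- enc$problem
  a <- problem$articulations
  combo <- if (nrow(a)) vapply(a$relation, function(m) relset_bits(m)[[1]], integer(1)) else integer(0)
  nonempty <- enc_nonempty_sets(enc)
  allowed <- consistency_for_combo(enc, combo, nonempty = nonempty)
  if (is.null(allowed)) stop("problem is inconsistent; MIR undefined", call. = FALSE)

  t1 <- problem$trees[[1]]; t2 <- problem$trees[[2]]
  pt1 <- enc$per_tree[[1]]; pt2 <- enc$per_tree[[2]]
  k1 <- pt1$k; k2 <- pt2$k
  n1 <- length(t1$concepts); n2 <- length(t2$concepts)

  # counts of allowed atoms per (row slot, col slot); slot 0 = outside
  r <- enc$grid[[1]]; cc_ <- enc$grid[[2]]   # alt index = slot index + 1
  lin <- (cc_ - 1L) * (k1 + 1L) + r
  Wmat <- matrix(tabulate(lin[allowed], nbins = (k1 + 1L) * (k2 + 1L)),
                 nrow = k1 + 1L)

  S1 <- matrix(0, k1 + 1L, n1, dimnames = list(NULL, t1$concepts))
  for (j in seq_len(n1)) S1[pt1$concept_slots[[j]] + 1L, j] <- 1
  S2 <- matrix(0, k2 + 1L, n2, dimnames = list(NULL, t2$concepts))
  for (j in seq_len(n2)) S2[pt2$concept_slots[[j]] + 1L, j] <- 1

  C1 <- t(S1) %*% Wmat                    # n1 x (k2+1)
  cross <- C1 %*% S2                      # n1 x n2
  tot1 <- rowSums(C1)
  tot2 <- colSums(Wmat %*% S2)

  # descendant-or-self indicator per tree: D[c, d] iff d in subtree of c
  desc_mat <- function(tr) {
    n <- length(tr$concepts)
    D <- matrix(FALSE, n, n, dimnames = list(tr$concepts, tr$concepts))
    for (cn in tr$concepts) D[cn, tree_descendants(tr, cn)] <- TRUE
    D
  }
  D1 <- desc_mat(t1); D2 <- desc_mat(t2)

  # input articulations needing at-least-one rechecks, oriented tree1 -> tree2
  need <- list()
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      bit <- combo[i]
      if (a$left_tag[i] == t1$tag) {
        x <- a$left_name[i]; y <- a$right_name[i]
      } else {
        x <- a$right_name[i]; y <- a$left_name[i]
        bit <- as.integer(converse_relset(bit))
      }
      kinds <- if (bit == REL_GT) "XnotY" else if (bit == REL_LT) "YnotX"
               else if (bit == REL_OV) c("XY", "XnotY", "YnotX") else character(0)
      for (kk in kinds) need[[length(need) + 1L]] <- list(x = x, y = y, kind = kk)
    }
  }

  # |slots(x) ∩ slots(a)| helper results expressed through tree ancestry:
  # within a tree two concepts' slot sets are nested or disjoint
  min1 <- function(x, z) if (D1[x, z]) z else if (D1[z, x]) x else NA_character_
  min2 <- function(y, z) if (D2[y, z]) z else if (D2[z, y]) y else NA_character_
  crx <- function(i, j) if (is.na(i) || is.na(j)) 0 else cross[i, j]
  t1of <- function(i) if (is.na(i)) 0 else tot1[[i]]
  t2of <- function(j) if (is.na(j)) 0 else tot2[[j]]

  # removal of |set ∩ D| for the input at-least sets, D given by weights
  # (wAB, wAnB, wBnA) over the pieces a∩b, a\b, b\a of the query pair
  input_sets_ok <- function(ai, bi, wAB, wAnB, wBnA) {
    for (nd in need) {
      x <- nd$x; y <- nd$y
      mxa <- min1(x, ai); myb <- min2(y, bi)
      q <- crx(mxa, myb)                       # |x∩y∩a∩b|
      if (nd$kind == "XY") {
        base <- cross[x, y]
        rem <- wAB * q +
          wAnB * (crx(mxa, y) - q) +
          wBnA * (crx(x, myb) - q)
      } else if (nd$kind == "XnotY") {
        base <- tot1[[x]] - cross[x, y]
        rem <- wAB * (crx(mxa, bi) - q) +
          wAnB * ((t1of(mxa) - crx(mxa, bi)) - (crx(mxa, y) - q)) +
          wBnA * ((cross[x, bi] - crx(mxa, bi)) - (crx(x, myb) - q))
      } else {                                  # YnotX
        base <- tot2[[y]] - cross[x, y]
        rem <- wAB * (crx(ai, myb) - q) +
          wAnB * ((cross[ai, y] - crx(ai, myb)) - (crx(mxa, y) - q)) +
          wBnA * ((t2of(myb) - crx(ai, myb)) - (crx(x, myb) - q))
      }
      if (base - rem < 1) return(FALSE)
    }
    TRUE
  }

  masks <- integer(n1 * n2)
  idx <- 0L
  for (bi in seq_len(n2)) {
    anc_b <- D2[, bi]; dec_b <- D2[bi, ]
    ancb_only <- anc_b & !dec_b
    tb <- tot2[[bi]]
    idb_base <- tot2 * dec_b                     # |d∩b| for d below b
    cb_col <- cross[, bi]
    for (ai in seq_len(n1)) {
      idx <- idx + 1L
      anc_a <- D1[, ai]; dec_a <- D1[ai, ]
      anca_only <- anc_a & !dec_a
      ta <- tot1[[ai]]
      cab <- cross[ai, bi]
      ca_row <- cross[ai, ]

      # tree1 concepts c: |c∩a∩b|, |c∩a|, |c∩b|
      iab <- cb_col * dec_a; iab[anca_only] <- cab
      ica <- tot1 * dec_a; ica[anca_only] <- ta
      icb <- cb_col
      # tree2 concepts d
      iab2 <- ca_row * dec_b; iab2[ancb_only] <- cab
      idb <- idb_base; idb[ancb_only] <- tb
      ida <- ca_row

      m <- 0L
      # EQ: remove a xor b
      rem1 <- (ica - iab) + (icb - iab)
      rem2 <- (ida - iab2) + (idb - iab2)
      if (all(tot1 - rem1 >= 1) && all(tot2 - rem2 >= 1) &&
          input_sets_ok(ai, bi, 0, 1, 1)) m <- bitwOr(m, REL_EQ)
      # GT: remove b\a, require a\b nonempty
      if (ta - cab >= 1 && all(tot1 - (icb - iab) >= 1) &&
          all(tot2 - (idb - iab2) >= 1) &&
          input_sets_ok(ai, bi, 0, 0, 1)) m <- bitwOr(m, REL_GT)
      # LT: remove a\b, require b\a nonempty
      if (tb - cab >= 1 && all(tot1 - (ica - iab) >= 1) &&
          all(tot2 - (ida - iab2) >= 1) &&
          input_sets_ok(ai, bi, 0, 1, 0)) m <- bitwOr(m, REL_LT)
      # OV: nothing removed, require all three pieces nonempty
      if (cab >= 1 && ta - cab >= 1 && tb - cab >= 1) m <- bitwOr(m, REL_OV)
      # EX: remove a∩b
      if (all(tot1 - iab >= 1) && all(tot2 - iab2 >= 1) &&
          input_sets_ok(ai, bi, 1, 0, 0)) m <- bitwOr(m, REL_EX)
      masks[idx] <- m
    }
  }
  # mir_pairs() orders left fastest within right? ensure same order:
  # expand.grid(left, right) varies left fastest; our loops fill bi outer,
  # ai inner, i.e. the same order.
  masks
}

# ---- partition workflow ---------------------------------------------------

#' Prune a problem to a concept subset and propagate inferred articulations
#'
#' Supports the bottom-up partition workflow: after aligning a low-level
#' partition, the inferred parent-level articulations are recorded and the
#' lowest-level concepts pruned away, so that the parents (with their
#' now-relaxed coverage) and the propagated articulations seed the next,
#' more inclusive alignment.
#'
#' @param problem An `rcc5_problem`.
#' @param mir MIR of `problem`, as returned by [infer_mir()].
#' @param keep Character vector of source-qualified labels to retain. Must
#'   be up-closed within each tree (every ancestor of a kept concept is
#'   kept).
#' @return A new `rcc5_problem` on the restricted trees, with coverage
#'   relaxed for kept parents that lost children and the MIR entries among
#'   kept cross-source pairs installed as input articulations.
#' @export
prune_and_propagate <- function(problem, mir, keep) {
  parts <- split_label(keep)
  trees <- list()
  for (tr in problem$trees) {
    knames <- parts$name[parts$tag == tr$tag]
    unknown <- setdiff(knames, tr$concepts)
    if (length(unknown)) {
      stop("keep references unknown concepts in tree '", tr$tag, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!length(knames)) stop("keep retains no concept of tree '", tr$tag, "'", call. = FALSE)
    for (cn in knames) {
      anc <- tree_ancestors(tr, cn)
      if (!all(anc %in% knames)) stop("keep not up-closed: ancestors of ",
                                      tr$tag, ".", cn, " missing", call. = FALSE)
    }
    edges <- NULL
    nocov <- character(0)
    for (p in intersect(names(tr$children), knames)) {
      ch_all <- tree_children(tr, p)
      ch <- setdiff(intersect(ch_all, knames), tr$nc_concepts)
      lost <- length(setdiff(ch_all, c(knames))) > 0L || !tr$covered[[p]] ||
        any(ch_all %in% tr$nc_concepts & !ch_all %in% knames)
      if (length(ch)) {
        edges <- rbind(edges, data.frame(parent = p, child = ch,
                                         stringsAsFactors = FALSE))
        if (lost) nocov <- c(nocov, p)
      }
    }
    if (is.null(edges)) {
      if (length(knames) != 1L) {
        stop("pruned tree '", tr$tag, "' is not connected", call. = FALSE)
      }
      trees[[tr$tag]] <- source_tree(tr$tag, NULL, root = knames)
    } else {
      trees[[tr$tag]] <- source_tree(tr$tag, edges, nocoverage = unique(nocov))
    }
  }
  sel <- mir$left %in% keep & mir$right %in% keep
  arts <- if (any(sel)) {
    data.frame(left = mir$left[sel], relation = format_relset(mir$mask[sel]),
               right = mir$right[sel], stringsAsFactors = FALSE)
  } else NULL
  alignment_problem(unname(trees), arts, options = problem$options)
}
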