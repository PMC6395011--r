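# Alignment region graphs: merged output regions under whole-concept or
# split-concept resolution.

#' Build the alignment region graph
#'
#' Merges concepts with coinciding extensions (in a concrete witness
#' model) into output regions and connects regions by the transitive
#' reduction of proper inclusion. Under whole-concept resolution,
#' overlapping input pairs are additionally joined by an overlap edge;
#' under split-concept resolution each overlapping pair `(A, B)`
#' contributes its three product regions `A*B`, `A\B`, `B\A` instead, so
#' no overlap edges remain.
#'
#' Pairwise MIR alone does not determine triple-wise intersections, so
#' regions are computed from a concrete witness; when the problem has more
#' than one possible world the returned graph describes the witness used
#' (reported in the result), which for the use-case fixtures is the unique
#' world.
#'
#' @param problem An `rcc5_problem`.
#' @param mir MIR of the problem (computed if missing).
#' @param witness A witness model from [check_consistency()]; computed if
#'   missing.
#' @param resolution `"whole"` or `"split"`.
#' @return An object of class `rcc5_regions`: list with `regions` (tibble:
#'   `region_id`, `kind`, `labels`, `split_labels`, `size`), `edges`
#'   (tibble: `from`, `to`, `type`), and `resolution`.
#' @export
build_regions <- function(problem, mir = NULL, witness = NULL,
                          resolution = c("whole", "split")) {
  resolution <- match.arg(resolution)
  if (is.null(mir)) mir <- infer_mir(problem)
  if (is.null(witness)) {
    cc <- check_consistency(problem)
    if (!isTRUE(cc$consistent)) stop("problem is not consistent", call. = FALSE)
    witness <- cc$witness
  }
  ext <- witness$extension
  labs <- names(ext)
  if (!all(c(mir$left, mir$right) %in% labs)) {
    stop("witness does not cover the problem's concepts", call. = FALSE)
  }
  if (any(vapply(ext, length, integer(1)) == 0L)) {
    stop("witness has an empty concept extension; witness/problem mismatch",
         call. = FALSE)
  }
  key <- vapply(ext, function(p) paste(sort(p), collapse = ","), character(1))

  regions <- tibble::tibble(key = unique(key))
  regions$region_id <- seq_len(nrow(regions))
  regions$labels <- lapply(regions$key, function(k) labs[key == k])
  tag_of <- function(ls) unique(vapply(strsplit(ls, ".", fixed = TRUE), `[[`, character(1), 1))
  regions$kind <- vapply(regions$labels, function(ls) {
    if (length(tag_of(ls)) >= 2L) "congruent" else "source_only"
  }, character(1))
  regions$split_labels <- replicate(nrow(regions), character(0), simplify = FALSE)
  ext_of_key <- lapply(regions$key, function(k) ext[[match(k, key)]])

  region_of_label <- stats::setNames(match(key, regions$key), labs)

  ov <- mir[mir$mask == REL_OV, , drop = FALSE]
  if (resolution == "split" && nrow(ov)) {
    for (i in seq_len(nrow(ov))) {
      A <- ov$left[i]; B <- ov$right[i]
      ea <- ext[[A]]; eb <- ext[[B]]
      prods <- list(intersect(ea, eb), setdiff(ea, eb), setdiff(eb, ea))
      plabs <- c(paste0(A, " * ", B), paste0(A, " \\ ", B), paste0(B, " \\ ", A))
      for (j in 1:3) {
        k <- paste(sort(prods[[j]]), collapse = ",")
        hit <- match(k, regions$key)
        if (is.na(hit)) {
          regions <- tibble::add_row(regions, key = k,
                                     region_id = nrow(regions) + 1L,
                                     labels = list(character(0)),
                                     kind = "split_product",
                                     split_labels = list(plabs[j]))
          ext_of_key[[nrow(regions)]] <- prods[[j]]
        } else {
          regions$split_labels[[hit]] <- c(regions$split_labels[[hit]], plabs[j])
        }
      }
    }
  }

  regions$size <- vapply(ext_of_key, length, integer(1))

  # proper-inclusion edges between distinct region extensions, reduced
  n <- nrow(regions)
  incl <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(ext_of_key[[i]]) < length(ext_of_key[[j]]) &&
          all(ext_of_key[[i]] %in% ext_of_key[[j]])) {
        incl[i, j] <- TRUE   # i properly included in j
      }
    }
  }
  red <- incl
  for (i in seq_len(n)) {
    for (j in which(incl[i, ])) {
      # drop i -> j if some k with i < k < j
      if (any(incl[i, ] & incl[, j])) red[i, j] <- FALSE
    }
  }
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in which(red[i, ])) {
      edges <- rbind(edges, data.frame(from = i, to = j, type = "inclusion",
                                       stringsAsFactors = FALSE))
    }
  }
  if (resolution == "whole" && nrow(ov)) {
    oe <- unique(data.frame(from = region_of_label[ov$left],
                            to = region_of_label[ov$right],
                            type = "overlap", stringsAsFactors = FALSE))
    edges <- rbind(edges, oe)
  }
  edges <- if (is.null(edges)) {
    tibble::tibble(from = integer(0), to = integer(0), type = character(0))
  } else tibble::as_tibble(edges)

  structure(
    list(regions = regions[, c("region_id", "kind", "labels", "split_labels", "size", "key")],
         edges = edges, resolution = resolution,
         extensions = ext_of_key, witness = witness),
    class = "rcc5_regions"
  )
}

#' @export
print.rcc5_regions <- function(x, ...) {
  cat("<rcc5 alignment regions> ", nrow(x$regions), " regions (",
      sum(x$regions$kind == "congruent"), " congruent, ",
      sum(x$regions$kind == "split_product"), " split products), ",
      nrow(x$edges), " edges, ", x$resolution, " resolution\n", sep = "")
  invisible(x)
}

#' Census of split-concept resolution labels
#'
#' Every overlapping input pair contributes the three product labels
#' `A*B`, `A\B`, `B\A`. The census classifies each label as a synonym of
#' an input-labeled region or as naming a novel region that no input
#' concept identifies, and counts the novel regions by label multiplicity
#' (uniquely vs redundantly labeled).
#'
#' @param mir MIR of the problem.
#' @param regions Region graph from [build_regions()] with
#'   `resolution = "split"`.
#' @return A list of class `rcc5_split_census`: `total_labels`,
#'   `synonym_labels`, `novel_labels`, `novel_regions`,
#'   `novel_unique`, `novel_redundant`, and `detail` (tibble).
#' @export
split_label_census <- function(mir, regions) {
  if (regions$resolution != "split") {
    stop("split_label_census needs regions built with resolution = 'split'",
         call. = FALSE)
  }
  n_ov <- sum(mir$mask == REL_OV)
  r <- regions$regions
  has_input <- vapply(r$labels, length, integer(1)) > 0L
  n_split <- vapply(r$split_labels, length, integer(1))
  novel <- !has_input & n_split > 0L
  detail <- tibble::tibble(
    region_id = r$region_id,
    kind = r$kind,
    input_labels = vapply(r$labels, paste, character(1), collapse = "; "),
    split_labels = vapply(r$split_labels, paste, character(1), collapse = "; "),
    n_split_labels = n_split,
    novel = novel
  )
  structure(list(
    total_labels = 3L * n_ov,
    synonym_labels = sum(n_split[has_input]),
    novel_labels = sum(n_split[novel]),
    novel_regions = sum(novel),
    novel_unique = sum(novel & n_split == 1L),
    novel_redundant = sum(novel & n_split > 1L),
    detail = detail
  ), class = "rcc5_split_census")
}

#' @export
print.rcc5_split_census <- function(x, ...) {
  cat("<split-concept label census>\n",
      "  total labels:    ", x$total_labels, "\n",
      "  synonyms:        ", x$synonym_labels, "\n",
      "  novel regions:   ", x$novel_regions, " (", x$novel_unique,
      " uniquely, ", x$novel_redundant, " redundantly labeled; ",
      x$novel_labels, " labels)\n", sep = "")
  invisible(x)
}

#' Count cross-source congruent region clusters
#'
#' Counts the maximal clusters of concepts connected by exactly-congruent
#' (`{==}`) MIR entries. Each cluster is one aligned output region
#' carrying at least one concept label from each participating source.
#'
#' @param mir MIR tibble from [infer_mir()].
#' @return Integer cluster count.
#' @export
count_congruent_regions <- function(mir) {
  eq <- mir[mir$mask == REL_EQ, c("left", "right"), drop = FALSE]
  if (!nrow(eq)) return(0L)
  # union-find over the EQ graph
  nodes <- unique(c(eq$left, eq$right))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_len(nrow(eq))) {
    ri <- find(match(eq$left[k], nodes))
    rj <- find(match(eq$right[k], nodes))
    if (ri != rj) parent[[rj]] <- ri
  }
  length(unique(vapply(seq_along(nodes), find, integer(1))))
}
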