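# Derived conflict analyses over the MIR: overlap matrix, chain
# participation, congruent-refinement census, clade-name reliability.

#' Pairwise overlap matrix
#'
#' Cross-tabulates the exactly-overlapping (`{><}`) MIR entries: rows are
#' first-source concepts with at least one overlap, columns likewise for
#' the second source, with row, column and grand totals. The grand total
#' equals the number of `{><}` entries in the (restricted) MIR.
#'
#' @param mir MIR tibble from [infer_mir()].
#' @param restrict Optional character vector of source-qualified labels;
#'   only entries with both members in the set are considered.
#' @return Object of class `rcc5_overlap_matrix` with elements `matrix`
#'   (logical, dimnames = concept labels), `row_totals`, `col_totals`,
#'   `grand_total`.
#' @export
overlap_matrix <- function(mir, restrict = NULL) {
  ov <- mir[mir$mask == REL_OV, , drop = FALSE]
  if (!is.null(restrict)) {
    ov <- ov[ov$left %in% restrict & ov$right %in% restrict, , drop = FALSE]
  }
  if (!nrow(ov)) {
    m <- matrix(FALSE, 0, 0)
    return(structure(list(matrix = m, row_totals = integer(0),
                          col_totals = integer(0), grand_total = 0L),
                     class = "rcc5_overlap_matrix"))
  }
  rows <- unique(ov$left)
  cols <- unique(ov$right)
  m <- matrix(FALSE, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(ov$left, ov$right)] <- TRUE
  rt <- rowSums(m); ct <- colSums(m)
  # order by decreasing participation, then label, as in the use case table
  m <- m[order(-rt, rownames(m)), order(-ct, colnames(m)), drop = FALSE]
  as_int <- function(v) stats::setNames(as.integer(v), names(v))
  structure(list(matrix = m, row_totals = as_int(rowSums(m)),
                 col_totals = as_int(colSums(m)),
                 grand_total = as.integer(sum(m))),
            class = "rcc5_overlap_matrix")
}

#' @export
print.rcc5_overlap_matrix <- function(x, ...) {
  cat("<overlap matrix> ", x$grand_total, " overlapping pairs (",
      nrow(x$matrix), " x ", ncol(x$matrix), " concepts)\n", sep = "")
  if (nrow(x$matrix)) {
    disp <- ifelse(x$matrix, "><", "")
    disp <- cbind(disp, Totals = x$row_totals)
    disp <- rbind(disp, Totals = c(x$col_totals, x$grand_total))
    print(as.data.frame(disp))
  }
  invisible(x)
}

#' @describeIn overlap_matrix Long-form tibble of the overlapping pairs.
#' @param x An `rcc5_overlap_matrix`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.rcc5_overlap_matrix <- function(x, ...) {
  if (!nrow(x$matrix)) {
    return(tibble::tibble(left = character(0), right = character(0)))
  }
  w <- which(x$matrix, arr.ind = TRUE)
  tibble::tibble(left = rownames(x$matrix)[w[, 1]],
                 right = colnames(x$matrix)[w[, 2]])
}

#' Overlap participation of a concept chain
#'
#' Number of exactly-overlapping MIR entries whose same-source member
#' belongs to the given set of concepts (typically a nested chain of
#' parents from one source).
#'
#' @param mir MIR tibble.
#' @param concepts Character vector of source-qualified labels, all from
#'   the same source.
#' @return Integer count.
#' @export
chain_overlap_count <- function(mir, concepts) {
  tags <- unique(split_label(concepts)$tag)
  if (length(tags) != 1L) {
    stop("chain concepts must come from a single source", call. = FALSE)
  }
  ov <- mir[mir$mask == REL_OV, , drop = FALSE]
  sum(ov$left %in% concepts | ov$right %in% concepts)
}

#' Census of congruent refinements
#'
#' A concept refines the other source's topology when it is properly
#' nested between that source's levels: its MIR entries resolve to proper
#' inclusions/exclusions with at least one proper-subset entry, and it is
#' congruent with nothing. Counted per source over above-terminal,
#' non-residue concepts.
#'
#' @param mir MIR tibble.
#' @param problem The `rcc5_problem` the MIR was computed from (supplies
#'   terminal status).
#' @return Tibble with one row per source: `source`, `refinements`, and
#'   the refining concept labels (list column).
#' @export
refinement_census <- function(mir, problem) {
  info <- problem_concepts(problem)
  internal <- info$label[!info$is_terminal & !info$is_nc_region]
  no_nc <- mir[!mir$left_nc & !mir$right_nc, , drop = FALSE]

  eq_left <- unique(no_nc$left[no_nc$mask == REL_EQ])
  eq_right <- unique(no_nc$right[no_nc$mask == REL_EQ])
  # left-source refinement: properly below some right concept, congruent
  # with none
  lt_left <- unique(no_nc$left[no_nc$mask == REL_LT])
  ref_left <- setdiff(intersect(lt_left, internal), eq_left)
  gt_right <- unique(no_nc$right[no_nc$mask == REL_GT])
  ref_right <- setdiff(intersect(gt_right, internal), eq_right)

  tags <- attr(mir, "tags")
  tibble::tibble(
    source = tags,
    refinements = c(length(ref_left), length(ref_right)),
    concepts = list(sort(ref_left), sort(ref_right))
  )
}

#' Clade-name reliability cross-tabulation
#'
#' Asks to what extent the name strings used by the two sources succeed
#' or fail to identify congruent and incongruent concept regions: each
#' analyzed MIR entry is classified by whether the two concepts carry the
#' same name (exact, case-sensitive string equality of the name component)
#' and by its resolved relation. Entries involving `nc_` residue regions
#' are excluded; entries whose MIR is still disjunctive are tallied in a
#' separate `ambiguous` row (empty for single-world alignments).
#'
#' @param mir MIR tibble.
#' @return Object of class `rcc5_name_reliability`: `table` (tibble with
#'   rows same/different/ambiguous), `analyzed`, `unreliable` (same-name
#'   non-congruent + different-name congruent count).
#' @export
name_reliability <- function(mir) {
  keep <- mir[!mir$left_nc & !mir$right_nc, , drop = FALSE]
  lname <- split_label(keep$left)$name
  rname <- split_label(keep$right)$name
  same <- lname == rname
  single <- keep$mask %in% unname(REL_BITS)
  cols <- unname(REL_TOKENS)
  count_row <- function(sel) {
    vapply(unname(REL_BITS), function(b) sum(keep$mask[sel] == b), integer(1))
  }
  tab <- tibble::tibble(
    names = c("same", "different", "ambiguous"),
    `==` = 0L, `>` = 0L, `<` = 0L, `><` = 0L, `!` = 0L
  )
  tab[1, cols] <- as.list(count_row(same & single))
  tab[2, cols] <- as.list(count_row(!same & single))
  # disjunctive entries carry no single relation; only their total is shown
  tab$total <- c(sum(same & single), sum(!same & single), sum(!single))
  unreliable <- sum(keep$mask[same & single] != REL_EQ) +
    sum(keep$mask[!same & single] == REL_EQ)
  structure(list(table = tab, analyzed = nrow(keep), unreliable = unreliable),
            class = "rcc5_name_reliability")
}

#' @export
print.rcc5_name_reliability <- function(x, ...) {
  cat("<clade-name reliability> ", x$analyzed, " MIR entries analyzed; ",
      x$unreliable, " unreliable name pairings\n", sep = "")
  print(x$table)
  invisible(x)
}
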