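# High-level alignment wrapper with broom-style accessors and plots.

#' Align the concept hierarchies of a problem
#'
#' One-call driver: checks consistency, infers the MIR, and bundles
#' problem, witness and MIR into an alignment object with `tidy()`,
#' `glance()` and `autoplot()` methods.
#'
#' @param problem An `rcc5_problem` (or text parsed by [parse_problem()]).
#' @param backend MIR backend, see [infer_mir()].
#' @param worlds_limit When not `NULL`, also count possible worlds up to
#'   this limit.
#' @return An object of class `rcc5_alignment`.
#' @export
#' @examples
#' pr <- fixture_psittaciformes("relaxed")
#' al <- align_concepts(pr)
#' glance(al)
align_concepts <- function(problem, backend = "auto", worlds_limit = NULL) {
  if (is.character(problem)) problem <- parse_problem(problem)
  cc <- check_consistency(problem)
  if (is.na(cc$consistent)) stop("undecided (limit): consistency could not be established", call. = FALSE)
  if (!cc$consistent) {
    stop("problem is inconsistent; minimal conflicting articulations:\n",
         paste(utils::capture.output(print(tibble::as_tibble(cc$conflict))), collapse = "\n"),
         call. = FALSE)
  }
  mir <- infer_mir(problem, backend = backend)
  worlds <- if (!is.null(worlds_limit)) enumerate_worlds(problem, worlds_limit) else NULL
  structure(
    list(problem = problem, consistency = cc, mir = mir, worlds = worlds),
    class = "rcc5_alignment"
  )
}

#' @export
print.rcc5_alignment <- function(x, ...) {
  g <- generics::glance(x)
  cat("<rcc5 alignment> ", g$n_left, " x ", g$n_right, " concepts, ",
      g$n_mir, " MIR entries; ", g$n_overlap, " overlapping, ",
      g$n_congruent_clusters, " congruent clusters\n", sep = "")
  if (!is.null(x$worlds)) {
    cat("  possible worlds: ", x$worlds$count,
        if (x$worlds$truncated) "+ (truncated)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an alignment into its MIR table
#'
#' @param x An `rcc5_alignment`.
#' @param ... Unused.
#' @return The MIR tibble (`left`, `right`, `relation`, `mask`, `left_nc`,
#'   `right_nc`).
#' @export
tidy.rcc5_alignment <- function(x, ...) x$mir

#' One-row summary of an alignment
#'
#' @param x An `rcc5_alignment`.
#' @param ... Unused.
#' @return Tibble with concept counts, MIR size, relation tallies,
#'   congruent cluster count and world count (when computed).
#' @export
glance.rcc5_alignment <- function(x, ...) {
  sizes <- attr(x$mir, "tree_sizes")
  tibble::tibble(
    n_left = sizes[[1]],
    n_right = sizes[[2]],
    n_mir = nrow(x$mir),
    n_congruent = sum(x$mir$mask == REL_EQ),
    n_overlap = sum(x$mir$mask == REL_OV),
    n_refining = sum(x$mir$mask %in% c(REL_GT, REL_LT)),
    n_exclusive = sum(x$mir$mask == REL_EX),
    n_ambiguous = sum(!x$mir$mask %in% unname(REL_BITS)),
    n_congruent_clusters = count_congruent_regions(x$mir),
    n_worlds = if (is.null(x$worlds)) NA_integer_ else x$worlds$count,
    consistent = TRUE
  )
}

#' Heatmap of the maximally informative relations
#'
#' Tile plot of the MIR: first-source concepts on the y axis, second
#' source on the x axis, fill by resolved relation (disjunctive entries
#' shown as "uncertain").
#'
#' @param object An `rcc5_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcc5_alignment <- function(object, ...) {
  d <- object$mir
  d$rel <- ifelse(d$mask %in% unname(REL_BITS), d$relation, "uncertain")
  d$rel <- factor(d$rel, levels = c("==", ">", "<", "><", "!", "uncertain"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$right, y = .data$left,
                                  fill = .data$rel)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c("==" = "gray40", ">" = "#1b9e77", "<" = "#7570b3",
                 "><" = "#d95f02", "!" = "gray90", "uncertain" = "#ffd92f"),
      drop = FALSE, name = "relation") +
    ggplot2::labs(x = attr(object$mir, "tags")[2], y = attr(object$mir, "tags")[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Bar chart of an overlap matrix's participation totals
#'
#' @param object An `rcc5_overlap_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcc5_overlap_matrix <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(concept = names(object$row_totals),
                   overlaps = as.integer(object$row_totals), source = "rows"),
    tibble::tibble(concept = names(object$col_totals),
                   overlaps = as.integer(object$col_totals), source = "columns")
  )
  d$concept <- stats::reorder(d$concept, d$overlaps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$overlaps, y = .data$concept)) +
    ggplot2::geom_col(fill = "#d95f02") +
    ggplot2::facet_wrap(~source, scales = "free_y") +
    ggplot2::labs(x = "overlapping pairs", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
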