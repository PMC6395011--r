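# Deterministic writers: MIR tables as CSV, alignment graphs as DOT.

#' Write a MIR table to CSV
#'
#' Columns `left,right,relation` with the canonical relation tokens,
#' sorted by left then right label; UTF-8, LF line endings.
#'
#' @param mir MIR tibble from [infer_mir()].
#' @param path Output path; `NULL` returns the CSV text invisibly.
#' @return The CSV text, invisibly.
#' @export
write_mir_csv <- function(mir, path = NULL) {
  d <- mir[order(mir$left, mir$right), c("left", "right", "relation")]
  lines <- c("left,right,relation",
             sprintf("%s,%s,%s", d$left, d$right, d$relation))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "", useBytes = TRUE)
  }
  invisible(txt)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Render an alignment region graph as DOT
#'
#' Styling follows the alignment-visualization conventions of the use
#' case figures: first-source-only regions are green boxes, second-source
#' -only regions yellow octagons, congruent multi-source clusters gray
#' rounded rectangles, split-product regions without any input label
#' salmon; inclusion is a solid arrow, overlap a dashed line.
#'
#' @param regions An `rcc5_regions` object from [build_regions()].
#' @param path Output path; `NULL` returns the DOT text invisibly.
#' @param name Graph name.
#' @return The DOT text, invisibly.
#' @export
write_dot <- function(regions, path = NULL, name = "alignment") {
  r <- regions$regions
  tags <- unique(unlist(lapply(r$labels, function(ls) {
    vapply(strsplit(ls, ".", fixed = TRUE), `[[`, character(1), 1)
  })))
  first_tag <- tags[1]
  node_lines <- vapply(seq_len(nrow(r)), function(i) {
    labels <- c(r$labels[[i]], r$split_labels[[i]])
    text <- paste(labels, collapse = "\\n")
    style <- if (r$kind[i] == "congruent") {
      'shape=box, style="rounded,filled", fillcolor=gray85'
    } else if (r$kind[i] == "split_product") {
      'shape=box, style=filled, fillcolor=salmon'
    } else {
      tg <- vapply(strsplit(r$labels[[i]], ".", fixed = TRUE), `[[`, character(1), 1)[1]
      if (identical(tg, first_tag)) {
        'shape=box, style=filled, fillcolor=palegreen'
      } else {
        'shape=octagon, style=filled, fillcolor=lightyellow'
      }
    }
    sprintf("  n%d [label=%s, %s];", r$region_id[i], dot_quote(text), style)
  }, character(1))
  edge_lines <- character(0)
  if (nrow(regions$edges)) {
    e <- regions$edges
    edge_lines <- ifelse(
      e$type == "inclusion",
      sprintf("  n%d -> n%d [color=black];", e$from, e$to),
      sprintf("  n%d -> n%d [style=dashed, color=blue, dir=none];", e$from, e$to)
    )
  }
  txt <- paste0("digraph ", dot_quote(name), " {\n  rankdir=BT;\n",
                paste(c(sort(node_lines), sort(edge_lines)), collapse = "\n"),
                "\n}\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "", useBytes = TRUE)
  }
  invisible(txt)
}
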