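# Line-oriented input dialect for alignment problems.
#
#   # comment
#   taxonomy <tag> [<free text>]
#   (<parent> <child> <child> ...)
#   nocoverage <parent>
#   articulation <tagL>-<tagR>
#   [<tagL>.<name> <relation> <tagR>.<name>]
#
# Relation tokens: ==  >  <  ><  !  plus the word aliases accepted by
# rcc5_relset(); disjunctions are written {A or B or C}.

#' Parse an alignment problem from its text dialect
#'
#' @param text Either a single string (possibly multi-line), a character
#'   vector of lines, or a file path (when `is_file = TRUE`).
#' @param options An [rcc5_options()] record applied to the parsed problem.
#' @param is_file Read `text` as a file path.
#' @return An `rcc5_problem`; the line numbers of concepts and articulations
#'   are attached as attribute `"source_map"` for error reporting.
#' @export
#' @examples
#' p <- parse_problem(c(
#'   "taxonomy A", "(P a b)",
#'   "taxonomy B", "(Q x y)",
#'   "articulation A-B", "[A.P == B.Q]"))
#' p
parse_problem <- function(text, options = rcc5_options(), is_file = FALSE) {
  lines <- if (is_file) readLines(text, warn = FALSE) else {
    if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  }
  perr <- function(i, msg) stop("line ", i, ": ", msg, call. = FALSE)

  mode <- "none"
  cur_tag <- NULL
  tree_edges <- list()     # tag -> list of data.frames
  tree_nocov <- list()     # tag -> character
  tree_order <- character(0)
  arts <- list()
  art_pair <- NULL
  smap <- list()

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^taxonomy\\s+", line)) {
      toks <- strsplit(line, "\\s+")[[1]]
      if (length(toks) < 2L) perr(i, "taxonomy line needs a source tag")
      cur_tag <- toks[[2]]
      if (grepl("[^A-Za-z0-9_]", cur_tag)) perr(i, paste0("invalid source tag '", cur_tag, "'"))
      if (cur_tag %in% tree_order) perr(i, paste0("duplicate taxonomy tag '", cur_tag, "'"))
      tree_order <- c(tree_order, cur_tag)
      tree_edges[[cur_tag]] <- list()
      tree_nocov[[cur_tag]] <- character(0)
      mode <- "taxonomy"
    } else if (grepl("^articulation\\b", line)) {
      toks <- strsplit(line, "\\s+")[[1]]
      if (length(toks) < 2L || !grepl("-", toks[[2]], fixed = TRUE)) {
        perr(i, "articulation line needs a '<tagL>-<tagR>' pair")
      }
      art_pair <- strsplit(toks[[2]], "-", fixed = TRUE)[[1]]
      if (length(art_pair) != 2L) perr(i, "articulation pair must name exactly two tags")
      mode <- "articulation"
    } else if (startsWith(line, "(")) {
      if (mode != "taxonomy") perr(i, "parent/child list outside a taxonomy block")
      if (!endsWith(line, ")")) perr(i, "unterminated parent/child list")
      inner <- trimws(substr(line, 2L, nchar(line) - 1L))
      toks <- strsplit(inner, "\\s+")[[1]]
      if (length(toks) < 2L) perr(i, "parent/child list needs a parent and at least one child")
      bad <- toks[grepl("[^A-Za-z0-9_]", toks)]
      if (length(bad)) perr(i, paste0("invalid concept name '", bad[[1]], "'"))
      tree_edges[[cur_tag]][[length(tree_edges[[cur_tag]]) + 1L]] <-
        data.frame(parent = toks[[1]], child = toks[-1], stringsAsFactors = FALSE)
      for (tk in toks) smap[[length(smap) + 1L]] <- list(line = i, kind = "concept",
                                                         ref = paste0(cur_tag, ".", tk))
    } else if (grepl("^nocoverage\\s+", line)) {
      if (mode != "taxonomy") perr(i, "nocoverage outside a taxonomy block")
      nm <- strsplit(line, "\\s+")[[1]][[2]]
      tree_nocov[[cur_tag]] <- c(tree_nocov[[cur_tag]], nm)
      smap[[length(smap) + 1L]] <- list(line = i, kind = "nocoverage",
                                        ref = paste0(cur_tag, ".", nm))
    } else if (startsWith(line, "[")) {
      if (mode != "articulation") perr(i, "articulation outside an articulation block")
      if (!endsWith(line, "]")) perr(i, "unterminated articulation")
      inner <- trimws(substr(line, 2L, nchar(line) - 1L))
      m <- regexec("^([A-Za-z0-9_]+)\\.([A-Za-z0-9_]+)\\s+(.+?)\\s+([A-Za-z0-9_]+)\\.([A-Za-z0-9_]+)$",
                   inner, perl = TRUE)
      g <- regmatches(inner, m)[[1]]
      if (length(g) != 6L) perr(i, "malformed articulation; expected [tag.name relation tag.name]")
      rel <- tryCatch(rcc5_relset(g[[4]]), error = function(e) perr(i, conditionMessage(e)))
      if (!identical(sort(c(g[[2]], g[[5]])), sort(art_pair)) &&
          !all(c(g[[2]], g[[5]]) %in% art_pair)) {
        perr(i, "articulation tags do not match the enclosing articulation block")
      }
      arts[[length(arts) + 1L]] <- data.frame(
        left_tag = g[[2]], left_name = g[[3]], relation = as.integer(rel),
        right_tag = g[[5]], right_name = g[[6]], stringsAsFactors = FALSE,
        line = i
      )
      smap[[length(smap) + 1L]] <- list(line = i, kind = "articulation",
                                        ref = paste0(g[[2]], ".", g[[3]], " / ", g[[5]], ".", g[[6]]))
    } else {
      perr(i, paste0("unrecognized line: '", substr(line, 1, 40), "'"))
    }
  }

  if (length(tree_order) < 2L) stop("problem needs at least two taxonomy blocks", call. = FALSE)
  trees <- lapply(tree_order, function(tag) {
    ed <- tree_edges[[tag]]
    if (!length(ed)) stop("taxonomy '", tag, "' has no parent/child lines", call. = FALSE)
    edges <- do.call(rbind, ed)
    tryCatch(source_tree(tag, edges, nocoverage = unique(tree_nocov[[tag]])),
             error = function(e) stop("taxonomy '", tag, "': ", conditionMessage(e), call. = FALSE))
  })
  art_df <- if (length(arts)) do.call(rbind, arts) else NULL
  if (!is.null(art_df)) {
    for (k in seq_len(nrow(art_df))) {
      ln <- art_df$line[k]
      res <- tryCatch(
        normalize_articulations(art_df[k, c("left_tag", "left_name", "relation",
                                            "right_tag", "right_name")],
                                stats::setNames(trees, tree_order)),
        error = function(e) perr(ln, conditionMessage(e)))
    }
  }
  prob <- alignment_problem(
    trees,
    if (is.null(art_df)) NULL else art_df[, c("left_tag", "left_name", "relation",
                                              "right_tag", "right_name")],
    options = options
  )
  attr(prob, "source_map") <- dplyr::bind_rows(lapply(smap, tibble::as_tibble))
  prob
}

#' Serialize an alignment problem to the text dialect
#'
#' Output is order-normalized (children and articulations sorted), so that
#' `parse_problem(serialize_problem(p))` reproduces an equal problem.
#' Materialized `nc_` residue concepts are not written as children; the
#' `nocoverage` directive that regenerates them is written instead.
#'
#' @param problem An `rcc5_problem`.
#' @return A single string in the problem dialect.
#' @export
serialize_problem <- function(problem) {
  out <- character(0)
  for (tr in problem$trees) {
    out <- c(out, paste("taxonomy", tr$tag))
    parents <- sort(names(tr$children))
    for (p in parents) {
      ch <- sort(setdiff(tree_children(tr, p), tr$nc_concepts))
      if (!length(ch)) next
      out <- c(out, paste0("(", paste(c(p, ch), collapse = " "), ")"))
    }
    relaxed <- sort(names(tr$covered)[!tr$covered])
    for (p in relaxed) out <- c(out, paste("nocoverage", p))
  }
  a <- problem$articulations
  if (nrow(a)) {
    pairs <- unique(a[, c("left_tag", "right_tag")])
    pairs <- pairs[order(pairs$left_tag, pairs$right_tag), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      sel <- a$left_tag == pairs$left_tag[k] & a$right_tag == pairs$right_tag[k]
      blk <- a[sel, , drop = FALSE]
      blk <- blk[order(blk$left_name, blk$right_name), , drop = FALSE]
      out <- c(out, paste0("articulation ", pairs$left_tag[k], "-", pairs$right_tag[k]))
      out <- c(out, sprintf("[%s.%s %s %s.%s]",
                            blk$left_tag, blk$left_name,
                            format_relset(blk$relation),
                            blk$right_tag, blk$right_name))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a problem file
#'
#' @param problem An `rcc5_problem`.
#' @param path Output file path (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_problem <- function(problem, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(serialize_problem(problem), con, sep = "", useBytes = TRUE)
  invisible(path)
}

# order-normalized structural equality used by tests and round-trip checks
problem_equal <- function(p1, p2) {
  if (!identical(sort(names(p1$trees)), sort(names(p2$trees)))) return(FALSE)
  for (tag in names(p1$trees)) {
    t1 <- p1$trees[[tag]]; t2 <- p2$trees[[tag]]
    if (!identical(sort(t1$concepts), sort(t2$concepts))) return(FALSE)
    if (!identical(t1$root, t2$root)) return(FALSE)
    if (!identical(sort(names(t1$children)), sort(names(t2$children)))) return(FALSE)
    for (p in names(t1$children)) {
      if (!identical(sort(t1$children[[p]]), sort(t2$children[[p]]))) return(FALSE)
    }
    if (!identical(t1$covered[sort(names(t1$covered))],
                   t2$covered[sort(names(t2$covered))])) return(FALSE)
  }
  key <- function(a) {
    k <- sprintf("%s.%s|%d|%s.%s", a$left_tag, a$left_name, a$relation,
                 a$right_tag, a$right_name)
    sort(k)
  }
  identical(key(p1$articulations), key(p2$articulations))
}
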