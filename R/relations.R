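# RCC-5 base relations and the 32-element lattice of their disjunctions.
#
# A relation set is stored as an integer bitmask over the five base
# relations; the empty mask (0L) is the lattice bottom and denotes an
# unsatisfiable articulation, the full mask (31L) carries no information.

REL_EQ <- 1L   # congruence                "=="
REL_GT <- 2L   # proper inclusion          ">"   (left properly includes right)
REL_LT <- 4L   # inverse proper inclusion  "<"
REL_OV <- 8L   # overlap                   "><"
REL_EX <- 16L  # exclusion                 "!"

REL_ALL <- 31L
REL_BITS <- c(EQ = 1L, GT = 2L, LT = 4L, OV = 8L, EX = 16L)
REL_TOKENS <- c(EQ = "==", GT = ">", LT = "<", OV = "><", EX = "!")
REL_WORDS <- c(
  equals = 1L, includes = 2L, is_included_in = 4L,
  overlaps = 8L, disjoint = 16L
)

#' RCC-5 base relation tokens
#'
#' The five base relations of Region Connection Calculus as used between
#' taxonomic/phylogenomic concept regions: congruence `==`, proper inclusion
#' `>`, inverse proper inclusion `<`, overlap `><`, and exclusion `!`.
#'
#' @return Character vector of the five relation tokens.
#' @export
#' @examples
#' rcc5_relations()
rcc5_relations <- function() unname(REL_TOKENS)

#' Build a relation set from tokens
#'
#' A relation set is any subset of the five RCC-5 base relations; the 32
#' subsets form the uncertainty lattice, from the empty (unsatisfiable) set
#' to the uninformative full disjunction. Accepted inputs: symbol tokens
#' (`"=="`, `">"`, `"<"`, `"><"`, `"!"`), word aliases (`"equals"`,
#' `"includes"`, `"is_included_in"`, `"overlaps"`, `"disjoint"`), or a
#' braced disjunction such as `"{== or ><}"`.
#'
#' @param x Character vector of tokens and/or disjunction strings, or an
#'   integer bitmask already in internal form.
#' @return Integer bitmask (0..31) of class `rcc5_relset`.
#' @export
#' @examples
#' rcc5_relset("{== or >}")
#' rcc5_relset(c("<", "overlaps"))
rcc5_relset <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(x)
    if (any(is.na(m)) || any(m < 0L) || any(m > 31L)) {
      stop("relation bitmask must be in 0..31", call. = FALSE)
    }
    return(structure(Reduce(bitwOr, m, 0L), class = "rcc5_relset"))
  }
  stopifnot(is.character(x))
  mask <- 0L
  for (piece in x) {
    s <- trimws(piece)
    if (grepl("^\\{", s)) {
      if (!grepl("\\}$", s)) stop("unterminated relation disjunction: ", piece, call. = FALSE)
      inner <- trimws(substr(s, 2L, nchar(s) - 1L))
      toks <- if (nzchar(inner)) strsplit(inner, "\\s+or\\s+")[[1]] else character(0)
    } else {
      toks <- s
    }
    for (tok in toks) {
      tok <- trimws(tok)
      bit <- if (tok %in% REL_TOKENS) {
        REL_BITS[[names(REL_TOKENS)[REL_TOKENS == tok]]]
      } else if (tok %in% names(REL_WORDS)) {
        REL_WORDS[[tok]]
      } else if (tok == "=") {
        # tolerated variant of the congruence symbol
        REL_EQ
      } else {
        stop("unknown relation token: '", tok, "'", call. = FALSE)
      }
      mask <- bitwOr(mask, bit)
    }
  }
  structure(mask, class = "rcc5_relset")
}

#' Format a relation set as its canonical token string
#'
#' Singletons serialize to their bare token; larger sets to a braced
#' disjunction `{a or b}` in the fixed order `==`, `>`, `<`, `><`, `!`;
#' the empty set to `{}` (unsatisfiable).
#'
#' @param mask Integer bitmask(s) in 0..31.
#' @return Character vector of the same length.
#' @export
#' @examples
#' format_relset(rcc5_relset(c("==", "!")))
format_relset <- function(mask) {
  mask <- as.integer(mask)
  vapply(mask, function(m) {
    toks <- REL_TOKENS[bitwAnd(m, REL_BITS) != 0L]
    if (length(toks) == 0L) "{}"
    else if (length(toks) == 1L) unname(toks)
    else paste0("{", paste(toks, collapse = " or "), "}")
  }, character(1))
}

#' @export
print.rcc5_relset <- function(x, ...) {
  cat("<rcc5 relation set> ", format_relset(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rcc5_relset <- function(x, ...) format_relset(x)

relset_members <- function(mask) {
  unname(REL_TOKENS[bitwAnd(as.integer(mask), REL_BITS) != 0L])
}

relset_bits <- function(mask) {
  unname(REL_BITS[bitwAnd(as.integer(mask), REL_BITS) != 0L])
}

#' Converse of a relation set
#'
#' Swaps the two directional relations (`>` and `<`) element-wise;
#' congruence, overlap and exclusion are symmetric. `converse(r)` is the
#' relation set holding between (b, a) whenever `r` holds between (a, b).
#'
#' @param mask A relation bitmask or token string.
#' @return Relation bitmask of class `rcc5_relset`.
#' @export
#' @examples
#' format_relset(converse_relset("{< or ><}"))
converse_relset <- function(mask) {
  if (is.character(mask)) mask <- rcc5_relset(mask)
  m <- as.integer(mask)
  gt <- bitwAnd(m, REL_GT)
  lt <- bitwAnd(m, REL_LT)
  out <- bitwAnd(m, bitwNot(REL_GT + REL_LT))
  out <- bitwOr(out, ifelse(gt != 0L, REL_LT, 0L))
  out <- bitwOr(out, ifelse(lt != 0L, REL_GT, 0L))
  structure(as.integer(out), class = "rcc5_relset")
}

#' Base RCC-5 relation realized by two finite sets
#'
#' Evaluates the set semantics of the five base relations: `==` iff the
#' sets are equal, `>` iff the left properly contains the right, `<` the
#' converse, `!` iff they are disjoint, `><` otherwise. Exactly one base
#' relation holds for any pair of nonempty sets.
#'
#' @param a,b Nonempty vectors interpreted as finite sets.
#' @return One of `"=="`, `">"`, `"<"`, `"><"`, `"!"`.
#' @export
#' @examples
#' base_relation_of_sets(1:2, 2:3)
base_relation_of_sets <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("undefined for empty region", call. = FALSE)
  }
  a <- unique(a); b <- unique(b)
  nab <- sum(a %in% b)
  if (nab == length(a) && nab == length(b)) "=="
  else if (nab == length(b)) ">"
  else if (nab == length(a)) "<"
  else if (nab == 0L) "!"
  else "><"
}

# Composition table of the RCC-5 base relations, generated once by brute
# force over all triples of nonempty subsets of a 6-point universe and
# frozen here. compose(r1, r2) is the set of base relations s for which
# sets a, b, c exist with a r1 b, b r2 c and a s c.
REL_COMPOSE_TABLE <- local({
  tab <- list(
    "== ==" = "==",       "== >" = ">",          "== <" = "<",
    "== ><" = "><",       "== !" = "!",
    "> ==" = ">",         "> >" = ">",           "> <" = "{== or > or < or ><}",
    "> ><" = "{> or ><}", "> !" = "{> or >< or !}",
    "< ==" = "<",         "< >" = "{== or > or < or >< or !}",
    "< <" = "<",          "< ><" = "{< or >< or !}", "< !" = "!",
    ">< ==" = "><",       ">< >" = "{> or >< or !}", ">< <" = "{< or ><}",
    ">< ><" = "{== or > or < or >< or !}", ">< !" = "{> or >< or !}",
    "! ==" = "!",         "! >" = "!",           "! <" = "{< or >< or !}",
    "! ><" = "{< or >< or !}", "! !" = "{== or > or < or >< or !}"
  )
  out <- matrix(0L, 5, 5, dimnames = list(REL_TOKENS, REL_TOKENS))
  for (k in names(tab)) {
    parts <- strsplit(k, " ")[[1]]
    out[parts[1], parts[2]] <- as.integer(rcc5_relset(tab[[k]]))
  }
  out
})

#' Compose two RCC-5 relations
#'
#' Given `a r1 b` and `b r2 c`, returns the set of base relations that can
#' hold between `a` and `c`. Disjunctive arguments compose to the union of
#' the compositions of their members, which makes the operation usable for
#' propagating articulations transitively across three sources.
#'
#' @param r1,r2 Base relation tokens, or relation sets (tokens, disjunction
#'   strings, or bitmasks).
#' @return Relation bitmask of class `rcc5_relset`.
#' @export
#' @examples
#' format_relset(compose_relations("<", "<"))
#' format_relset(compose_relations("<", ">"))
compose_relations <- function(r1, r2) {
  m1 <- if (is.character(r1)) rcc5_relset(r1) else rcc5_relset(as.integer(r1))
  m2 <- if (is.character(r2)) rcc5_relset(r2) else rcc5_relset(as.integer(r2))
  out <- 0L
  for (t1 in relset_members(m1)) {
    for (t2 in relset_members(m2)) {
      out <- bitwOr(out, REL_COMPOSE_TABLE[t1, t2])
    }
  }
  structure(out, class = "rcc5_relset")
}
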