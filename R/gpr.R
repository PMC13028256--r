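## GPR rule strings follow the conventional grammar
##   expr   := term ("or" term)*
##   term   := factor ("and" factor)*
##   factor := "(" expr ")" | gene-id
## "and" binds tighter than "or"; connectives are case-insensitive.

#' Parse a gene-protein-reaction rule string
#'
#' Parses a boolean rule such as \code{"(gA and gB) or gC"} into a
#' [GprRule-class] expression tree. \code{and} binds tighter than \code{or};
#' parentheses override precedence; an empty or all-whitespace string yields
#' the empty rule (no gene association).
#'
#' @param rule character(1) rule string.
#' @return A [GprRule-class].
#' @examples
#' parseGpr("(gA and gB) or gC")
#' parseGpr("Prupe.3G101000")
#' parseGpr("")   # no gene association
#' @export
parseGpr <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  rule <- trimws(rule)
  if (!nzchar(rule) || is.na(rule))
    return(new("GprRule", tree = list()))

  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  kind <- ifelse(toks == "(", "lpar",
          ifelse(toks == ")", "rpar",
          ifelse(tolower(toks) == "and", "and",
          ifelse(tolower(toks) == "or", "or", "gene"))))
  pos <- 0L
  peek <- function() if (pos < length(toks)) kind[pos + 1L] else "eof"
  advance <- function() {
    pos <<- pos + 1L
    toks[pos]
  }
  parseFactor <- function() {
    k <- peek()
    if (k == "lpar") {
      advance()
      node <- parseExpr()
      if (peek() != "rpar") stop("unbalanced parentheses in GPR rule: ", rule)
      advance()
      node
    } else if (k == "gene") {
      list(type = "leaf", gene = advance())
    } else {
      stop("dangling connective or empty term in GPR rule: ", rule)
    }
  }
  parseTerm <- function() {
    kids <- list(parseFactor())
    while (peek() == "and") {
      advance()
      kids <- c(kids, list(parseFactor()))
    }
    if (length(kids) == 1L) kids[[1]] else list(type = "and", children = kids)
  }
  parseExpr <- function() {
    kids <- list(parseTerm())
    while (peek() == "or") {
      advance()
      kids <- c(kids, list(parseTerm()))
    }
    if (length(kids) == 1L) kids[[1]] else list(type = "or", children = kids)
  }
  tree <- parseExpr()
  if (pos != length(toks))
    stop("unbalanced parentheses in GPR rule: ", rule)
  new("GprRule", tree = tree)
}

#' Serialize a GPR rule back to a string
#'
#' Inverse of [parseGpr()] up to boolean equivalence: the returned string
#' re-parses to a rule with identical truth table over its genes.
#' Parentheses are emitted only where \code{or} occurs under \code{and}.
#'
#' @param gpr a [GprRule-class].
#' @return character(1); \code{""} for the empty rule.
#' @export
gprToString <- function(gpr) {
  stopifnot(is(gpr, "GprRule"))
  fmt <- function(node) {
    if (length(node) == 0L) return("")
    if (node$type == "leaf") return(node$gene)
    parts <- vapply(node$children, function(ch) {
      s <- fmt(ch)
      if (node$type == "and" && length(ch) && identical(ch$type, "or"))
        s <- paste0("(", s, ")")
      s
    }, character(1))
    paste(parts, collapse = paste0(" ", node$type, " "))
  }
  fmt(gpr@tree)
}

#' Genes referenced by a GPR rule
#'
#' @param gpr a [GprRule-class].
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gprLeaves <- function(gpr) {
  stopifnot(is(gpr, "GprRule"))
  walk <- function(node) {
    if (length(node) == 0L) return(character(0))
    if (node$type == "leaf") return(node$gene)
    unlist(lapply(node$children, walk))
  }
  unique(walk(gpr@tree))
}

#' Evaluate a GPR rule under a gene on/off assignment
#'
#' Used to check boolean equivalence of parse/serialize round trips.
#' Genes missing from \code{assignment} count as \code{FALSE}.
#'
#' @param gpr a [GprRule-class].
#' @param assignment named logical vector, gene id -> on/off.
#' @return logical(1); \code{NA} for the empty rule.
#' @export
evalGpr <- function(gpr, assignment) {
  stopifnot(is(gpr, "GprRule"))
  ev <- function(node) {
    if (node$type == "leaf")
      return(isTRUE(assignment[[node$gene]]))
    vals <- vapply(node$children, ev, logical(1))
    if (node$type == "and") all(vals) else any(vals)
  }
  if (length(gpr@tree) == 0L) return(NA)
  ev(gpr@tree)
}

#' @describeIn GprRule-class compact display of the rule string.
#' @param object a \code{GprRule}.
#' @export
setMethod("show", "GprRule", function(object) {
  s <- gprToString(object)
  cat("GprRule:", if (nzchar(s)) s else "<no gene association>", "\n")
})
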