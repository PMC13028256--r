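## Reaction-equation dialect:
##   "cys_c + hcn_c --> cyanoala_c + h2s_c + h_c"     irreversible
##   "fum_m + h2o_m <=> mal_m"                         reversible
##   "gssg_c + h_c + nadph_c --> 2.0 gsh_c + nadp_c"   explicit coefficient
##   " --> glc_c" / "co2_c --> "                       pool source / sink
## Terms are "+"-separated, "coef metabolite" with coefficient defaulting
## to 1. A metabolite occurring on both sides is net-summed.

.ARROWS <- c("-->", "<=>")

#' Parse a reaction equation string
#'
#' Splits an equation on its single arrow token (\code{-->} irreversible,
#' \code{<=>} reversible) and returns the net signed stoichiometry: substrates
#' (left side) negative, products (right side) positive. One side may be
#' empty, which marks a pool/sink (exchange) reaction.
#'
#' @param equation character(1).
#' @return list with elements \code{stoichiometry} (named numeric),
#'   \code{reversible} (logical) and \code{is_exchange} (logical: one side
#'   empty).
#' @examples
#' parseReactionEquation("gssg_c + h_c + nadph_c --> 2.0 gsh_c + nadp_c")
#' parseReactionEquation("fum_m + h2o_m <=> mal_m")
#' @export
parseReactionEquation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  hits <- lapply(.ARROWS, function(a)
    gregexpr(a, equation, fixed = TRUE)[[1]])
  nhit <- vapply(hits, function(h) sum(h > 0), integer(1))
  if (sum(nhit) == 0L)
    stop("no arrow ('-->' or '<=>') in equation: ", equation)
  if (sum(nhit) > 1L)
    stop("more than one arrow in equation: ", equation)
  arrow <- .ARROWS[nhit == 1L]
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  lhs <- if (length(sides) >= 1L) trimws(sides[1]) else ""
  rhs <- if (length(sides) >= 2L) trimws(sides[2]) else ""

  parseSide <- function(side, sign) {
    if (!nzchar(side)) return(numeric(0))
    if (grepl("^\\+", side) || grepl("\\+$", side))
      stop("empty term (stray '+') in equation: ", equation)
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    if (length(terms) == 0L || any(!nzchar(terms)))
      stop("empty term (stray '+') in equation: ", equation)
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1
        metab <- parts[1]
      } else if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef))
          stop("malformed coefficient '", parts[1], "' in equation: ",
               equation)
        metab <- parts[2]
      } else {
        stop("malformed term '", tm, "' in equation: ", equation)
      }
      out[metab] <- (if (metab %in% names(out)) out[[metab]] else 0) +
        sign * coef
    }
    out
  }

  st <- parseSide(lhs, -1)
  for (metab in names(rh <- parseSide(rhs, +1)))
    st[metab] <- (if (metab %in% names(st)) st[[metab]] else 0) + rh[[metab]]
  st <- st[abs(st) > 1e-9]
  list(stoichiometry = st,
       reversible = arrow == "<=>",
       is_exchange = !nzchar(lhs) || !nzchar(rhs))
}

#' Format a stoichiometry as an equation string
#'
#' Inverse of [parseReactionEquation()]: negative coefficients go left of the
#' arrow, positive right, metabolites in alphabetical order, unit
#' coefficients omitted and integer coefficients printed with one decimal
#' (e.g. \code{"2.0 gsh_c"}).
#'
#' @param stoichiometry named numeric vector (negative = consumed).
#' @param reversible logical(1); selects \code{<=>} over \code{-->}.
#' @return character(1).
#' @export
formatReactionEquation <- function(stoichiometry, reversible = FALSE) {
  fmtCoef <- function(x) {
    if (abs(x - round(x)) < 1e-9) sprintf("%.1f", round(x))
    else format(x, digits = 10)
  }
  fmtSide <- function(st) {
    if (length(st) == 0L) return("")
    st <- st[order(names(st))]
    paste(vapply(seq_along(st), function(i) {
      if (abs(st[[i]] - 1) < 1e-9) names(st)[i]
      else paste(fmtCoef(st[[i]]), names(st)[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmtSide(-stoichiometry[stoichiometry < 0])
  rhs <- fmtSide(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "-->"
  trimws(paste(lhs, arrow, rhs))
}
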