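#' @include AllClasses.R
NULL

#' @describeIn MetabolicModel-class reaction identifiers, in model order.
#' @param x a \code{MetabolicModel}.
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @describeIn MetabolicModel-class metabolite identifiers, in model order.
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @describeIn MetabolicModel-class the reaction table (\code{DataFrame}).
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @describeIn MetabolicModel-class the metabolite table (\code{DataFrame}).
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @describeIn MetabolicModel-class all gene ids referenced by GPR rules.
#' @export
setMethod("genes", "MetabolicModel", function(x)
  sort(unique(unlist(lapply(x@gpr, gprLeaves), use.names = FALSE))))

#' @describeIn MetabolicModel-class named list of [GprRule-class] objects.
#' @export
setMethod("gprRules", "MetabolicModel", function(x) x@gpr)

#' @describeIn MetabolicModel-class named character vector of subsystems.
#' @export
setMethod("subsystems", "MetabolicModel", function(x)
  stats::setNames(x@reactions$subsystem, x@reactions$id))

#' @describeIn MetabolicModel-class named logical: one reaction side empty.
#' @export
setMethod("isExchange", "MetabolicModel", function(x)
  stats::setNames(x@reactions$is_exchange, x@reactions$id))

#' @describeIn MetabolicModel-class named vector of lower flux bounds.
#' @export
setMethod("lowerBounds", "MetabolicModel", function(x)
  stats::setNames(x@reactions$lower_bound, x@reactions$id))

#' @describeIn MetabolicModel-class named vector of upper flux bounds.
#' @export
setMethod("upperBounds", "MetabolicModel", function(x)
  stats::setNames(x@reactions$upper_bound, x@reactions$id))

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel \"", object@name, "\": ",
      nrow(object@reactions), " reactions, ",
      nrow(object@metabolites), " metabolites, ",
      length(genes(object)), " genes\n", sep = "")
  sub <- table(object@reactions$subsystem)
  if (length(sub)) {
    cat("subsystems:\n")
    for (s in names(sub))
      cat(sprintf("  %-38s %3d\n", s, sub[[s]]))
  }
})

#' Add a reaction to a model
#'
#' @param model a [MetabolicModel-class].
#' @param id new unique reaction id.
#' @param equation equation string (see [parseReactionEquation()]).
#' @param gpr GPR rule string (default: no gene association).
#' @param subsystem subsystem label.
#' @param lower_bound,upper_bound flux bounds; defaults follow the
#'   reversibility of the equation arrow.
#' @return the extended, re-validated model.
#' @export
addReaction <- function(model, id, equation, gpr = "", subsystem = "",
                        lower_bound = NA, upper_bound = NA) {
  stopifnot(is(model, "MetabolicModel"))
  if (id %in% model@reactions$id)
    stop("reaction id already present: ", id)
  pe <- parseReactionEquation(equation)
  if (is.na(lower_bound))
    lower_bound <- if (pe$reversible) -.DEFAULT_UB else 0
  if (is.na(upper_bound)) upper_bound <- .DEFAULT_UB
  old <- model@reactions
  core <- c("id", "reversible", "lower_bound", "upper_bound", "subsystem",
            "is_exchange")
  n <- nrow(old)
  stoich <- c(lapply(seq_len(n), function(j) {
    st <- model@stoichiometry[, j]
    st[st != 0]
  }), list(pe$stoichiometry))
  extra <- setdiff(colnames(old), core)
  ann <- if (length(extra)) {
    a <- old[, extra, drop = FALSE]
    pad <- DataFrame(lapply(a, function(col) c(col, NA)))
    pad[seq_len(n + 1L), , drop = FALSE]
  } else NULL
  mod <- .makeModel(c(old$id, id), stoich,
                    c(old$reversible, pe$reversible),
                    c(old$lower_bound, lower_bound),
                    c(old$upper_bound, upper_bound),
                    c(model@gpr, list(parseGpr(gpr))),
                    c(old$subsystem, subsystem),
                    c(old$is_exchange, pe$is_exchange),
                    annotations = ann, name = model@name)
  validObject(mod)
  mod
}

#' Remove reactions from a model
#'
#' Drops the given reactions and any metabolite no longer referenced by any
#' remaining reaction.
#'
#' @param model a [MetabolicModel-class].
#' @param ids reaction ids to remove.
#' @return the reduced model.
#' @export
removeReactions <- function(model, ids) {
  stopifnot(is(model, "MetabolicModel"))
  miss <- setdiff(ids, model@reactions$id)
  if (length(miss)) stop("unknown reaction id: ", paste(miss, collapse = ", "))
  keep <- !(model@reactions$id %in% ids)
  S <- model@stoichiometry[, keep, drop = FALSE]
  keepMet <- Matrix::rowSums(S != 0) > 0
  mod <- model
  mod@reactions <- model@reactions[keep, , drop = FALSE]
  mod@metabolites <- model@metabolites[keepMet, , drop = FALSE]
  mod@stoichiometry <- S[keepMet, , drop = FALSE]
  mod@gpr <- model@gpr[keep]
  validObject(mod)
  mod
}

#' Set flux bounds on a reaction
#'
#' @param model a [MetabolicModel-class].
#' @param id reaction id.
#' @param lower,upper new bounds; either may be \code{NA} to keep the
#'   current value.
#' @return the updated model.
#' @export
setBounds <- function(model, id, lower = NA, upper = NA) {
  stopifnot(is(model, "MetabolicModel"))
  j <- match(id, model@reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", id)
  if (!is.na(lower)) model@reactions$lower_bound[j] <- lower
  if (!is.na(upper)) model@reactions$upper_bound[j] <- upper
  if (model@reactions$lower_bound[j] > model@reactions$upper_bound[j])
    stop("lower bound exceeds upper bound for ", id)
  ## allow a negative lower bound only on reversible reactions
  if (!model@reactions$reversible[j] && model@reactions$lower_bound[j] < 0)
    stop("negative lower bound on irreversible reaction ", id)
  model
}

#' Reserve-mobilization pool reactions
#'
#' Pool (mobilization) reactions release stored reserves into the network:
#' they are exchange reactions (one empty side) in the
#' \code{"reserve mobilization"} subsystem. Gas/water/proton exchange and
#' demand sinks are exchanges too but are not pools and are never capped by
#' [applyRipeningConstraints()].
#'
#' @param model a [MetabolicModel-class].
#' @return character vector of reaction ids.
#' @export
poolReactions <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  rxn <- model@reactions
  rxn$id[rxn$is_exchange &
           tolower(rxn$subsystem) == "reserve mobilization"]
}
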