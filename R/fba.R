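## Flux snap tolerance: reported fluxes with |v| below this are set to exact
## zero so lever classification does not chase solver noise.
.FLUX_SNAP <- 1e-6
.RQS_ID <- "RQS"
.RQS_METABOLITES <- c("chlorogenate_c", "cyanidin_c", "ethylene_c",
                      "galacturonate_c")

#' Build the stoichiometric matrix
#'
#' Returns the metabolite-by-reaction coefficient matrix S of a model, the
#' object flux balance analysis operates on: steady state means S v = 0.
#'
#' @param model a [MetabolicModel-class].
#' @param sparse return a sparse \code{dgCMatrix} (default) or base matrix.
#' @return matrix with metabolite ids as rownames, reaction ids as colnames.
#' @export
buildStoichMatrix <- function(model, sparse = TRUE) {
  stopifnot(is(model, "MetabolicModel"))
  if (sparse) model@stoichiometry else as.matrix(model@stoichiometry)
}

#' Ripening constraint configuration
#'
#' Constructor for [RipeningConfig-class]. Defaults follow the maintenance
#' regime of the reference fruit model: NGAM ATP demand floored at
#' 1.0 mmol/gDW/h, reserve mobilization capped at 10.0, and the citrate and
#' chlorogenate mobilization pools blocked so the ripening-quality sink
#' cannot be fed by stored chlorogenate nor energy metabolism bypassed.
#'
#' @param ngam_reaction_id id of the NGAM reaction.
#' @param ngam_lower_bound strictly positive maintenance flux floor.
#' @param pool_upper_bound cap on reserve-mobilization reactions.
#' @param blocked_pools pool reaction ids fixed at (0, 0).
#' @return A [RipeningConfig-class].
#' @export
ripeningConfig <- function(ngam_reaction_id = "NGAM",
                           ngam_lower_bound = 1.0,
                           pool_upper_bound = 10.0,
                           blocked_pools = c("MOB_CIT", "MOB_CGA")) {
  cfg <- new("RipeningConfig",
             ngam_reaction_id = ngam_reaction_id,
             ngam_lower_bound = ngam_lower_bound,
             pool_upper_bound = pool_upper_bound,
             blocked_pools = blocked_pools)
  validObject(cfg)
  cfg
}

#' Append the ripening-quality sink objective
#'
#' Adds the pseudo-reaction \code{RQS} (ripening-quality sink), an
#' irreversible drain consuming one unit each of chlorogenate_c, cyanidin_c,
#' ethylene_c and galacturonate_c. Maximizing it enforces simultaneous
#' production of the four ripening-associated traits: phenylpropanoid
#' (chlorogenate), anthocyanin (cyanidin), climacteric hormone (ethylene)
#' and pectin depolymerization proxy (galacturonate).
#'
#' @param model a [MetabolicModel-class] containing the four metabolites.
#' @return the model with one extra reaction.
#' @export
addRqsObjective <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  if (.RQS_ID %in% model@reactions$id)
    stop("model already has an RQS reaction")
  missing <- setdiff(.RQS_METABOLITES, model@metabolites$id)
  if (length(missing))
    stop("metabolite(s) required by the RQS objective not in model: ",
         paste(missing, collapse = ", "))
  addReaction(model, .RQS_ID,
              paste(paste(.RQS_METABOLITES, collapse = " + "), "--> "),
              subsystem = "objective")
}

#' Apply the ripening (maintenance-regime) constraints
#'
#' Sets the NGAM lower bound to its configured strictly positive value, caps
#' every reserve-mobilization pool reaction (see [poolReactions()]) at
#' \code{pool_upper_bound}, and fixes the blocked pools at (0, 0).
#'
#' @param model a [MetabolicModel-class].
#' @param config a [RipeningConfig-class].
#' @return the constrained model.
#' @export
applyRipeningConstraints <- function(model, config = ripeningConfig()) {
  stopifnot(is(model, "MetabolicModel"), is(config, "RipeningConfig"))
  validObject(config)
  if (!config@ngam_reaction_id %in% model@reactions$id)
    stop("NGAM reaction not in model: ", config@ngam_reaction_id)
  miss <- setdiff(config@blocked_pools, model@reactions$id)
  if (length(miss))
    stop("blocked pool reaction(s) not in model: ",
         paste(miss, collapse = ", "))
  model <- setBounds(model, config@ngam_reaction_id,
                     lower = config@ngam_lower_bound)
  for (p in poolReactions(model))
    model <- setBounds(model, p,
                       upper = if (p %in% config@blocked_pools) 0
                               else config@pool_upper_bound,
                       lower = if (p %in% config@blocked_pools) 0 else NA)
  model
}

## Solve min/max c'v over the flux polytope {S v = 0, lb <= v <= ub}.
## Infinite bounds are clamped to +-1e6 so the solver works on a box.
.modelLP <- function(model, objcoef, maximize) {
  S <- as.matrix(model@stoichiometry)
  lb <- pmax(model@reactions$lower_bound, -1e6)
  ub <- pmin(model@reactions$upper_bound, 1e6)
  .lpSolve(objcoef, S, rep(0, nrow(S)), lb, ub, maximize = maximize)
}

.snap <- function(v) {
  v[abs(v) < .FLUX_SNAP] <- 0
  v
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through one objective reaction over the
#' steady-state flux polytope \{S v = 0, lb <= v <= ub\}. Infeasibility and
#' unboundedness are reported in the solution status, never as a silent
#' zero.
#'
#' @param model a constrained [MetabolicModel-class].
#' @param objective id of the objective reaction (default the RQS sink).
#' @param direction \code{"max"} or \code{"min"}.
#' @return A [FluxSolution-class].
#' @examples
#' mod <- applyRipeningConstraints(buildReferenceModel())
#' sol <- solveFBA(mod, "RQS")
#' objectiveValue(sol)
#' @export
solveFBA <- function(model, objective = .RQS_ID,
                     direction = c("max", "min")) {
  stopifnot(is(model, "MetabolicModel"))
  direction <- match.arg(direction)
  j <- match(objective, model@reactions$id)
  if (is.na(j)) stop("objective reaction not in model: ", objective)
  obj <- numeric(nrow(model@reactions))
  obj[j] <- 1
  res <- .modelLP(model, obj, maximize = direction == "max")
  fl <- if (identical(res$status, "optimal"))
    .snap(stats::setNames(res$x, model@reactions$id))
  else stats::setNames(rep(NA_real_, nrow(model@reactions)),
                       model@reactions$id)
  new("FluxSolution",
      fluxes = fl,
      objectiveValue = if (identical(res$status, "optimal")) res$objval
                       else NA_real_,
      status = res$status,
      metadata = list(objective = objective, direction = direction))
}

#' Attainable flux range of one reaction
#'
#' Variability-style pair of LPs: the minimum and maximum steady-state flux
#' through \code{reaction} subject to the model bounds and, optionally, a
#' floor on the ripening-quality sink flux.
#'
#' @param model a constrained [MetabolicModel-class].
#' @param reaction reaction id.
#' @param rqs_floor optional lower bound imposed on the RQS flux.
#' @param rqs_id id of the RQS reaction.
#' @return named numeric \code{c(min = , max = )}.
#' @export
fluxRange <- function(model, reaction, rqs_floor = NULL, rqs_id = .RQS_ID) {
  stopifnot(is(model, "MetabolicModel"))
  j <- match(reaction, model@reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", reaction)
  if (!is.null(rqs_floor))
    model <- setBounds(model, rqs_id, lower = rqs_floor)
  obj <- numeric(nrow(model@reactions))
  obj[j] <- 1
  lo <- .modelLP(model, obj, maximize = FALSE)
  hi <- .modelLP(model, obj, maximize = TRUE)
  if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal"))
    stop("flux range LP not optimal (", lo$status, "/", hi$status,
         "): infeasible constraints?")
  c(min = lo$objval, max = hi$objval)
}

#' Smallest flux magnitude a reaction must carry
#'
#' The minimum attainable |v| through \code{reaction} over all steady-state
#' solutions sustaining at least \code{rqs_floor} units of ripening-quality
#' sink flux. Solved as two LPs (minimize and maximize v): if even the
#' maximum is negative the reaction is forced backwards with magnitude
#' -max; if the minimum is positive it is forced forwards with magnitude
#' min; otherwise zero flux is attainable and the reaction is not required.
#'
#' @inheritParams fluxRange
#' @param rqs_floor lower bound imposed on the RQS flux; must be feasible.
#' @return nonnegative flux magnitude.
#' @export
minRequiredFlux <- function(model, reaction, rqs_floor, rqs_id = .RQS_ID) {
  rng <- tryCatch(fluxRange(model, reaction, rqs_floor, rqs_id),
                  error = function(e)
                    stop("RQS floor ", rqs_floor, " infeasible: ",
                         conditionMessage(e), call. = FALSE))
  mag <- max(0, rng[["min"]], -rng[["max"]])
  if (mag < .FLUX_SNAP) 0 else mag
}

#' @describeIn FluxSolution-class named flux vector.
#' @param x a \code{FluxSolution}.
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @describeIn FluxSolution-class optimal objective value.
#' @export
setMethod("objectiveValue", "FluxSolution", function(x) x@objectiveValue)

#' @describeIn FluxSolution-class solver status string.
#' @export
setMethod("solverStatus", "FluxSolution", function(x) x@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution: status", object@status)
  if (identical(object@status, "optimal")) {
    cat(", objective", format(object@objectiveValue, digits = 6))
    nz <- sum(object@fluxes != 0)
    cat(", ", nz, " of ", length(object@fluxes),
        " reactions carry flux", sep = "")
  }
  cat("\n")
})
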