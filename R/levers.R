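#' Transcriptome-weighted minimum-flux solution
#'
#' Solves the soft-penalty parsimonious problem: fix the ripening-quality
#' sink flux at \code{rqs_target} and minimize the weighted total flux
#' \deqn{\min \sum_i w_i (v_i^+ + v_i^-) \quad s.t. \quad S v = 0,\;
#'   lb \le v \le ub,\; v_{RQS} = rqs\_target,}
#' where each net flux is split into nonnegative forward and reverse parts
#' (\eqn{v = v^+ - v^-}) so that the weighted absolute value is linear.
#' Reactions whose genes are transcriptionally downregulated carry larger
#' weights and are avoided wherever an alternative route exists; flux they
#' keep despite the penalty is structurally required.
#'
#' @param model a constrained [MetabolicModel-class] containing the RQS.
#' @param weights a [ReactionWeightSet-class] covering the model reactions.
#' @param rqs_target strictly positive RQS flux to sustain (default 1).
#' @param rqs_id id of the RQS reaction.
#' @return A [FluxSolution-class]; \code{objectiveValue} is the weighted
#'   total flux.
#' @export
minWeightedFlux <- function(model, weights, rqs_target = 1,
                            rqs_id = .RQS_ID) {
  stopifnot(is(model, "MetabolicModel"), is(weights, "ReactionWeightSet"))
  validObject(weights)
  if (rqs_target <= 0) stop("rqs_target must be strictly positive")
  if (!rqs_id %in% model@reactions$id)
    stop("RQS reaction not in model: ", rqs_id)
  wtab <- weights@table
  w <- stats::setNames(wtab$weight, wtab$reaction_id)[model@reactions$id]
  if (any(is.na(w)))
    stop("weight set does not cover all model reactions")
  if (any(w <= 0)) stop("non-positive reaction weight")

  model <- setBounds(model, rqs_id, lower = rqs_target, upper = rqs_target)
  S <- as.matrix(model@stoichiometry)
  lb <- pmax(model@reactions$lower_bound, -1e6)
  ub <- pmin(model@reactions$upper_bound, 1e6)
  n <- length(lb)
  ## v = f - r with f, r >= 0; positive weights make f*r = 0 at optimum
  Aeq <- cbind(S, -S)
  lbf <- c(pmax(lb, 0), pmax(-ub, 0))
  ubf <- c(pmax(ub, 0), pmax(-lb, 0))
  res <- .lpSolve(c(w, w), Aeq, rep(0, nrow(S)), lbf, ubf)
  if (!identical(res$status, "optimal"))
    stop("weighted flux minimization ", res$status,
         " at rqs_target = ", rqs_target)
  v <- .snap(stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)],
                             model@reactions$id))
  new("FluxSolution", fluxes = v, objectiveValue = res$objval,
      status = "optimal",
      metadata = list(objective = "weighted minimum total flux",
                      rqs_target = rqs_target,
                      scheme = weights@scheme))
}

#' Normalize a flux solution by the RQS flux
#'
#' Expresses each reaction's absolute flux per unit of ripening-quality
#' sink flux, the scale on which lever magnitudes are reported; the RQS
#' itself maps to 1.
#'
#' @param solution a [FluxSolution-class].
#' @param rqs_flux strictly positive RQS flux of that solution.
#' @return named numeric vector of normalized magnitudes.
#' @export
normalizeSolution <- function(solution, rqs_flux) {
  stopifnot(is(solution, "FluxSolution"))
  if (!is.numeric(rqs_flux) || length(rqs_flux) != 1L || rqs_flux <= 0)
    stop("rqs_flux must be a single strictly positive flux")
  abs(solution@fluxes) / rqs_flux
}

#' Detect regulatory lever reactions
#'
#' A reaction is a regulatory lever for a contrast when (a) its
#' transcriptional class is \code{down} and (b) it cannot reach zero flux in
#' any steady-state solution sustaining the RQS target
#' ([minRequiredFlux()] > \code{eps}). Requiredness is evaluated by
#' per-reaction flux-range LPs, so the lever call is immune to alternate
#' optima of the penalized solution; the penalized solution only provides
#' the reported direction and normalized magnitude.
#'
#' @param model a constrained [MetabolicModel-class] containing the RQS.
#' @param weights a [ReactionWeightSet-class].
#' @param classes named character vector reaction id -> class (defaults to
#'   the classes stored in \code{weights}).
#' @param rqs_target strictly positive RQS flux to sustain.
#' @param eps activity threshold separating numerical noise from genuine
#'   required flux (default 1e-6).
#' @param rqs_id id of the RQS reaction.
#' @return \code{DataFrame} with one row per lever: \code{reaction_id},
#'   \code{class}, \code{required}, \code{normalized_magnitude},
#'   \code{direction} (\code{"forward (-->)"}, \code{"reverse (<--)"} or
#'   \code{"irreversible"}).
#' @export
detectLevers <- function(model, weights, classes = reactionClasses(weights),
                         rqs_target = 1, eps = .FLUX_SNAP,
                         rqs_id = .RQS_ID) {
  stopifnot(is(model, "MetabolicModel"), eps > 0)
  sol <- minWeightedFlux(model, weights, rqs_target, rqs_id)
  nmag <- normalizeSolution(sol, rqs_target)
  cand <- names(classes)[classes == "down"]
  cand <- intersect(model@reactions$id, cand)
  rows <- lapply(cand, function(r) {
    mag <- minRequiredFlux(model, r, rqs_floor = rqs_target, rqs_id = rqs_id)
    if (mag <= eps) return(NULL)
    j <- match(r, model@reactions$id)
    dir <- if (!model@reactions$reversible[j]) "irreversible"
           else if (sol@fluxes[[r]] >= 0) "forward (-->)"
           else "reverse (<--)"
    DataFrame(reaction_id = r, class = "down", required = TRUE,
              normalized_magnitude = nmag[[r]], direction = dir)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows)
  else DataFrame(reaction_id = character(0), class = character(0),
                 required = logical(0), normalized_magnitude = numeric(0),
                 direction = character(0))
}

#' Full per-contrast lever analysis
#'
#' End-to-end pipeline for one expression contrast: apply the ripening
#' constraints, check that the FBA optimum can sustain the RQS target
#' (feasibility gate), classify genes and reactions, build penalty weights,
#' solve the weighted minimum-flux problem at the RQS target and detect
#' levers with normalized magnitudes and directions.
#'
#' @param model a [MetabolicModel-class] containing the RQS reaction
#'   (constraints are applied internally from \code{config}).
#' @param contrast an [ExpressionContrast-class].
#' @param config a [RipeningConfig-class].
#' @param scheme penalty weight scheme (see [defaultWeightScheme()]).
#' @param lfc_threshold,require_significance gene classification
#'   parameters, see [classifyGenes()].
#' @param rqs_target RQS flux to sustain (default 1 flux unit, which makes
#'   normalized magnitudes well defined and independent of pool caps).
#' @param eps lever activity threshold.
#' @return A [LeverReport-class].
#' @examples
#' mod <- buildReferenceModel()
#' rep <- runContrastAnalysis(mod, scenarioContrast("MG_E1vsE2", seed = 1))
#' leverTable(rep)
#' @export
runContrastAnalysis <- function(model, contrast, config = ripeningConfig(),
                                scheme = defaultWeightScheme(),
                                lfc_threshold = 1,
                                require_significance = TRUE,
                                rqs_target = 1, eps = .FLUX_SNAP) {
  stopifnot(is(model, "MetabolicModel"), is(contrast, "ExpressionContrast"))
  model <- applyRipeningConstraints(model, config)
  opt <- solveFBA(model, .RQS_ID, "max")
  if (!identical(solverStatus(opt), "optimal") ||
      objectiveValue(opt) < rqs_target - 1e-9)
    stop("model cannot sustain rqs_target = ", rqs_target,
         " (FBA optimum ", format(objectiveValue(opt)), ")")
  gcl <- classifyGenes(contrast, lfc_threshold, require_significance)
  rcl <- classifyReactions(model, gcl, warn_missing = FALSE)
  w <- reactionWeights(model, rcl, scheme)
  lev <- detectLevers(model, w, rcl, rqs_target, eps)
  if (nrow(lev)) lev$contrast <- contrast@contrastId
  else lev$contrast <- character(0)
  lev <- lev[, c("reaction_id", "contrast", "class", "required",
                 "normalized_magnitude", "direction")]
  new("LeverReport", contrastId = contrast@contrastId, records = lev,
      metadata = list(scheme = scheme, lfc_threshold = lfc_threshold,
                      require_significance = require_significance,
                      rqs_target = rqs_target, eps = eps,
                      fba_optimum = objectiveValue(opt),
                      snap_tolerance = .FLUX_SNAP))
}

#' @describeIn LeverReport-class the lever record table.
#' @param x a \code{LeverReport}.
#' @export
setMethod("leverTable", "LeverReport", function(x) x@records)

#' @describeIn LeverReport-class the contrast identifier.
#' @export
setMethod("contrastId", "LeverReport", function(x) x@contrastId)

setMethod("show", "LeverReport", function(object) {
  cat("LeverReport for contrast", object@contrastId, "-",
      nrow(object@records), "lever reaction(s)\n")
  if (nrow(object@records)) print(as.data.frame(object@records))
})

#' Union of lever reactions across reports
#'
#' @param reports list of [LeverReport-class] objects.
#' @return sorted character vector of distinct lever reaction ids.
#' @export
leverUnion <- function(reports) {
  sort(unique(unlist(lapply(reports, function(r) {
    stopifnot(is(r, "LeverReport"))
    r@records$reaction_id
  }), use.names = FALSE)))
}
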