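#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Boolean gene-protein-reaction rule
#'
#' A \code{GprRule} holds the boolean association between genes and a
#' reaction as an expression tree over gene identifiers with \code{and} /
#' \code{or} connectives (isoenzymes combine with \code{or}, complex subunits
#' with \code{and}). An empty tree means the reaction has no gene
#' association (transporters, pool and pseudo-reactions).
#'
#' @slot tree a nested list; either \code{list()} (empty rule), a leaf
#'   (\code{list(type = "leaf", gene = <id>)}) or an inner node
#'   (\code{list(type = "and"|"or", children = <list of nodes>)}).
#'
#' @seealso [parseGpr()], [gprToString()], [gprLeaves()]
#' @export
setClass("GprRule", representation(tree = "list"))

setValidity("GprRule", function(object) {
  chk <- function(node) {
    if (length(node) == 0L) return(TRUE)
    if (identical(node$type, "leaf"))
      return(is.character(node$gene) && nzchar(node$gene))
    if (!node$type %in% c("and", "or") || length(node$children) < 2L)
      return(FALSE)
    all(vapply(node$children, chk, logical(1)))
  }
  if (chk(object@tree)) TRUE else "malformed GPR expression tree"
})

#' Constraint-based metabolic network
#'
#' Columnar S4 container for a compartmented metabolic network: a metabolite
#' table, a reaction table (bounds, reversibility, subsystem, exchange flag,
#' plus any opaque annotation columns carried over from the source file), a
#' sparse stoichiometric matrix and one [GprRule-class] per reaction.
#' Metabolite identifiers carry a single compartment suffix (\code{_c}
#' cytosol, \code{_m} mitochondrion, \code{_v} vacuole). Negative
#' stoichiometric coefficients mark consumption, positive production.
#'
#' Models are normally created by [readReactionTable()] or
#' [buildReferenceModel()], not by calling \code{new()} directly.
#'
#' @slot name model name.
#' @slot metabolites \code{DataFrame} with columns \code{id},
#'   \code{base_name}, \code{compartment}.
#' @slot reactions \code{DataFrame} with columns \code{id},
#'   \code{reversible}, \code{lower_bound}, \code{upper_bound},
#'   \code{subsystem}, \code{is_exchange}; extra columns are preserved
#'   verbatim.
#' @slot stoichiometry sparse \code{dgCMatrix}, metabolites x reactions.
#' @slot gpr list of [GprRule-class], one per reaction.
#'
#' @seealso [readReactionTable()], [solveFBA()], [buildReferenceModel()]
#' @export
setClass("MetabolicModel", representation(
  name = "character",
  metabolites = "DataFrame",
  reactions = "DataFrame",
  stoichiometry = "Matrix",
  gpr = "list"
))

.validCompartments <- c("c", "m", "v")

setValidity("MetabolicModel", function(object) {
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  msg <- character(0)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (nrow(met)) {
    suf <- sub("^.*_([cmv])$", "\\1", met$id)
    bad <- !grepl("^.+_[cmv]$", met$id)
    if (any(bad))
      msg <- c(msg, paste0("metabolite id without compartment suffix: ",
                           paste(met$id[bad], collapse = ", ")))
    if (!all(suf[!bad] == met$compartment[!bad]))
      msg <- c(msg, "compartment column disagrees with id suffix")
    if (any(!nzchar(met$base_name))) msg <- c(msg, "empty metabolite base name")
  }
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msg <- c(msg, "stoichiometric matrix dimensions do not match tables")
  if (nrow(rxn)) {
    if (any(rxn$lower_bound > rxn$upper_bound))
      msg <- c(msg, "lower bound exceeds upper bound")
    if (any(!rxn$reversible & rxn$lower_bound < 0))
      msg <- c(msg, "irreversible reaction with negative lower bound")
    if (any(Matrix::colSums(S != 0) == 0))
      msg <- c(msg, "reaction with no nonzero stoichiometric coefficient")
  }
  if (length(object@gpr) != nrow(rxn))
    msg <- c(msg, "need exactly one GPR rule per reaction")
  if (length(msg)) msg else TRUE
})

#' Ripening constraint configuration
#'
#' Bundle of the maintenance-regime constraints applied to a fruit model:
#' which reaction carries the non-growth-associated maintenance (NGAM) ATP
#' demand and its strictly positive lower bound (default 1.0 mmol/gDW/h), the
#' shared upper bound on reserve-mobilization pool reactions (default 10.0),
#' and the pool reactions blocked outright so that the network cannot bypass
#' de novo synthesis (by default the citrate and chlorogenate mobilization
#' pools).
#'
#' @slot ngam_reaction_id id of the NGAM ATP-hydrolysis reaction.
#' @slot ngam_lower_bound flux floor for NGAM, must be > 0.
#' @slot pool_upper_bound cap applied to reserve-mobilization reactions.
#' @slot blocked_pools ids of pool reactions fixed at (0, 0).
#'
#' @seealso [ripeningConfig()], [applyRipeningConstraints()]
#' @export
setClass("RipeningConfig", representation(
  ngam_reaction_id = "character",
  ngam_lower_bound = "numeric",
  pool_upper_bound = "numeric",
  blocked_pools = "character"
))

setValidity("RipeningConfig", function(object) {
  msg <- character(0)
  if (length(object@ngam_lower_bound) != 1L || object@ngam_lower_bound <= 0)
    msg <- c(msg, "ngam_lower_bound must be a single strictly positive flux")
  if (length(object@pool_upper_bound) != 1L || object@pool_upper_bound < 0)
    msg <- c(msg, "pool_upper_bound must be a single nonnegative flux")
  if (length(msg)) msg else TRUE
})

#' Differential-expression contrast
#'
#' Per-gene log2 fold-changes with significance calls for one variety-by-
#' transition comparison (e.g. harvest vs shelf-life in one cultivar).
#'
#' @slot contrastId identifier such as \code{"MG_E1vsE2"}.
#' @slot records \code{DataFrame} with columns \code{gene_id} (unique),
#'   \code{log2fc} (finite) and \code{significant} (logical).
#'
#' @seealso [classifyGenes()], [scenarioContrast()]
#' @export
setClass("ExpressionContrast", representation(
  contrastId = "character",
  records = "DataFrame"
))

setValidity("ExpressionContrast", function(object) {
  rec <- object@records
  msg <- character(0)
  need <- c("gene_id", "log2fc", "significant")
  if (!all(need %in% colnames(rec)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (any(!nzchar(rec$gene_id))) msg <- c(msg, "empty gene id")
  if (anyDuplicated(rec$gene_id)) msg <- c(msg, "duplicated gene id")
  if (any(!is.finite(rec$log2fc))) msg <- c(msg, "non-finite log2fc")
  if (length(msg)) msg else TRUE
})

#' Per-reaction transcriptional penalty weights
#'
#' Maps every reaction of a model to a transcriptional class (\code{up},
#' \code{down}, \code{neutral} or \code{mixed}, aggregated from gene classes
#' through the GPR rule) and to the strictly positive penalty weight used in
#' transcriptome-weighted flux minimization. The weight scheme must satisfy
#' weight(down) > weight(mixed) > weight(neutral) > weight(up) > 0 so that
#' transcriptionally disfavored reactions are penalized more than favored
#' ones, with conflicting evidence in between.
#'
#' @slot table \code{DataFrame} with columns \code{reaction_id},
#'   \code{class}, \code{weight}.
#' @slot scheme named numeric vector mapping class to weight.
#'
#' @seealso [reactionWeights()], [minWeightedFlux()]
#' @export
setClass("ReactionWeightSet", representation(
  table = "DataFrame",
  scheme = "numeric"
))

setValidity("ReactionWeightSet", function(object) {
  s <- object@scheme
  msg <- character(0)
  if (!all(c("down", "mixed", "neutral", "up") %in% names(s)))
    return("scheme must name weights for down, mixed, neutral and up")
  if (any(s <= 0)) msg <- c(msg, "weights must be strictly positive")
  if (!(s["down"] > s["mixed"] && s["mixed"] > s["neutral"] &&
        s["neutral"] > s["up"]))
    msg <- c(msg, "weights must be ordered down > mixed > neutral > up")
  if (any(object@table$weight <= 0))
    msg <- c(msg, "per-reaction weights must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Steady-state flux distribution
#'
#' Result of one linear-programming solve: the flux vector, the objective
#' value and the solver status. Fluxes below the snap tolerance are reported
#' as exact zeros. When the status is \code{"optimal"} the vector satisfies
#' mass balance (S v = 0) and all bounds to solver tolerance.
#'
#' @slot fluxes named numeric vector of fluxes (mmol/gDW/h), one per reaction.
#' @slot objectiveValue optimal objective value.
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @slot metadata list of solver details (objective spec, tolerances).
#'
#' @seealso [solveFBA()], [minWeightedFlux()]
#' @export
setClass("FluxSolution", representation(
  fluxes = "numeric",
  objectiveValue = "numeric",
  status = "character",
  metadata = "list"
))

#' Regulatory-lever report
#'
#' Levers are reactions that must carry flux to sustain the ripening-quality
#' sink even though their genes are transcriptionally downregulated in the
#' contrast analyzed. The report lists one record per lever with its
#' normalized flux magnitude (flux per unit RQS flux) and net direction,
#' plus solver metadata (weight scheme, thresholds, tolerances).
#'
#' @slot contrastId the expression contrast analyzed.
#' @slot records \code{DataFrame} with columns \code{reaction_id},
#'   \code{contrast}, \code{class}, \code{required},
#'   \code{normalized_magnitude}, \code{direction}.
#' @slot metadata list (weight scheme, rqs target, eps, DE thresholds).
#'
#' @seealso [detectLevers()], [runContrastAnalysis()]
#' @export
setClass("LeverReport", representation(
  contrastId = "character",
  records = "DataFrame",
  metadata = "list"
))
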