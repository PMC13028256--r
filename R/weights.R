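.CLASS_LEVELS <- c("up", "neutral", "mixed", "down")
## penalty rank used for GPR aggregation: higher = more penalized
.classRank <- c(up = 1, neutral = 2, mixed = 3, down = 4)

#' Expression contrast constructor
#'
#' @param contrast_id identifier such as \code{"MG_E1vsE2"}.
#' @param gene_id,log2fc,significant parallel per-gene vectors.
#' @return An [ExpressionContrast-class].
#' @export
expressionContrast <- function(contrast_id, gene_id, log2fc, significant) {
  ## exact duplicate records collapse silently; conflicting duplicates are
  ## rejected by the class validity check
  rec <- unique(data.frame(gene_id = as.character(gene_id),
                           log2fc = as.numeric(log2fc),
                           significant = as.logical(significant),
                           stringsAsFactors = FALSE))
  obj <- new("ExpressionContrast", contrastId = contrast_id,
             records = DataFrame(rec, row.names = NULL))
  validObject(obj)
  obj
}

#' Read / write a contrast TSV
#'
#' Tab-delimited dialect: columns \code{gene_id}, \code{log2fc},
#' \code{significant} (0/1), with a header row.
#'
#' @param file path.
#' @param contrast_id id for the returned object; defaults to the file
#'   base name.
#' @return An [ExpressionContrast-class].
#' @export
readContrast <- function(file, contrast_id = NULL) {
  if (is.null(contrast_id))
    contrast_id <- sub("\\.[^.]*$", "", basename(file))
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  expressionContrast(contrast_id, d$gene_id, d$log2fc,
                     as.logical(d$significant))
}

#' @rdname readContrast
#' @param contrast an [ExpressionContrast-class].
#' @export
writeContrast <- function(contrast, file) {
  stopifnot(is(contrast, "ExpressionContrast"))
  d <- as.data.frame(contrast@records)
  d$significant <- as.integer(d$significant)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @describeIn ExpressionContrast-class the contrast identifier.
#' @param x an \code{ExpressionContrast}.
#' @export
setMethod("contrastId", "ExpressionContrast", function(x) x@contrastId)

setMethod("show", "ExpressionContrast", function(object) {
  cat("ExpressionContrast", object@contrastId, "with",
      nrow(object@records), "genes\n")
})

#' Classify genes as up, down or neutral
#'
#' A gene is \code{up} when its log2 fold-change is at least
#' \code{lfc_threshold} (and significant, when significance is required),
#' \code{down} when at most \code{-lfc_threshold}, otherwise
#' \code{neutral}. There is no \code{mixed} class at the gene level.
#'
#' @param contrast an [ExpressionContrast-class].
#' @param lfc_threshold strictly positive |log2FC| cutoff (default 1).
#' @param require_significance require the significance flag for an
#'   up/down call (default TRUE).
#' @return named character vector, gene id -> class.
#' @export
classifyGenes <- function(contrast, lfc_threshold = 1,
                          require_significance = TRUE) {
  stopifnot(is(contrast, "ExpressionContrast"), lfc_threshold > 0)
  rec <- contrast@records
  pass <- if (require_significance) rec$significant else TRUE
  cls <- ifelse(rec$log2fc >= lfc_threshold & pass, "up",
         ifelse(rec$log2fc <= -lfc_threshold & pass, "down", "neutral"))
  stats::setNames(cls, rec$gene_id)
}

#' Aggregate gene classes through a GPR rule
#'
#' Recursive aggregation mirroring enzyme logic: an \code{and} node (enzyme
#' complex) takes its most-penalized child (down > mixed > neutral > up) —
#' one missing subunit compromises the complex; an \code{or} node
#' (isoenzymes) takes its least-penalized child, except that strictly
#' conflicting isoenzyme evidence (some up, some down) is treated
#' conservatively as \code{mixed}. Reactions with no gene association are
#' always \code{neutral}; genes absent from \code{gene_classes} count as
#' neutral.
#'
#' @param gpr a [GprRule-class].
#' @param gene_classes named character vector from [classifyGenes()].
#' @return one of \code{"up"}, \code{"down"}, \code{"neutral"},
#'   \code{"mixed"}.
#' @export
classifyReaction <- function(gpr, gene_classes) {
  stopifnot(is(gpr, "GprRule"))
  agg <- function(node) {
    if (identical(node$type, "leaf")) {
      cl <- gene_classes[node$gene]
      if (is.na(cl)) "neutral" else unname(cl)
    } else {
      kids <- vapply(node$children, agg, character(1))
      if (node$type == "and") {
        kids[which.max(.classRank[kids])]
      } else {
        if (any(kids == "up") && any(kids == "down")) "mixed"
        else kids[which.min(.classRank[kids])]
      }
    }
  }
  if (length(gpr@tree) == 0L) return("neutral")
  unname(agg(gpr@tree))
}

#' Classify every reaction of a model
#'
#' Applies [classifyReaction()] to each reaction's GPR. Genes that appear in
#' GPR rules but not in the classification are treated as neutral with one
#' summary warning (transcript evidence never forces a reaction off).
#'
#' @param model a [MetabolicModel-class].
#' @param gene_classes named character vector from [classifyGenes()].
#' @param warn_missing warn about GPR genes without expression records.
#' @return named character vector, reaction id -> class.
#' @export
classifyReactions <- function(model, gene_classes, warn_missing = TRUE) {
  stopifnot(is(model, "MetabolicModel"))
  if (warn_missing) {
    miss <- setdiff(genes(model), names(gene_classes))
    if (length(miss))
      warning(length(miss), " GPR gene(s) without expression records, ",
              "treated as neutral: ",
              paste(utils::head(miss, 5), collapse = ", "),
              if (length(miss) > 5) ", ...")
  }
  vapply(stats::setNames(model@gpr, model@reactions$id), classifyReaction,
         character(1), gene_classes = gene_classes)
}

#' Default transcriptional penalty scheme
#'
#' Weights used in transcriptome-weighted flux minimization. Only the
#' ordering down > mixed > neutral > up is biologically meaningful; the
#' default magnitudes \{down 2.0, mixed 1.5, neutral 1.0, up 0.5\} are a
#' moderate choice with a down/up ratio of 4.
#'
#' @return named numeric vector over the four classes.
#' @export
defaultWeightScheme <- function() {
  c(down = 2.0, mixed = 1.5, neutral = 1.0, up = 0.5)
}

#' Per-reaction penalty weights from transcriptional classes
#'
#' Maps each model reaction to (class, scheme[class]); reactions absent from
#' \code{classes} default to neutral. The scheme must respect the penalty
#' ordering down > mixed > neutral > up with all weights positive, otherwise
#' it is rejected.
#'
#' @param model a [MetabolicModel-class].
#' @param classes named character vector, reaction id -> class (e.g. from
#'   [classifyReactions()]).
#' @param scheme class -> weight mapping, see [defaultWeightScheme()].
#' @return A [ReactionWeightSet-class].
#' @export
reactionWeights <- function(model, classes = character(0),
                            scheme = defaultWeightScheme()) {
  stopifnot(is(model, "MetabolicModel"))
  ids <- model@reactions$id
  cls <- stats::setNames(rep("neutral", length(ids)), ids)
  known <- intersect(names(classes), ids)
  cls[known] <- classes[known]
  if (!all(cls %in% .CLASS_LEVELS))
    stop("unknown reaction class: ",
         paste(setdiff(unique(cls), .CLASS_LEVELS), collapse = ", "))
  obj <- new("ReactionWeightSet",
             table = DataFrame(reaction_id = ids, class = unname(cls),
                               weight = unname(scheme[cls])),
             scheme = scheme)
  validObject(obj)
  obj
}

#' @describeIn ReactionWeightSet-class the (reaction, class, weight) table.
#' @param x a \code{ReactionWeightSet}.
#' @export
setMethod("weightTable", "ReactionWeightSet", function(x) x@table)

#' @describeIn ReactionWeightSet-class named class vector
#'   (reaction id -> class).
#' @export
setMethod("reactionClasses", "ReactionWeightSet", function(x)
  stats::setNames(x@table$class, x@table$reaction_id))

setMethod("show", "ReactionWeightSet", function(object) {
  cat("ReactionWeightSet over", nrow(object@table), "reactions;",
      "scheme:", paste(names(object@scheme), object@scheme,
                       sep = "=", collapse = ", "), "\n")
  print(table(object@table$class))
})
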