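#' @importFrom Matrix sparseMatrix colSums rowSums t
NULL

## Assemble a MetabolicModel from parallel per-reaction vectors. `stoich` is a
## list of named numeric vectors; annotations (extra table columns) are
## carried as-is.
.makeModel <- function(ids, stoich, reversible, lower, upper, gpr,
                       subsystem, is_exchange, annotations = NULL,
                       name = "model") {
  n <- length(ids)
  if (anyDuplicated(ids))
    stop("duplicate reaction id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  metIds <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  bad <- metIds[!grepl("^.+_[cmv]$", metIds)]
  if (length(bad))
    stop("metabolite id without compartment suffix (_c, _m or _v): ",
         paste(bad, collapse = ", "))
  met <- DataFrame(
    id = metIds,
    base_name = sub("_[cmv]$", "", metIds),
    compartment = sub("^.*_([cmv])$", "\\1", metIds)
  )
  triplets <- do.call(rbind, lapply(seq_len(n), function(j) {
    st <- stoich[[j]]
    if (length(st) == 0L) return(NULL)
    cbind(match(names(st), metIds), j, unname(st))
  }))
  S <- if (is.null(triplets))
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(metIds), n),
                         dimnames = list(metIds, ids))
  else
    Matrix::sparseMatrix(i = triplets[, 1], j = triplets[, 2],
                         x = triplets[, 3],
                         dims = c(length(metIds), n),
                         dimnames = list(metIds, ids))
  rxn <- DataFrame(
    id = ids,
    reversible = reversible,
    lower_bound = lower,
    upper_bound = upper,
    subsystem = subsystem,
    is_exchange = is_exchange
  )
  if (!is.null(annotations) && ncol(annotations))
    rxn <- cbind(rxn, annotations)
  gpr <- lapply(gpr, function(g) if (is(g, "GprRule")) g else parseGpr(g))
  names(gpr) <- ids
  new("MetabolicModel", name = name, metabolites = met, reactions = rxn,
      stoichiometry = S, gpr = gpr)
}

.DEFAULT_UB <- 1000

.headerAliases <- c(id = "id", equation = "equation", gpr = "gpr",
                    subsystem = "subsystem", lb = "lower_bound",
                    lower_bound = "lower_bound", ub = "upper_bound",
                    upper_bound = "upper_bound")

#' Read a curated reaction table
#'
#' Reads the tab-delimited curated reaction-list dialect: columns \code{id},
#' \code{equation}, \code{gpr}, \code{subsystem} and optional
#' \code{lower_bound} / \code{upper_bound} (aliases \code{lb}, \code{ub}), a
#' header row permitted, \code{#}-prefixed comment lines skipped. Unknown
#' columns are preserved as opaque annotations. Missing bounds default to
#' (0, 1000) for irreversible and (-1000, 1000) for reversible reactions.
#'
#' @param file path to a UTF-8 tab-delimited file, or \code{NULL} when
#'   \code{text} is given.
#' @param text optional character vector of raw lines (overrides
#'   \code{file}).
#' @param name model name.
#' @return A validated [MetabolicModel-class].
#' @examples
#' txt <- c("id\tequation\tgpr\tsubsystem",
#'          "FUM_m\tfum_m + h2o_m <=> mal_m\tG_FUM_m\tTCA cycle")
#' readReactionTable(text = txt)
#' @seealso [writeReactionTable()], [parseReactionEquation()]
#' @export
readReactionTable <- function(file = NULL, text = NULL, name = "model") {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    text <- readLines(file, encoding = "UTF-8")
    if (identical(name, "model"))
      name <- sub("\\.[^.]*$", "", basename(file))
  }
  keep <- !grepl("^[[:space:]]*#", text) & nzchar(trimws(text))
  lineno <- which(keep)
  rows <- strsplit(text[keep], "\t", fixed = TRUE)

  colNames <- c("id", "equation", "gpr", "subsystem", "lower_bound",
                "upper_bound")
  if (length(rows) && tolower(trimws(rows[[1]][1])) == "id") {
    hdr <- tolower(trimws(rows[[1]]))
    colNames <- ifelse(hdr %in% names(.headerAliases),
                       .headerAliases[hdr], trimws(rows[[1]]))
    rows <- rows[-1]
    lineno <- lineno[-1]
  }
  if (length(rows) == 0L) {
    warning("empty reaction table: returning a model with 0 reactions")
    return(.makeModel(character(0), list(), logical(0), numeric(0),
                      numeric(0), list(), character(0), logical(0),
                      name = name))
  }

  getcol <- function(fields, col) {
    i <- match(col, colNames)
    if (is.na(i) || i > length(fields)) NA_character_
    else trimws(fields[i])
  }
  n <- length(rows)
  ids <- character(n); stoich <- vector("list", n)
  rev <- logical(n); exch <- logical(n)
  lbv <- numeric(n); ubv <- numeric(n)
  gprs <- vector("list", n); subsys <- character(n)
  extraCols <- setdiff(colNames[!is.na(colNames)],
                       unname(.headerAliases))
  extras <- if (length(extraCols))
    as.data.frame(matrix(NA_character_, n, length(extraCols),
                         dimnames = list(NULL, extraCols)),
                  stringsAsFactors = FALSE)
  else NULL

  for (k in seq_len(n)) {
    fields <- rows[[k]]
    parsed <- tryCatch({
      id <- getcol(fields, "id")
      if (is.na(id) || !nzchar(id)) stop("missing reaction id")
      eq <- getcol(fields, "equation")
      if (is.na(eq) || !nzchar(eq)) stop("missing equation")
      pe <- parseReactionEquation(eq)
      if (length(pe$stoichiometry) == 0L)
        stop("equation with no net stoichiometry")
      lb <- suppressWarnings(as.numeric(getcol(fields, "lower_bound")))
      ub <- suppressWarnings(as.numeric(getcol(fields, "upper_bound")))
      if (is.na(lb)) lb <- if (pe$reversible) -.DEFAULT_UB else 0
      if (is.na(ub)) ub <- .DEFAULT_UB
      g <- getcol(fields, "gpr")
      list(id = id, pe = pe, lb = lb, ub = ub,
           gpr = parseGpr(if (is.na(g)) "" else g),
           subsystem = {
             s <- getcol(fields, "subsystem")
             if (is.na(s)) "" else s
           })
    }, error = function(e)
      stop("reaction table line ", lineno[k], ": ", conditionMessage(e),
           call. = FALSE))
    ids[k] <- parsed$id
    stoich[[k]] <- parsed$pe$stoichiometry
    rev[k] <- parsed$pe$reversible
    exch[k] <- parsed$pe$is_exchange
    lbv[k] <- parsed$lb; ubv[k] <- parsed$ub
    gprs[[k]] <- parsed$gpr
    subsys[k] <- parsed$subsystem
    if (!is.null(extras))
      for (ec in extraCols)
        extras[k, ec] <- getcol(fields, ec)
  }
  mod <- .makeModel(ids, stoich, rev, lbv, ubv, gprs, subsys, exch,
                    annotations = if (is.null(extras)) NULL
                                  else DataFrame(extras),
                    name = name)
  validObject(mod)
  mod
}

#' Write a model as a curated reaction table
#'
#' Emits the same tab-delimited dialect accepted by [readReactionTable()]
#' (header row, unit coefficients omitted, \code{<=>} for reversible
#' reactions, explicit bounds, annotation columns appended), so that
#' \code{readReactionTable(text = writeReactionTable(m))} reconstructs
#' \code{m}.
#'
#' @param model a [MetabolicModel-class].
#' @param file optional path; when \code{NULL} the lines are returned.
#' @return character vector of lines, invisibly when written to a file.
#' @export
writeReactionTable <- function(model, file = NULL) {
  stopifnot(is(model, "MetabolicModel"))
  rxn <- model@reactions
  S <- model@stoichiometry
  core <- c("id", "reversible", "lower_bound", "upper_bound", "subsystem",
            "is_exchange")
  extraCols <- setdiff(colnames(rxn), core)
  header <- paste(c("id", "equation", "gpr", "subsystem", "lower_bound",
                    "upper_bound", extraCols), collapse = "\t")
  lines <- vapply(seq_len(nrow(rxn)), function(j) {
    st <- S[, j]
    st <- st[st != 0]
    eq <- formatReactionEquation(st, rxn$reversible[j])
    extra <- if (length(extraCols))
      vapply(extraCols, function(ec) {
        v <- rxn[[ec]][j]
        if (is.na(v)) "" else as.character(v)
      }, character(1))
    else character(0)
    paste(c(rxn$id[j], eq, gprToString(model@gpr[[j]]), rxn$subsystem[j],
            format(rxn$lower_bound[j], digits = 12),
            format(rxn$upper_bound[j], digits = 12), extra),
          collapse = "\t")
  }, character(1))
  out <- c(header, lines)
  if (is.null(file)) return(out)
  writeLines(out, file, useBytes = TRUE)
  invisible(out)
}
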