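# Independent constraint-based-modeling oracle: the same reaction table is
# loaded by cobrapy (via the `python` interpreter on PATH) and optimized with
# its own LP stack. Used to cross-check FBA objectives and weighted
# minimum-flux solutions computed by this package.

.oraclePy <- '
import json, sys
from cobra import Model, Reaction, Metabolite

def parse_side(side, sign, stoich):
    side = side.strip()
    if not side:
        return
    for term in side.split(" + "):
        parts = term.split()
        coef, met = (1.0, parts[0]) if len(parts) == 1 else (float(parts[0]), parts[1])
        stoich[met] = stoich.get(met, 0.0) + sign * coef

def load_model(path):
    m = Model("oracle")
    mets = {}
    rxns = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\\n")
            if not line.strip() or line.startswith("#"):
                continue
            f = line.split("\\t")
            if f[0] == "id":
                continue
            rid, eq = f[0], f[1]
            lb = float(f[4]) if len(f) > 4 and f[4] else None
            ub = float(f[5]) if len(f) > 5 and f[5] else None
            arrow = "<=>" if "<=>" in eq else "-->"
            lhs, rhs = eq.split(arrow)
            st = {}
            parse_side(lhs, -1.0, st)
            parse_side(rhs, +1.0, st)
            if lb is None:
                lb = -1000.0 if arrow == "<=>" else 0.0
            if ub is None:
                ub = 1000.0
            r = Reaction(rid)
            r.bounds = (lb, ub)
            rxns.append((r, st))
            for met in st:
                mets.setdefault(met, Metabolite(met))
    m.add_reactions([r for r, _ in rxns])
    for r, st in rxns:
        r.add_metabolites({mets[k]: v for k, v in st.items()})
    return m

task = json.load(open(sys.argv[1]))
m = load_model(task["model_tsv"])
if task["mode"] == "fba":
    m.objective = task["objective"]
    m.objective_direction = task.get("direction", "max")
    sol = m.optimize()
    out = {"status": sol.status,
           "objective": sol.objective_value if sol.status == "optimal" else None}
else:  # weighted minimum total flux at fixed RQS
    w = task["weights"]
    m.reactions.get_by_id(task["rqs_id"]).bounds = (task["rqs_target"],
                                                    task["rqs_target"])
    obj = m.problem.Objective(0, direction="min")
    m.objective = obj
    coefs = {}
    for r in m.reactions:
        coefs[r.forward_variable] = w[r.id]
        coefs[r.reverse_variable] = w[r.id]
    m.objective.set_linear_coefficients(coefs)
    sol = m.optimize()
    out = {"status": sol.status,
           "objective": sol.objective_value if sol.status == "optimal" else None,
           "fluxes": {r.id: sol.fluxes[r.id] for r in m.reactions}
                     if sol.status == "optimal" else None}
json.dump(out, open(sys.argv[2], "w"))
'

.oracleAvailable <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    ok <- nzchar(Sys.which("python")) &&
      system2("python", c("-c", shQuote("import cobra")),
              stdout = FALSE, stderr = FALSE) == 0
    cached <<- ok
    ok
  }
})

# Run the cobrapy oracle on a model. mode "fba": maximize/minimize one
# reaction. mode "weighted": minimize sum w_i (v_i^+ + v_i^-) with RQS fixed.
oracleSolve <- function(model, mode = "fba", objective = "RQS",
                        direction = "max", weights = NULL,
                        rqs_target = 1, rqs_id = "RQS") {
  stopifnot(.oracleAvailable())
  tsv <- tempfile(fileext = ".tsv")
  writeReactionTable(model, tsv)
  script <- tempfile(fileext = ".py")
  writeLines(.oraclePy, script)
  taskf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  task <- list(mode = mode, model_tsv = tsv, objective = objective,
               direction = direction, rqs_target = rqs_target,
               rqs_id = rqs_id)
  if (!is.null(weights)) task$weights <- as.list(weights)
  writeLines(jsonlite::toJSON(task, auto_unbox = TRUE, digits = NA), taskf)
  status <- system2("python", c(script, taskf, outf),
                    stdout = FALSE, stderr = "")
  stopifnot(status == 0)
  jsonlite::fromJSON(outf)
}
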