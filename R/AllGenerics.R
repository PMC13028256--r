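setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))
setGeneric("reactions", function(x) standardGeneric("reactions"))
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
setGeneric("genes", function(x) standardGeneric("genes"))
setGeneric("gprRules", function(x) standardGeneric("gprRules"))
setGeneric("subsystems", function(x) standardGeneric("subsystems"))
setGeneric("isExchange", function(x) standardGeneric("isExchange"))
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))
setGeneric("fluxes", function(x) standardGeneric("fluxes"))
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))
setGeneric("leverTable", function(x) standardGeneric("leverTable"))
setGeneric("contrastId", function(x) standardGeneric("contrastId"))
setGeneric("weightTable", function(x) standardGeneric("weightTable"))
setGeneric("reactionClasses", function(x) standardGeneric("reactionClasses"))
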