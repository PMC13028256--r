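test_that("weighted flux minimization routes around penalized reactions", {
  # two single-step routes between the same metabolites: the penalized one
  # (weight 2) is abandoned in favor of the weight-1 twin
  twin <- readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem",
    "SRC\t --> a_c\t\treserve mobilization",
    "R_hi\ta_c --> b_c\tGhi\tcore",
    "R_lo\ta_c --> b_c\tGlo\tcore",
    "RQS\tb_c --> \t\tobjective"))
  w <- reactionWeights(twin, c(R_hi = "down"))
  sol <- minWeightedFlux(twin, w, rqs_target = 1)
  expect_equal(unname(fluxes(sol)[["R_hi"]]), 0)
  expect_equal(unname(fluxes(sol)[["R_lo"]]), 1)

  # a longer detour is still taken when the direct route is penalized
  # heavily enough (weight 4 > two weight-1 steps)
  par <- addReaction(parallelModel(), "RQS", "b_c --> ")
  w2 <- reactionWeights(par, c(R_direct = "down"),
                        scheme = c(down = 4, mixed = 1.5, neutral = 1,
                                   up = 0.5))
  sol2 <- minWeightedFlux(par, w2, rqs_target = 1)
  expect_equal(unname(fluxes(sol2)[["R_direct"]]), 0)
  expect_equal(unname(fluxes(sol2)[c("R_alt1", "R_alt2")]), c(1, 1))
  # with the penalty on the detour instead, the direct route wins
  w3 <- reactionWeights(par, c(R_alt1 = "down"))
  sol3 <- minWeightedFlux(par, w3, rqs_target = 1)
  expect_equal(unname(fluxes(sol3)[["R_direct"]]), 1)
  expect_equal(unname(fluxes(sol3)[["R_alt1"]]), 0)
})

test_that("uniform weights reduce to plain minimum total flux", {
  par <- parallelModel()
  par <- addReaction(par, "RQS", "b_c --> ")
  sol <- minWeightedFlux(par, reactionWeights(par), rqs_target = 1)
  # direct one-step route is shorter than the two-step alternative:
  # total flux = SRC + R_direct + RQS = 3
  expect_equal(objectiveValue(sol), 3)
  expect_equal(unname(fluxes(sol)[["R_direct"]]), 1)
  expect_error(minWeightedFlux(par, reactionWeights(par), rqs_target = 0),
               "strictly positive")
  expect_error(minWeightedFlux(par, reactionWeights(par), rqs_target = 1e5),
               "infeasible|exceeds")
})

test_that("reversible splitting never leaves futile two-way flux", {
  lp <- loopModel()
  lp <- addReaction(lp, "RQS", "b_c --> ")
  sol <- minWeightedFlux(lp, reactionWeights(lp), rqs_target = 2)
  v <- fluxes(sol)
  expect_lt(max(abs(buildStoichMatrix(lp) %*% v)), 1e-6)
  # the futile cycle F1/F2/F3 stays silent beyond what demand requires
  expect_equal(unname(v[["F1"]]), 2)
  expect_equal(unname(v[["F2"]]), 0)
  expect_equal(unname(v[["F3"]]), 0)
})

test_that("HQT keeps forward flux despite downregulation (MG E1 vs E2)", {
  mod <- referenceConstrained()
  ctr <- scenarioContrast("MG_E1vsE2", seed = 1)
  rcl <- classifyReactions(mod, classifyGenes(ctr), warn_missing = FALSE)
  expect_identical(unname(rcl[["HQT_c"]]), "down")
  w <- reactionWeights(mod, rcl)
  sol <- minWeightedFlux(mod, w, rqs_target = 1)
  expect_gt(fluxes(sol)[["HQT_c"]], 0)
})

test_that("normalization is per unit of RQS flux", {
  mod <- referenceConstrained()
  sol <- minWeightedFlux(mod, reactionWeights(mod), rqs_target = 1)
  nm <- normalizeSolution(sol, 1)
  expect_equal(unname(nm[["RQS"]]), 1)
  expect_true(all(nm >= 0))
  expect_error(normalizeSolution(sol, 0), "strictly positive")
  expect_error(normalizeSolution(sol, -1), "strictly positive")
})

test_that("lever calls need both downregulation and requiredness", {
  mod <- referenceConstrained()
  # nothing disfavored -> no levers
  lev0 <- detectLevers(mod, reactionWeights(mod))
  expect_identical(nrow(lev0), 0L)

  # RP E3 vs E4: QDH is upregulated, so despite carrying flux it is no lever
  ctr <- scenarioContrast("RP_E3vsE4", seed = 1)
  rcl <- classifyReactions(mod, classifyGenes(ctr), warn_missing = FALSE)
  w <- reactionWeights(mod, rcl)
  lev <- detectLevers(mod, w, rcl)
  expect_false("QDH_c" %in% lev$reaction_id)
  sol <- minWeightedFlux(mod, w, rqs_target = 1)
  expect_lt(fluxes(sol)[["QDH_c"]], 0)   # still carries reverse flux

  # MG E1 vs E2: HQT forward and QDH reverse are levers
  ctr2 <- scenarioContrast("MG_E1vsE2", seed = 1)
  rcl2 <- classifyReactions(mod, classifyGenes(ctr2), warn_missing = FALSE)
  lev2 <- detectLevers(mod, reactionWeights(mod, rcl2), rcl2)
  expect_true(all(c("HQT_c", "QDH_c") %in% lev2$reaction_id))
  expect_identical(lev2$direction[lev2$reaction_id == "HQT_c"],
                   "forward (-->)")
  expect_identical(lev2$direction[lev2$reaction_id == "QDH_c"],
                   "reverse (<--)")
  expect_true(all(lev2$class == "down") && all(lev2$required))
})

test_that("requiredness is structural: invariant across weight schemes", {
  mod <- referenceConstrained()
  ctr <- scenarioContrast("MG_E1vsE2", seed = 3)
  rcl <- classifyReactions(mod, classifyGenes(ctr), warn_missing = FALSE)
  levers <- lapply(altSchemes(), function(s)
    sort(detectLevers(mod, reactionWeights(mod, rcl, s), rcl)$reaction_id))
  base <- sort(detectLevers(mod, reactionWeights(mod, rcl))$reaction_id)
  for (lv in levers) expect_identical(lv, base)
})

test_that("directions of the quinate levers are scheme-independent", {
  mod <- referenceConstrained()
  ctr <- scenarioContrast("MG_E3vsE4", seed = 2)
  rcl <- classifyReactions(mod, classifyGenes(ctr), warn_missing = FALSE)
  for (s in altSchemes()) {
    lev <- detectLevers(mod, reactionWeights(mod, rcl, s), rcl)
    expect_identical(lev$direction[lev$reaction_id == "HQT_c"],
                     "forward (-->)")
    expect_identical(lev$direction[lev$reaction_id == "QDH_c"],
                     "reverse (<--)")
  }
})

test_that("fluxes scale with the RQS target; normalized magnitudes do not", {
  mod <- referenceConstrained()
  ctr <- scenarioContrast("MG_E1vsE2", seed = 1)
  rcl <- classifyReactions(mod, classifyGenes(ctr), warn_missing = FALSE)
  w <- reactionWeights(mod, rcl)
  for (target in c(0.5, 1, 1.5)) {
    sol <- minWeightedFlux(mod, w, rqs_target = target)
    nm <- normalizeSolution(sol, target)
    expect_equal(unname(nm[["HQT_c"]]), 1, tolerance = 1e-6,
                 label = paste("HQT at target", target))
    expect_equal(unname(nm[["QDH_c"]]), 2, tolerance = 1e-6,
                 label = paste("QDH at target", target))
  }
})

test_that("end-to-end contrast analysis assembles a coherent report", {
  mod <- buildReferenceModel()
  rep <- runContrastAnalysis(mod, scenarioContrast("MG_E3vsE4", seed = 1))
  expect_s4_class(rep, "LeverReport")
  expect_identical(contrastId(rep), "MG_E3vsE4")
  tab <- leverTable(rep)
  expect_setequal(tab$reaction_id, c("HQT_c", "QDH_c"))
  expect_true(all(tab$contrast == "MG_E3vsE4"))
  expect_false(anyDuplicated(tab$reaction_id) > 0)
  md <- rep@metadata
  expect_identical(md$rqs_target, 1)
  expect_gte(md$fba_optimum, 1)

  # an all-neutral contrast yields an empty report
  gn <- genes(mod)
  flat <- expressionContrast("flat", gn, rep(0, length(gn)),
                             rep(FALSE, length(gn)))
  rep0 <- runContrastAnalysis(mod, flat)
  expect_identical(nrow(leverTable(rep0)), 0L)
})
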