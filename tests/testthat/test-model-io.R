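test_that("equation parsing recovers signed stoichiometry and reversibility", {
  # benchmark equations as printed in the curated table
  pe <- parseReactionEquation("cys_c + hcn_c --> cyanoala_c + h2s_c + h_c")
  expect_false(pe$reversible)
  expect_mapequal(as.list(pe$stoichiometry),
                  list(cys_c = -1, hcn_c = -1, cyanoala_c = 1,
                       h2s_c = 1, h_c = 1))

  pe <- parseReactionEquation("gssg_c + h_c + nadph_c --> 2.0 gsh_c + nadp_c")
  expect_equal(pe$stoichiometry[["gsh_c"]], 2.0)

  pe <- parseReactionEquation("fum_m + h2o_m <=> mal_m")
  expect_true(pe$reversible)
  expect_false(pe$is_exchange)

  # same metabolite on both sides is net-summed
  pe <- parseReactionEquation("a_c + 2.0 b_c --> 3.0 b_c + c_c")
  expect_equal(pe$stoichiometry[["b_c"]], 1.0)

  # a fully cancelling metabolite drops out
  pe <- parseReactionEquation("a_c + b_c --> b_c + c_c")
  expect_false("b_c" %in% names(pe$stoichiometry))

  # empty sides mark exchange (pool/sink) reactions
  expect_true(parseReactionEquation(" --> glc_c")$is_exchange)
  expect_true(parseReactionEquation("co2_c --> ")$is_exchange)
})

test_that("malformed equations are rejected with informative errors", {
  expect_error(parseReactionEquation("a_c + b_c"), "no arrow")
  expect_error(parseReactionEquation("a_c --> b_c --> c_c"),
               "more than one arrow")
  expect_error(parseReactionEquation("1..5 a_c --> b_c"),
               "malformed coefficient")
  expect_error(parseReactionEquation("a_c + --> b_c"), "empty term")
})

test_that("equation formatting inverts parsing", {
  eqs <- c("cys_c + hcn_c --> cyanoala_c + h2s_c + h_c",
           "gssg_c + h_c + nadph_c --> 2.0 gsh_c + nadp_c",
           "fum_m + h2o_m <=> mal_m",
           "2.5 a_c + b_m --> 0.5 c_v",
           " --> glc_c",
           "co2_c --> ")
  for (eq in eqs) {
    pe <- parseReactionEquation(eq)
    back <- parseReactionEquation(
      formatReactionEquation(pe$stoichiometry, pe$reversible))
    expect_mapequal(as.list(back$stoichiometry), as.list(pe$stoichiometry))
    expect_identical(back$reversible, pe$reversible)
  }
  expect_match(formatReactionEquation(c(a_c = -1, b_c = 1)), "a_c --> b_c")
  expect_match(formatReactionEquation(c(gssg_c = -1, gsh_c = 2)), "2.0 gsh_c")
})

test_that("GPR parsing honors precedence, parentheses and emptiness", {
  expect_identical(parseGpr("Prupe.3G101000")@tree,
                   list(type = "leaf", gene = "Prupe.3G101000"))
  expect_length(parseGpr("")@tree, 0)
  expect_length(parseGpr("   ")@tree, 0)

  # and binds tighter than or
  t1 <- parseGpr("gA and gB or gC")@tree
  expect_identical(t1$type, "or")
  expect_identical(t1$children[[1]]$type, "and")
  t2 <- parseGpr("(gA and gB) or gC")@tree
  expect_identical(t2, t1)
  t3 <- parseGpr("gA and (gB or gC)")@tree
  expect_identical(t3$type, "and")

  expect_error(parseGpr("(gA and gB"), "unbalanced")
  expect_error(parseGpr("gA and"), "dangling")
  expect_error(parseGpr("gA or or gB"), "dangling")
})

test_that("GPR serialize/parse round trip preserves boolean semantics", {
  # random rules over a small gene alphabet, checked by full truth table
  set.seed(42)
  geneIds <- paste0("g", 1:6)
  randomTree <- function(depth) {
    if (depth == 0 || runif(1) < 0.4)
      return(list(type = "leaf", gene = sample(geneIds, 1)))
    kids <- lapply(seq_len(sample(2:3, 1)), function(i) randomTree(depth - 1))
    list(type = sample(c("and", "or"), 1), children = kids)
  }
  for (i in 1:25) {
    g <- new("GprRule", tree = randomTree(3))
    g2 <- parseGpr(gprToString(g))
    leaves <- union(gprLeaves(g), gprLeaves(g2))
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(leaves)))
    for (r in seq_len(nrow(grid))) {
      asg <- stats::setNames(as.logical(grid[r, ]), leaves)
      expect_identical(evalGpr(g2, asg), evalGpr(g, asg))
    }
  }
})

test_that("reaction tables parse into validated models", {
  tab <- c(
    "id\tequation\tgpr\tsubsystem",
    "ACO_m\tcit_m <=> isocit_m\tG_ACO_m\tTCA cycle",
    "CAS_c\tcys_c + hcn_c --> cyanoala_c + h2s_c + h_c\tG_CAS_c\tdetox",
    "EPSPS_c\tpep_c + s3p_c --> epsp_c + pi_c\tG_EPSPS_c\tshikimate",
    "FUM_m\tfum_m + h2o_m <=> mal_m\tG_FUM_m\tTCA cycle",
    "GR_c\tgssg_c + h_c + nadph_c --> 2.0 gsh_c + nadp_c\tG_GR_c\tredox",
    "HQT_c\tpcoumcoa_c + quinate_c <=> coa_c + pcoumaroylqnt_c\tPrupe.3G101000\tphenylpropanoid",
    "PPA_AT_c\tglu_c + prephenate_c --> akg_c + arogenate_c\tG_PPA_AT_c\tshikimate",
    "QDH_c\tdhq_c + h_c + nadh_c <=> nad_c + quinate_c\tPrupe.6G166100\tshikimate"
  )
  mod <- readReactionTable(text = tab)
  expect_s4_class(mod, "MetabolicModel")
  expect_identical(nrow(reactions(mod)), 8L)
  rev <- reactions(mod)$id[reactions(mod)$reversible]
  expect_setequal(rev, c("ACO_m", "FUM_m", "HQT_c", "QDH_c"))
  # default bounds by reversibility
  expect_equal(unname(lowerBounds(mod)[c("ACO_m", "CAS_c")]), c(-1000, 0))
  expect_equal(unname(upperBounds(mod)[["GR_c"]]), 1000)
  # compartments derive from the id suffix
  met <- metabolites(mod)
  expect_identical(unname(met$compartment[met$id == "fum_m"]), "m")
  expect_identical(unname(met$base_name[met$id == "quinate_c"]), "quinate")
  # gene set equals the union of GPR leaves
  expect_true(all(c("Prupe.3G101000", "Prupe.6G166100") %in% genes(mod)))
})

test_that("table errors carry line numbers; empty tables warn", {
  expect_error(readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem",
    "R1\ta_c --> b_c\t\tx",
    "R1\tb_c --> c_c\t\tx"
  )), "duplicate reaction id")
  expect_error(readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem",
    "R1\ta_c --> b_c\t\tx",
    "R2\tno arrow here\t\tx"
  )), "line 3")
  expect_error(readReactionTable(text = "R1\ta_q --> b_c\t\tx"),
               "compartment suffix")
  expect_warning(m0 <- readReactionTable(text = "id\tequation\tgpr\tsubsystem"),
                 "empty")
  expect_identical(nrow(reactions(m0)), 0L)
  expect_identical(dim(buildStoichMatrix(m0)), c(0L, 0L))
})

test_that("comment lines are skipped and unknown columns preserved", {
  tab <- c("id\tequation\tgpr\tsubsystem\tlower_bound\tupper_bound\tec_number",
           "# a comment",
           "R1\ta_c --> b_c\tgX\tcore\t0\t50\t1.1.1.1")
  mod <- readReactionTable(text = tab)
  expect_identical(reactions(mod)$ec_number, "1.1.1.1")
  expect_equal(unname(upperBounds(mod)[["R1"]]), 50)
  out <- writeReactionTable(mod)
  expect_match(out[1], "ec_number")
  expect_identical(readReactionTable(text = out)@reactions$ec_number,
                   "1.1.1.1")
})

test_that("reaction table write/parse round trip is the identity", {
  mods <- c(toyModels(), list(reference = buildReferenceModel()))
  for (m in mods) {
    m2 <- readReactionTable(text = writeReactionTable(m), name = m@name)
    expect_identical(reactionIds(m2), reactionIds(m))
    expect_setequal(metaboliteIds(m2), metaboliteIds(m))
    S1 <- as.matrix(buildStoichMatrix(m))
    S2 <- as.matrix(buildStoichMatrix(m2))[rownames(S1), colnames(S1)]
    expect_equal(S2, S1, tolerance = 1e-12)
    expect_equal(reactions(m2)$lower_bound, reactions(m)$lower_bound)
    expect_equal(reactions(m2)$upper_bound, reactions(m)$upper_bound)
    expect_identical(vapply(gprRules(m2), gprToString, character(1)),
                     vapply(gprRules(m), gprToString, character(1)))
    # write(parse(write(m))) is line-identical to write(m)
    expect_identical(writeReactionTable(m2), writeReactionTable(m))
  }
})

test_that("model editing keeps the object valid", {
  mod <- chainModel()
  mod2 <- addReaction(mod, "R2", "b_c --> c_c", gpr = "gZ")
  expect_identical(nrow(reactions(mod2)), 4L)
  expect_error(addReaction(mod2, "R2", "a_c --> c_c"), "already present")
  mod3 <- removeReactions(mod2, "R2")
  expect_identical(reactionIds(mod3), reactionIds(mod))
  expect_false("c_c" %in% metaboliteIds(mod3))
  expect_error(removeReactions(mod, "nope"), "unknown reaction")
  expect_error(setBounds(mod, "R1", lower = 2, upper = 1), "exceeds")
  expect_error(setBounds(mod, "R1", lower = -1), "irreversible")
})
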