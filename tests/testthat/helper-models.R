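# Small hand-built networks used across the test files. All are built
# through the public reaction-table parser so the tests exercise the same
# entry path as user models.

# linear chain: capped source -> a -> b -> sink
chainModel <- function(source_ub = 5) {
  readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem\tlower_bound\tupper_bound",
    sprintf("SRC\t --> a_c\t\treserve mobilization\t0\t%g", source_ub),
    "R1\ta_c --> b_c\tG1\tcore\t\t",
    "SNK\tb_c --> \t\texchange\t\t"
  ), name = "chain")
}

# two routes from a to b: direct (R_direct) and two-step (R_alt1, R_alt2)
parallelModel <- function() {
  readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem",
    "SRC\t --> a_c\t\treserve mobilization",
    "R_direct\ta_c --> b_c\tGdir\tcore",
    "R_alt1\ta_c --> x_c\tGalt1\tcore",
    "R_alt2\tx_c --> b_c\tGalt2\tcore",
    "SNK\tb_c --> \t\texchange"
  ), name = "parallel")
}

# reversible conversions plus a potential futile cycle a -> b -> c -> a
loopModel <- function() {
  readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem",
    "SRC\t --> a_c\t\treserve mobilization",
    "F1\ta_c <=> b_c\tG1\tcore",
    "F2\tb_c <=> c_c\tG2\tcore",
    "F3\tc_c <=> a_c\tG3\tcore",
    "SNK\tb_c --> \t\texchange"
  ), name = "loop")
}

# branched demand: one source feeds two sinks through a shared intermediate
branchModel <- function() {
  readReactionTable(text = c(
    "id\tequation\tgpr\tsubsystem\tlower_bound\tupper_bound",
    "SRC\t --> a_c\t\treserve mobilization\t0\t8",
    "R1\ta_c --> 2.0 b_c\tG1\tcore\t\t",
    "R2\tb_c --> c_c\tG2\tcore\t\t",
    "SNK_B\tb_c --> \t\texchange\t\t",
    "SNK_C\tc_c --> \t\texchange\t\t"
  ), name = "branch")
}

# the three toy networks used for oracle equivalence checks
toyModels <- function() {
  list(chain = chainModel(), parallel = parallelModel(), loop = loopModel())
}

referenceConstrained <- function(...) {
  applyRipeningConstraints(buildReferenceModel(), ripeningConfig(...))
}

# admissible alternative weight schemes (ordering respected, max/min <= 10)
altSchemes <- function() {
  list(
    c(down = 4.0, mixed = 2.0, neutral = 1.0, up = 0.8),
    c(down = 1.6, mixed = 1.3, neutral = 1.0, up = 0.2),
    c(down = 10.0, mixed = 5.0, neutral = 2.0, up = 1.0)
  )
}
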