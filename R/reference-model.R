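## Reduced reference model of ripening peach mesocarp metabolism.
##
## The network is written in the curated reaction-table dialect and parsed by
## readReactionTable(), so the shipped constructor and the file round trip
## are guaranteed to agree. Design constraints baked into the connectivity:
##
##  * chlorogenate is reachable only via HQT_c (p-coumaroylquinate) and its
##    3'-hydroxylation; the chlorogenate mobilization pool is blocked by the
##    default RipeningConfig, so the RQS cannot bypass de novo synthesis;
##  * dehydroquinate comes only from vacuolar quinate reserves through QDH_c
##    running in reverse (quinate -> dehydroquinate + NADH); there is no
##    DAHP-synthase entry from erythrose-4-P/PEP, which makes the quinate
##    route structurally required;
##  * ethylene synthesis co-produces HCN (ACC oxidase), removable only by
##    beta-cyanoalanine synthase CAS_c;
##  * the two hydroxylations (C4H, C3'H) oxidize 2 GSH each; GSSG is
##    recycled only by glutathione reductase GR_c;
##  * NADPH comes only from cytosolic NADP-isocitrate dehydrogenase fed by
##    mitochondrial isocitrate export, and oxaloacetate for citrate synthase
##    is regenerated only through the southern TCA arm, so ACO_m and FUM_m
##    must stay active whenever the RQS (or NGAM, via respiration) runs;
##  * glycolytic NADH can only be reoxidized by the mitochondrial chain
##    (external NADH dehydrogenase) and pyruvate has no fermentative
##    overflow, so the NGAM ATP demand also forces respiration;
##  * galacturonate derives from a pectin reserve pool via polygalacturonase.
##
## Every enzymatic reaction carries a synthetic single-gene GPR ("G_" +
## reaction id); HQT_c and QDH_c use their published gene identifiers.

.referenceTableLines <- function() {
  c(
  "id\tequation\tgpr\tsubsystem",
  "# --- reserve mobilization pools (capped by RipeningConfig) ---",
  "MOB_HEXOSE\t --> glc_c\t\treserve mobilization",
  "MOB_QUINATE\t --> quinate_v\t\treserve mobilization",
  "MOB_MET\t --> met_c\t\treserve mobilization",
  "MOB_CYS\t --> cys_c\t\treserve mobilization",
  "MOB_PECTIN\t --> pectin_c\t\treserve mobilization",
  "MOB_CIT\t --> cit_v\t\treserve mobilization",
  "MOB_CGA\t --> chlorogenate_v\t\treserve mobilization",
  "MOB_ATP\t --> atp_c\t\treserve mobilization",
  "MOB_ADP\t --> adp_c\t\treserve mobilization",
  "MOB_PI\t --> pi_c\t\treserve mobilization",
  "MOB_NAD\t --> nad_c\t\treserve mobilization",
  "MOB_NADP\t --> nadp_c\t\treserve mobilization",
  "MOB_COA\t --> coa_c\t\treserve mobilization",
  "# --- transport ---",
  "T_QUINATE\tquinate_v --> quinate_c\t\ttransport",
  "T_CIT\tcit_v <=> cit_c\t\ttransport",
  "T_CGA\tchlorogenate_v --> chlorogenate_c\t\ttransport",
  "T_PYR\tpyr_c --> pyr_m\t\ttransport",
  "T_ISOCIT\tisocit_m --> isocit_c\t\ttransport",
  "T_AKG\takg_c --> akg_m\t\ttransport",
  "T_ATPADP\tadp_c + atp_m <=> adp_m + atp_c\t\ttransport",
  "T_PI\tpi_c <=> pi_m\t\ttransport",
  "T_O2\to2_c <=> o2_m\t\ttransport",
  "T_CO2\tco2_m <=> co2_c\t\ttransport",
  "T_H2O\th2o_c <=> h2o_m\t\ttransport",
  "T_H\th_c <=> h_m\t\ttransport",
  "# --- gas / water / proton exchange and detoxification sinks ---",
  "EX_O2\t --> o2_c\t\texchange",
  "EX_CO2\tco2_c --> \t\texchange",
  "EX_H2O\th2o_c <=> \t\texchange",
  "EX_H\th_c <=> \t\texchange",
  "SINK_CYANOALA\tcyanoala_c --> \t\texchange",
  "SINK_H2S\th2s_c --> \t\texchange",
  "# --- central carbon (cytosol) ---",
  paste0("GLYC1_c\t2.0 atp_c + glc_c --> 2.0 adp_c + 2.0 g3p_c\t",
         "G_GLYC1_c\tcentral carbon"),
  paste0("GLYC2_c\tadp_c + g3p_c + nad_c + pi_c --> ",
         "atp_c + h_c + h2o_c + nadh_c + pep_c\tG_GLYC2_c\tcentral carbon"),
  "PK_c\tadp_c + h_c + pep_c --> atp_c + pyr_c\tG_PK_c\tcentral carbon",
  paste0("PDHB_c\tatp_c + coa_c + h2o_c + nad_c + pyr_c --> ",
         "accoa_c + adp_c + co2_c + h_c + nadh_c + pi_c\t",
         "G_PDHB_c\tcentral carbon"),
  paste0("ICDH_c\tisocit_c + nadp_c --> akg_c + co2_c + nadph_c\t",
         "G_ICDH_c\tcentral carbon"),
  paste0("GDH_c\takg_c + h_c + nadh_c + nh4_c --> glu_c + h2o_c + nad_c\t",
         "G_GDH_c\tcentral carbon"),
  "# --- TCA cycle (mitochondrion) ---",
  paste0("PDH_m\tcoa_m + nad_m + pyr_m --> accoa_m + co2_m + nadh_m\t",
         "G_PDH_m\tTCA cycle"),
  "CS_m\taccoa_m + h2o_m + oaa_m --> cit_m + coa_m\tG_CS_m\tTCA cycle",
  "ACO_m\tcit_m <=> isocit_m\tG_ACO_m\tTCA cycle",
  paste0("IDH_m\tisocit_m + nad_m --> akg_m + co2_m + nadh_m\t",
         "G_IDH_m\tTCA cycle"),
  paste0("AKGDH_m\takg_m + coa_m + nad_m --> co2_m + nadh_m + succoa_m\t",
         "G_AKGDH_m\tTCA cycle"),
  paste0("SCS_m\tadp_m + pi_m + succoa_m --> atp_m + coa_m + succ_m\t",
         "G_SCS_m\tTCA cycle"),
  paste0("SDH_m\t1.5 adp_m + 0.5 o2_m + 1.5 pi_m + succ_m --> ",
         "1.5 atp_m + fum_m + 2.5 h2o_m\tG_SDH_m\tTCA cycle"),
  "FUM_m\tfum_m + h2o_m <=> mal_m\tG_FUM_m\tTCA cycle",
  "MDH_m\tmal_m + nad_m --> h_m + nadh_m + oaa_m\tG_MDH_m\tTCA cycle",
  "# --- oxidative phosphorylation (lumped) ---",
  paste0("OXPHOS_m\t2.5 adp_m + h_m + nadh_m + 0.5 o2_m + 2.5 pi_m --> ",
         "2.5 atp_m + 3.5 h2o_m + nad_m\tG_OXPHOS_m\t",
         "oxidative phosphorylation"),
  paste0("NDE_m\t1.5 adp_m + h_c + nadh_c + 0.5 o2_m + 1.5 pi_m --> ",
         "1.5 atp_m + 2.5 h2o_m + nad_c\tG_NDE_m\t",
         "oxidative phosphorylation"),
  "# --- maintenance ---",
  "NGAM\tatp_c + h2o_c --> adp_c + h_c + pi_c\t\tmaintenance",
  "# --- shikimate pathway (cytosol) ---",
  paste0("QDH_c\tdhq_c + h_c + nadh_c <=> nad_c + quinate_c\t",
         "Prupe.6G166100\tshikimate pathway"),
  "DHQD_c\tdhq_c --> dhs_c + h2o_c\tG_DHQD_c\tshikimate pathway",
  paste0("SKDH_c\tdhs_c + h_c + nadph_c --> nadp_c + shikimate_c\t",
         "G_SKDH_c\tshikimate pathway"),
  paste0("SK_c\tatp_c + shikimate_c --> adp_c + h_c + s3p_c\t",
         "G_SK_c\tshikimate pathway"),
  paste0("EPSPS_c\tpep_c + s3p_c --> epsp_c + pi_c\t",
         "G_EPSPS_c\tshikimate pathway"),
  "CHRS_c\tepsp_c --> chorismate_c + pi_c\tG_CHRS_c\tshikimate pathway",
  "CHRM_c\tchorismate_c --> prephenate_c\tG_CHRM_c\tshikimate pathway",
  paste0("PPA_AT_c\tglu_c + prephenate_c --> akg_c + arogenate_c\t",
         "G_PPA_AT_c\tshikimate pathway"),
  paste0("ADT_c\tarogenate_c + h_c --> co2_c + h2o_c + phe_c\t",
         "G_ADT_c\tshikimate pathway"),
  "# --- phenylpropanoid / chlorogenate ---",
  paste0("PAL_c\tphe_c --> cinnamate_c + nh4_c\t",
         "G_PAL_c\tphenylpropanoid/chlorogenate"),
  paste0("C4H_c\tcinnamate_c + 2.0 gsh_c + o2_c --> ",
         "gssg_c + h2o_c + pcoumarate_c\t",
         "G_C4H_c\tphenylpropanoid/chlorogenate"),
  paste0("4CL_c\tatp_c + coa_c + pcoumarate_c --> ",
         "adp_c + pcoumcoa_c + pi_c\tG_4CL_c\tphenylpropanoid/chlorogenate"),
  paste0("HQT_c\tpcoumcoa_c + quinate_c <=> coa_c + pcoumaroylqnt_c\t",
         "Prupe.3G101000\tphenylpropanoid/chlorogenate"),
  paste0("C3H_c\t2.0 gsh_c + o2_c + pcoumaroylqnt_c --> ",
         "chlorogenate_c + gssg_c + h2o_c\t",
         "G_C3H_c\tphenylpropanoid/chlorogenate"),
  "# --- glutathione redox ---",
  paste0("GR_c\tgssg_c + h_c + nadph_c --> 2.0 gsh_c + nadp_c\t",
         "G_GR_c\tglutathione redox"),
  "# --- flavonoid / anthocyanin (to cyanidin) ---",
  paste0("ACCase_c\taccoa_c + atp_c + co2_c + h2o_c --> ",
         "adp_c + h_c + malcoa_c + pi_c\t",
         "G_ACCase_c\tflavonoid/anthocyanin"),
  paste0("CHS_c\t3.0 malcoa_c + pcoumcoa_c --> ",
         "3.0 co2_c + 4.0 coa_c + narchalcone_c\t",
         "G_CHS_c\tflavonoid/anthocyanin"),
  "CHI_c\tnarchalcone_c --> naringenin_c\tG_CHI_c\tflavonoid/anthocyanin",
  paste0("ANS_c\th_c + naringenin_c + 2.0 nadph_c + 2.0 o2_c --> ",
         "cyanidin_c + 2.0 nadp_c + 3.0 h2o_c\t",
         "G_ANS_c\tflavonoid/anthocyanin"),
  "# --- ethylene biosynthesis (Yang cycle, lumped) + cyanide detox ---",
  paste0("SAMS_c\tatp_c + h2o_c + met_c --> adp_c + pi_c + sam_c\t",
         "G_SAMS_c\tethylene/cyanide detox"),
  "ACS_c\tsam_c --> acc_c\tG_ACS_c\tethylene/cyanide detox",
  paste0("ACCO_c\tacc_c + o2_c --> co2_c + ethylene_c + h2o_c + hcn_c\t",
         "G_ACCO_c\tethylene/cyanide detox"),
  paste0("CAS_c\tcys_c + hcn_c --> cyanoala_c + h2s_c + h_c\t",
         "G_CAS_c\tethylene/cyanide detox"),
  "# --- cell wall / pectin degradation ---",
  "PG_c\th2o_c + pectin_c --> galacturonate_c\tG_PG_c\tcell wall degradation"
  )
}

#' Build the reduced reference fruit model
#'
#' Deterministic constructor for the reduced peach-mesocarp ripening model:
#' nine metabolic subsystems (central carbon, TCA cycle, lumped oxidative
#' phosphorylation, shikimate pathway, phenylpropanoid/chlorogenate,
#' flavonoid/anthocyanin to cyanidin, lumped ethylene biosynthesis with
#' cyanide detoxification, cell-wall/pectin degradation, glutathione redox)
#' plus reserve-mobilization pools, transport and exchange pseudo-reactions,
#' the NGAM maintenance demand and the RQS objective sink. The eight
#' benchmark reactions (ACO_m, CAS_c, EPSPS_c, FUM_m, GR_c, HQT_c,
#' PPA_AT_c, QDH_c) appear with their published stoichiometries.
#'
#' The connectivity is arranged so that each benchmark reaction is
#' structurally required to sustain the RQS: chlorogenate only via HQT_c,
#' dehydroquinate only from quinate reserves via QDH_c in reverse (no
#' DAHP-synthase entry), HCN detoxified only by CAS_c, GSSG recycled only by
#' GR_c, NADPH only from isocitrate export (forcing ACO_m), oxaloacetate
#' only through fumarase (forcing FUM_m).
#'
#' @param include_rqs append the RQS objective sink (default TRUE).
#' @return A validated [MetabolicModel-class] (74 reactions + RQS).
#' @examples
#' mod <- buildReferenceModel()
#' mod
#' @export
buildReferenceModel <- function(include_rqs = TRUE) {
  mod <- readReactionTable(text = .referenceTableLines(),
                           name = "peach mesocarp ripening (reduced)")
  if (include_rqs) mod <- addRqsObjective(mod)
  mod
}

#' Write the demo input files
#'
#' Materializes the self-contained analysis inputs into a directory:
#' \code{reference_model.tsv}, the four scenario contrast TSVs
#' (\code{MG_E1vsE2.tsv}, \code{MG_E3vsE4.tsv}, \code{RP_E1vsE2.tsv},
#' \code{RP_E3vsE4.tsv}) and \code{config.json} holding the default
#' [ripeningConfig()].
#'
#' @param dir output directory (created if needed).
#' @param seed seed forwarded to [scenarioContrast()].
#' @return the directory path, invisibly.
#' @export
writeDemoFiles <- function(dir, seed = 20260101) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeReactionTable(buildReferenceModel(),
                     file.path(dir, "reference_model.tsv"))
  for (cid in .SCENARIO_IDS)
    writeContrast(scenarioContrast(cid, seed = seed),
                  file.path(dir, paste0(cid, ".tsv")))
  cfg <- ripeningConfig()
  json <- paste0(
    "{\n",
    "  \"ngam_reaction_id\": \"", cfg@ngam_reaction_id, "\",\n",
    "  \"ngam_lower_bound\": ", format(cfg@ngam_lower_bound), ",\n",
    "  \"pool_upper_bound\": ", format(cfg@pool_upper_bound), ",\n",
    "  \"blocked_pools\": [",
    paste0("\"", cfg@blocked_pools, "\"", collapse = ", "), "]\n}")
  writeLines(json, file.path(dir, "config.json"))
  invisible(dir)
}
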