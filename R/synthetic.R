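# Deterministic synthetic-data generators.
#
# make_toy_gem() builds TOY-CORE, a compact yeast-like metabolic network:
# glucose transport, a lumped upper glycolysis catalysed by an isoenzyme
# pair, lumped lower glycolysis, a lumped pentose phosphate shunt (sole NADPH
# source), a lumped TCA oxidation catalysed by a two-subunit complex,
# oxidative phosphorylation, ethanol fermentation, a glycerol branch from
# DHAP via glycerol 3-phosphate, four nitrogen sources with distinct planted
# economics (glutamine: 2 N plus fully catabolisable carbon; ammonium: 1 N,
# no carbon; isoleucine/phenylalanine: 1 N with carbon skeletons excreted as
# keto/aryl acids), urea overflow for surplus nitrogen, ATP maintenance and
# a three-class biomass (protein/carbohydrate/RNA). All non-planted reactions
# are elementally and charge balanced; two deliberately unbalanced reactions
# and one generic-residue (unauditable) reaction are planted closed so they
# never carry flux. The returned PlantedTruth record carries every quantity
# tests need: hand-derived glucose demand, nitrogen content of biomass,
# marginal ATP economics of the four nitrogen sources, essential genes and
# synthetic-lethal pairs.

.toy_met <- function(id, name, compartment, formula, charge, dG = NA_real_) {
  data.frame(id = id, name = name, compartment = compartment, formula = formula,
             charge = charge, deltaG0 = dG, stringsAsFactors = FALSE)
}

#' Build the TOY-CORE synthetic model with planted ground truth
#'
#' @param verify Re-verify planted essentiality and synthetic-lethal pairs
#'   with the brute-force deletion oracle before returning (default TRUE).
#' @param glc_uptake Medium glucose uptake bound, mmol/gDW/h (default 10).
#' @return List with `model` (a [gem()], minimal glucose+ammonium medium
#'   applied, growth objective) and `truth` (PlantedTruth list).
#' @export
make_toy_gem <- function(verify = TRUE, glc_uptake = 10) {
  cmp <- c(e = "extracellular", c = "cytoplasm")

  # formation dG0' values (kJ/mol) are synthetic annotations chosen to give
  # chemically sensible signs for the central pathway sums
  dG <- c(glc = -426.7, dhap = -1095.7, pyr = -470, akg = -633.6, glu = -377.8,
          gln = -128.6, nh4 = -26.1, ile = -175.8, phe = -207.1, kmv = -300,
          ppyr = -350, glyc = -177, g3p = -1080, etoh = -181.6, co2 = -386,
          o2 = 16.4, h2o = -157.6, h = 0, pi = -1059.5, atp = -2295.8,
          adp = -1424.7, nad = -2261, nadh = -2238.4, nadp = -2850,
          nadph = -2827, urea = -42.9)
  frm <- c(glc = "C6H12O6", dhap = "C3H5O6P", pyr = "C3H3O3", akg = "C5H4O5",
           glu = "C5H8NO4", gln = "C5H10N2O3", nh4 = "H4N", ile = "C6H13NO2",
           phe = "C9H11NO2", kmv = "C6H9O3", ppyr = "C9H7O3", pac = "C8H7O2",
           glyc = "C3H8O3", g3p = "C3H7O6P", etoh = "C2H6O", co2 = "CO2",
           o2 = "O2", h2o = "H2O", h = "H", pi = "HPO4", atp = "C10H12N5O13P3",
           adp = "C10H12N5O10P2", nad = "C21H26N7O14P2", nadh = "C21H27N7O14P2",
           nadp = "C21H25N7O17P3", nadph = "C21H26N7O17P3", urea = "CH4N2O",
           protein = "C5H8N2O2", carb = "C6H10O5", rna = "C9H12N4O7P",
           lipX = "C10H18O2R")
  chg <- c(glc = 0, dhap = -2, pyr = -1, akg = -2, glu = -1, gln = 0, nh4 = 1,
           ile = 0, phe = 0, kmv = -1, ppyr = -1, pac = -1, glyc = 0, g3p = -2,
           etoh = 0, co2 = 0, o2 = 0, h2o = 0, h = 1, pi = -2, atp = -4,
           adp = -3, nad = -1, nadh = -2, nadp = -3, nadph = -4, urea = 0,
           protein = 0, carb = 0, rna = -1, lipX = 0)

  ext <- c("glc", "nh4", "gln", "ile", "phe", "o2", "co2", "h2o", "h", "pi",
           "etoh", "glyc", "urea", "kmv", "pac")
  cyt <- setdiff(names(frm), character(0))
  mets <- rbind(
    do.call(rbind, lapply(ext, function(b) .toy_met(
      paste0(b, "_e"), b, "e", frm[[b]], chg[[b]],
      if (b %in% names(dG)) dG[[b]] else NA_real_))),
    do.call(rbind, lapply(cyt, function(b) .toy_met(
      paste0(b, "_c"), b, "c", frm[[b]], chg[[b]],
      if (b %in% c("pac", "protein", "carb", "rna", "lipX")) NA_real_ else dG[[b]])))
  )
  # biomass composition: 0.5 / 0.4 / 0.1 g/gDW protein / carbohydrate / RNA
  mw <- vapply(c(protein = "C5H8N2O2", carb = "C6H10O5", rna = "C9H12N4O7P"),
               formula_weight, 0.0)
  bio <- c(protein = 0.5, carb = 0.4, rna = 0.1)
  coef <- 1000 * bio / mw # mmol/gDW

  rx <- list(); meta <- list()
  add <- function(id, st, lb, ub, gpr = "", subsystem = "", pseudo = FALSE, name = id) {
    rx[[id]] <<- st
    meta[[id]] <<- data.frame(id = id, name = name, lb = lb, ub = ub,
                              subsystem = subsystem, deltaG0 = NA_real_,
                              pseudo = pseudo, gpr = gpr, stringsAsFactors = FALSE)
  }
  exch <- function(base, lb) add(paste0("EX_", base), stats::setNames(-1, paste0(base, "_e")),
                                 lb, 1000, subsystem = "Exchange", pseudo = TRUE)

  exch("glc", -glc_uptake); exch("nh4", -1000)
  exch("gln", 0); exch("ile", 0); exch("phe", 0)
  exch("o2", -1000); exch("co2", 0); exch("h2o", -1000); exch("h", -1000)
  exch("pi", -1000); exch("etoh", 0); exch("glyc", 0); exch("urea", 0)
  exch("kmv", 0); exch("pac", 0)

  tr <- function(id, base, gpr = "", lb = 0, ub = 1000, extra = NULL) {
    st <- stats::setNames(c(-1, 1), paste0(base, c("_e", "_c")))
    add(id, c(st, extra), lb, ub, gpr, "Transport")
  }
  tr("GLCt", "glc", "gHXT1", ub = glc_uptake)
  tr("NH4t", "nh4", "gMEP1")
  tr("GLNt", "gln", "gGNP1")
  tr("ILEt", "ile", "gBAP2")
  add("PHEt", c(phe_e = -1, atp_c = -1, h2o_c = -1, phe_c = 1, adp_c = 1,
                pi_c = 1, h_c = 1), 0, 1000, "gAAP1", "Transport")
  tr("O2t", "o2")
  add("CO2t", c(co2_c = -1, co2_e = 1), -1000, 1000, "", "Transport")
  add("H2Ot", c(h2o_e = -1, h2o_c = 1), -1000, 1000, "", "Transport")
  add("Ht", c(h_e = -1, h_c = 1), -1000, 1000, "", "Transport")
  add("PIt", c(pi_e = -1, pi_c = 1), -1000, 1000, "", "Transport")
  add("ETOHt", c(etoh_c = -1, etoh_e = 1), 0, 1000, "", "Transport")
  add("GLYCt", c(glyc_c = -1, glyc_e = 1), 0, 1000, "", "Transport")
  add("UREAt", c(urea_c = -1, urea_e = 1), 0, 1000, "", "Transport")
  add("KMVt", c(kmv_c = -1, kmv_e = 1), 0, 1000, "", "Transport")
  add("PACt", c(pac_c = -1, pac_e = 1), 0, 1000, "", "Transport")

  add("HXK", c(glc_c = -1, atp_c = -2, dhap_c = 2, adp_c = 2, h_c = 2),
      0, 1000, "gGLY1A or gGLY1B", "Glycolysis", name = "upper glycolysis (lumped)")
  add("PYK", c(dhap_c = -1, adp_c = -2, pi_c = -1, nad_c = -1,
               pyr_c = 1, atp_c = 2, nadh_c = 1, h2o_c = 1),
      0, 1000, "gGLY2 or gGLY2B", "Glycolysis",
      name = "lower glycolysis (lumped)")
  add("PPP", c(glc_c = -1, nadp_c = -12, h2o_c = -6, co2_c = 6, nadph_c = 12, h_c = 12),
      0, 1000, "gZWF1", "Pentose phosphate pathway", name = "oxidative PPP (lumped)")
  add("TCA", c(pyr_c = -1, nad_c = -5, h2o_c = -3, co2_c = 3, nadh_c = 5, h_c = 4),
      0, 1000, "gTCA1 and gTCA2", "TCA cycle", name = "pyruvate oxidation (lumped)")
  add("AKGS", c(pyr_c = -2, nad_c = -2, h2o_c = -1, akg_c = 1, co2_c = 1,
                nadh_c = 2, h_c = 2), 0, 1000, "gIDH1", "TCA cycle")
  add("AKGOX", c(akg_c = -1, nad_c = -8, h2o_c = -5, co2_c = 5, nadh_c = 8, h_c = 6),
      0, 1000, "gKGD1", "TCA cycle")
  add("OXPHOS", c(nadh_c = -2, o2_c = -1, adp_c = -3, pi_c = -3, h_c = -5,
                  nad_c = 2, atp_c = 3, h2o_c = 5),
      0, 1000, "gOXP1", "Oxidative phosphorylation")
  add("FERM", c(pyr_c = -1, nadh_c = -1, h_c = -2, etoh_c = 1, co2_c = 1, nad_c = 1),
      0, 1000, "gADH1", "Fermentation")
  add("GPD", c(dhap_c = -1, nadh_c = -1, h_c = -1, g3p_c = 1, nad_c = 1),
      0, 1000, "gGPD1 or gGPD2", "Glycerol metabolism")
  add("GPP", c(g3p_c = -1, h2o_c = -1, glyc_c = 1, pi_c = 1),
      0, 1000, "gGPP1 or gGPP2", "Glycerol metabolism")
  add("GDH", c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1,
               glu_c = 1, nadp_c = 1, h2o_c = 1),
      0, 1000, "gGDH1", "Nitrogen metabolism")
  add("GDH2", c(glu_c = -1, h2o_c = -1, nad_c = -1,
                akg_c = 1, nh4_c = 1, nadh_c = 1, h_c = 1),
      0, 1000, "gGDH2", "Nitrogen metabolism")
  add("GLS", c(gln_c = -1, h2o_c = -1, glu_c = 1, nh4_c = 1),
      0, 1000, "gGLS1", "Nitrogen metabolism")
  add("GS", c(glu_c = -1, nh4_c = -1, atp_c = -1,
              gln_c = 1, adp_c = 1, pi_c = 1, h_c = 1),
      0, 1000, "gGLN1", "Nitrogen metabolism")
  add("ILETA", c(ile_c = -1, akg_c = -1, kmv_c = 1, glu_c = 1),
      0, 1000, "gBAT1", "Nitrogen metabolism")
  add("PHETA", c(phe_c = -1, akg_c = -1, ppyr_c = 1, glu_c = 1),
      0, 1000, "gARO8", "Nitrogen metabolism")
  add("PPYROX", c(ppyr_c = -1, nad_c = -1, h2o_c = -1,
                  pac_c = 1, co2_c = 1, nadh_c = 1, h_c = 1),
      0, 1000, "gARO10", "Nitrogen metabolism")
  add("UREAS", c(nh4_c = -2, co2_c = -1, atp_c = -6, h2o_c = -5,
                 urea_c = 1, adp_c = 6, pi_c = 6, h_c = 8),
      0, 1000, "gCAR1", "Nitrogen metabolism")
  add("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      0, 1000, "", "Maintenance", pseudo = TRUE)

  add("PROTS", c(glu_c = -1, nh4_c = -1, atp_c = -4, nadph_c = -1,
                 protein_c = 1, adp_c = 4, pi_c = 4, nadp_c = 1),
      0, 1000, "", "Biomass", pseudo = TRUE)
  add("CARBS", c(glc_c = -1, atp_c = -1, carb_c = 1, adp_c = 1, pi_c = 1),
      0, 1000, "", "Biomass", pseudo = TRUE)
  add("RNAS", c(glc_c = -1, nh4_c = -2, atp_c = -6, pi_c = -1,
                rna_c = 1, adp_c = 6), 0, 1000, "", "Biomass", pseudo = TRUE)
  add("GROWTH", c(stats::setNames(-coef, c("protein_c", "carb_c", "rna_c")),
                  atp_c = -30, h2o_c = -30, adp_c = 30, pi_c = 30, h_c = 30),
      0, 1000, "", "Biomass", pseudo = TRUE, name = "growth")

  # planted defects for the balance audit: closed so they never carry flux
  add("BAD1", c(glc_c = -1, pyr_c = 2, h_c = 2), 0, 0, "", "Planted defects")
  add("BAD2", c(akg_c = -1, nh4_c = -1, glu_c = 1), 0, 0, "", "Planted defects")
  add("BADX", c(lipX_c = -1, h2o_c = -1, glyc_c = 1), 0, 0, "", "Planted defects")

  rxns <- do.call(rbind, meta)
  model <- gem(id = "TOY-CORE", compartments = cmp, mets = mets, rxns = rxns,
               stoich = rx, objective = "GROWTH",
               extra = list(biomass_class = c(
                 protein_c = "protein", carb_c = "carbohydrate", rna_c = "rna",
                 atp_c = "cofactor", h2o_c = "cofactor", adp_c = "cofactor",
                 pi_c = "cofactor", h_c = "cofactor")))

  # reaction dG0' from the metabolite annotations (consistency by construction)
  for (rid in model$rxns$id[!model$rxns$pseudo]) {
    model$rxns[rid, "deltaG0"] <- reaction_deltaG_from_metabolites(model, rid)
  }

  # ---- planted truth -------------------------------------------------------
  # hand-derived stoichiometric economics (see the methods vignette):
  # ATP yield 20 per glucose respired; biomass demands per gDW below.
  P <- unname(coef["protein"]); C <- unname(coef["carb"]); R <- unname(coef["rna"])
  atp_demand <- 4 * P + C + 6 * R + 30 - 2 * P - 6 * P # net after glu-synthesis credits
  glc_per_gdw <- P + C + R + 2 * P / 12 + atp_demand / 20
  n_per_gdw <- 2 * P + 2 * R
  truth <- list(
    biomass = list(fractions = bio, coefficients = coef, mw = mw),
    glc_per_gdw = glc_per_gdw,
    n_per_gdw = n_per_gdw,
    max_growth = glc_uptake / glc_per_gdw,
    atp_per_glc = 20,
    # marginal ATP value per mol of forced surplus source uptake (sign: gain);
    # the planted preference slope is |value| / atp_per_glc
    n_marginal_atp = c(EX_gln = 7.5, EX_nh4 = -3, EX_ile = -1.5, EX_phe = -1),
    n_pref_order = c("EX_gln", "EX_nh4", "EX_ile", "EX_phe"),
    n_atoms = c(EX_gln = 2, EX_nh4 = 1, EX_ile = 1, EX_phe = 1),
    essential_genes = c("gHXT1", "gMEP1", "gIDH1", "gGDH1", "gZWF1"),
    # genes whose single deletion reduces (without abolishing) optimal growth
    growth_reducing_genes = c("gTCA1", "gTCA2", "gOXP1"),
    # gGLY1A+gGLY1B: both isoenzymes of the sole glucose-phosphorylating
    # step. gADH1+gOXP1: no fermentation and no respiration leaves ATP
    # unattainable (the glycerol shunt disposes of NADH but yields none).
    lethal_pairs = list(c("gGLY1A", "gGLY1B"), c("gGLY2", "gGLY2B"),
                        c("gADH1", "gOXP1")),
    unbalanced_rxns = c("BAD1", "BAD2"),
    unauditable_rxns = "BADX",
    emp_pathway = c("HXK", "PYK"),
    glycerol_branch = c("GPD", "GPP", "GLYCt", "EX_glyc"),
    stress_up_genes = c("gZWF1", "gTCA1", "gTCA2", "gIDH1", "gKGD1",
                        "gGPD1", "gGPD2", "gGPP1", "gGPP2"),
    stress_down_genes = c("gGLY2", "gADH1"),
    # core carbon/energy enzymes are high-abundance transcripts; anchoring
    # them well above the expression threshold keeps their reactions out of
    # the below-threshold penalty set except where the stress repression
    # (gGLY2, gADH1) deliberately pushes them under it
    high_expression_genes = c("gGLY2", "gGLY2B", "gADH1", "gGLY1A", "gGLY1B",
                              "gOXP1", "gTCA1", "gTCA2", "gIDH1", "gZWF1",
                              "gGDH1", "gHXT1", "gMEP1"),
    glc_gene = "gHXT1",
    medium = c(EX_glc = glc_uptake, EX_nh4 = 1000, EX_o2 = 1000, EX_pi = 1000,
               EX_h2o = 1000, EX_h = 1000),
    # oxygen-limited, glucose-forced (chemostat-style) condition used for the
    # single-cell contexts: respiration is capped and glucose must be
    # consumed, so cells that exclude fermentation reoxidise the surplus
    # glycolytic NADH through the glycerol branch
    scgem_medium = c(EX_glc = glc_uptake, EX_nh4 = 1000, EX_o2 = 15,
                     EX_pi = 1000, EX_h2o = 1000, EX_h = 1000)
  )

  if (verify) {
    wt <- fba(model)
    stopifnot(wt$status == "optimal",
              abs(wt$objective - truth$max_growth) < 1e-6 * truth$max_growth)
    genes <- unique(c(unlist(truth$lethal_pairs), truth$essential_genes))
    grid <- double_gene_deletion(model, genes, mode = "gpr")
    lab <- classify_lethality(grid)
    for (g in truth$essential_genes) stopifnot(lab[g, g] == "lethal")
    for (pr in truth$lethal_pairs) {
      stopifnot(lab[pr[1], pr[2]] == "lethal",
                lab[pr[1], pr[1]] == "viable", lab[pr[2], pr[2]] == "viable")
    }
  }
  list(model = model, truth = truth)
}

#' Parent model for the single-cell context pipeline
#'
#' Applies the oxygen-limited medium and forces full glucose consumption
#' (chemostat-style equality on the glucose exchange), the condition under
#' which the fermentation/glycerol overflow split is active and the planted
#' stressed/unstressed flux difference can be expressed.
#'
#' @param toy Output of [make_toy_gem()].
#' @return A constrained [gem()].
#' @export
make_scgem_parent <- function(toy) {
  m <- apply_medium(toy$model, toy$truth$scgem_medium)
  glc <- toy$truth$scgem_medium[["EX_glc"]]
  m$rxns["EX_glc", c("lb", "ub")] <- -glc
  m
}

#' Synthetic single-cell expression profiles with a planted condition shift
#'
#' Log-normal base expression per gene; "stressed" cells shift pentose
#' phosphate, TCA and glycerol-branch genes up and lower glycolysis /
#' fermentation genes down by the effect size; Bernoulli dropout zeroes
#' entries. Defaults mirror the study conditions the module emulates: 80
#' stressed and 83 unstressed cells.
#'
#' @param toy Output of [make_toy_gem()].
#' @param n_stressed,n_unstressed Cells per group (defaults 80 and 83).
#' @param effect Multiplicative effect size (>= 1; default 10, the order of
#'   the strong osmotic induction of the glycerol-branch genes; 1 = none).
#' @param dropout Dropout probability per entry (default 0.1).
#' @param seed Integer seed.
#' @return List with `profiles` (gene x cell matrix), `labels` (named factor
#'   stressed/unstressed), `truth` (shifted gene sets, effect).
#' @export
make_single_cell_profiles <- function(toy, n_stressed = 80, n_unstressed = 83,
                                      effect = 10, dropout = 0.1, seed = 1) {
  stopifnot(effect >= 0)
  genes <- toy$model$genes
  n <- n_stressed + n_unstressed
  labels <- factor(rep(c("stressed", "unstressed"), c(n_stressed, n_unstressed)))
  with_seed(seed, {
    base_mean <- ifelse(genes %in% toy$truth$high_expression_genes, 20, 10)
    base <- stats::rlnorm(length(genes), meanlog = log(base_mean), sdlog = 0.2)
    m <- matrix(stats::rlnorm(length(genes) * n, meanlog = 0, sdlog = 0.4),
                length(genes), n, dimnames = list(genes, paste0("cell", seq_len(n))))
    m <- m * base
    up <- genes %in% toy$truth$stress_up_genes
    dn <- genes %in% toy$truth$stress_down_genes
    stressed <- labels == "stressed"
    if (effect > 0) {
      m[up, stressed] <- m[up, stressed] * effect
      m[dn, stressed] <- m[dn, stressed] / effect
    }
    if (dropout > 0) {
      drop <- matrix(stats::runif(length(m)) < dropout, nrow(m), ncol(m))
      m[drop] <- 0
    }
  })
  names(labels) <- colnames(m)
  list(profiles = m, labels = labels,
       truth = list(up = toy$truth$stress_up_genes,
                    down = toy$truth$stress_down_genes, effect = effect,
                    dropout = dropout))
}

#' Synthetic knockout-strain fold-change profiles with planted growth
#'
#' Each strain knocks out one (or two) genes at the minimal fold and draws a
#' glucose-transporter fold that linearly limits growth on the
#' carbon-limited toy; other genes sit near 1 with a few extreme outliers
#' planted beyond the 1st/99th percentiles to exercise winsorization.
#' Planted expected growth comes from the bound-scaling oracle: wildtype
#' growth times min(1, transporter fold), and 0 for strains knocking out a
#' planted essential metabolic gene.
#'
#' @param toy Output of [make_toy_gem()].
#' @param n_strains Number of strains (default 200).
#' @param fold_range Allowed non-knockout fold range, default c(1/117, 64).
#' @param seed Integer seed.
#' @return List with `strains` (list of id/ko_genes/folds), `meta`
#'   (data.frame strain, ko, rel_doubling_time) and `truth` (planted growth).
#' @export
make_knockout_profiles <- function(toy, n_strains = 200,
                                   fold_range = c(1 / 117, 64), seed = 1) {
  model <- toy$model
  wt <- toy$truth$max_growth
  metab <- model$genes
  nonmetab <- paste0("gREG", seq_len(40)) # regulators outside the model
  ess <- toy$truth$essential_genes
  viable_ko <- setdiff(metab, c(ess, toy$truth$glc_gene,
                                toy$truth$growth_reducing_genes,
                                unlist(toy$truth$lethal_pairs)))
  all_genes <- c(metab, nonmetab)
  with_seed(seed, {
    strains <- lapply(seq_len(n_strains), function(i) {
      kind <- sample(c("nonmetab", "viable", "essential"), 1,
                     prob = c(0.8, 0.12, 0.08))
      ko <- switch(kind,
                   nonmetab = sample(nonmetab, 1),
                   viable = sample(viable_ko, 1),
                   essential = sample(ess, 1))
      folds <- stats::setNames(stats::rlnorm(length(all_genes), 0, 0.05), all_genes)
      # glucose transporter fold drives the planted growth effect
      f_glc <- stats::runif(1, 0.3, 1.3)
      folds[toy$truth$glc_gene] <- f_glc
      # planted extreme outliers beyond the percentile caps, on regulator
      # genes so the raw extremes cannot throttle the model before capping
      out_idx <- sample(setdiff(nonmetab, ko), 2)
      folds[out_idx] <- c(fold_range[2] * 2, fold_range[1] / 2)
      folds[ko] <- fold_range[1]
      planted <- if (kind == "essential") 0 else wt * min(1, f_glc)
      list(id = sprintf("strain%03d", i), ko_genes = ko, folds = folds,
           kind = kind, planted_growth = planted)
    })
    planted <- vapply(strains, `[[`, 0.0, "planted_growth")
    # measured relative doubling time ~ 1/growth with lognormal noise;
    # lethal strains get a large finite doubling time
    dt <- ifelse(planted > 0, wt / planted, 20) *
      stats::rlnorm(length(planted), 0, 0.05)
  })
  meta <- data.frame(strain = vapply(strains, `[[`, "", "id"),
                     ko_gene = vapply(strains, `[[`, "", "ko_genes"),
                     rel_doubling_time = dt, stringsAsFactors = FALSE)
  list(strains = strains, meta = meta,
       truth = list(planted_growth = stats::setNames(
         vapply(strains, `[[`, 0.0, "planted_growth"), meta$strain)))
}

#' Synthetic paired flux/protein condition series with planted slopes
#'
#' For each chosen GPR-bearing reaction, draws a log-normal protein series
#' over `n_conditions` and sets flux = c * protein^rho * exp(noise).
#' Complexes get subunit series whose per-condition minimum reproduces the
#' planted limiting series; isoenzyme pairs get two protein series with
#' distinct planted slopes whose mean is the planted reaction rho.
#'
#' @param toy Output of [make_toy_gem()].
#' @param rho_map Named numeric, reaction id -> planted rho. Default plants a
#'   mixture over single/complex/isoenzyme reactions.
#' @param n_conditions Number of conditions (default 12).
#' @param sigma Log-normal noise sd on flux (default 0.1).
#' @param seed Integer seed.
#' @return List with `flux` (reaction x condition), `protein` (gene x
#'   condition), `truth` (planted rho per reaction, isoenzyme slopes).
#' @export
make_flux_protein_series <- function(toy, rho_map = NULL, n_conditions = 12,
                                     sigma = 0.1, seed = 1) {
  model <- toy$model
  if (is.null(rho_map)) {
    rho_map <- c(PYK = 1, PPP = 0.6, GDH = 0.3, FERM = 0.1, GPD = 0.9,
                 TCA = 0.5, HXK = 0.5, AKGOX = 0.2, GLS = 0.8, UREAS = 0.05)
  }
  conds <- paste0("cond", seq_len(n_conditions))
  flux <- matrix(0, length(rho_map), n_conditions,
                 dimnames = list(names(rho_map), conds))
  prot_rows <- list()
  iso_truth <- list()
  with_seed(seed, {
    for (rid in names(rho_map)) {
      tree <- model$gprs[[rid]]
      branches <- gpr_branches(tree)
      rho <- rho_map[[rid]]
      if (length(branches) == 1L) {
        p <- stats::rlnorm(n_conditions, log(5), 0.8)
        f <- p^rho * exp(stats::rnorm(n_conditions, 0, sigma))
        b <- branches[[1]]
        if (length(b) == 1L) {
          prot_rows[[b]] <- p
        } else {
          # complex: first subunit limits everywhere, others sit above it
          prot_rows[[b[1]]] <- p
          for (g in b[-1]) {
            prot_rows[[g]] <- p * (1 + stats::runif(n_conditions, 0.05, 0.5))
          }
        }
      } else {
        # isoenzymes: per-branch slopes rho +/- 0.2 whose mean is rho
        betas <- rho + c(-0.2, 0.2)
        if (length(branches) > 2L) betas <- rep(rho, length(branches))
        p1 <- stats::rlnorm(n_conditions, log(5), 0.8)
        f <- p1^betas[1] * exp(stats::rnorm(n_conditions, 0, sigma))
        gs <- vapply(branches, `[[`, "", 1)
        prot_rows[[gs[1]]] <- p1
        for (j in seq_along(branches)[-1]) {
          prot_rows[[gs[j]]] <- f^(1 / betas[j])
        }
        iso_truth[[rid]] <- betas
      }
      flux[rid, ] <- f
    }
  })
  protein <- do.call(rbind, prot_rows)
  colnames(protein) <- conds
  list(flux = flux, protein = protein,
       truth = list(rho = rho_map, iso_slopes = iso_truth, sigma = sigma))
}

#' Synthetic phenotype conditions for the nitrogen-limitation pipeline
#'
#' Solves the toy at random fixed growth rates, records its exchange fluxes
#' perturbed by +/-10%, and draws biomass macro-fractions in realistic
#' ranges. Every condition is feasible after the 0.8x measurement
#' relaxation.
#'
#' @param toy Output of [make_toy_gem()].
#' @param n Number of conditions.
#' @param seed Integer seed.
#' @return List of condition lists (id, exchanges, growth, protein,
#'   carbohydrate, rna) as consumed by [nitrogen_condition_pfba()].
#' @export
make_phenotype_conditions <- function(toy, n = 4, seed = 1) {
  model <- toy$model
  ex <- c("EX_glc", "EX_o2") # measured uptake rates (chemostat style)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      g <- stats::runif(1, 0.05, 0.25)
      m <- fix_growth(model, g)
      sol <- pfba(m, objective = "ATPM")
      stopifnot(sol$status == "optimal")
      meas <- sol$fluxes[ex] * stats::runif(length(ex), 0.9, 1.1)
      fr <- c(protein = stats::runif(1, 0.38, 0.55),
              carbohydrate = stats::runif(1, 0.3, 0.45),
              rna = stats::runif(1, 0.05, 0.12))
      list(id = paste0("cond", i), exchanges = meas, growth = g,
           protein = fr[["protein"]], carbohydrate = fr[["carbohydrate"]],
           rna = fr[["rna"]])
    })
  })
}
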