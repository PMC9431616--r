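# Seeded toy ME models of an anaerobic photoheterotroph.
#
# The generator emulates the architecture that drives the biology of
# interest: organic substrates spanning a range of carbon oxidation
# states, a lumped TCA-like oxidation producing NADH and CO2, cyclic
# photophosphorylation (photosystem -> quinone pool -> bc1 -> pmf-driven
# ATP synthase) with a ferredoxin-reduction branch (ETFD), a
# Calvin-Benson-Bassham module with distinct form I/II rubiscos,
# pentose drain to nucleotides, three nitrogenase isozymes with ordered
# ATP costs, malate dehydrogenase and glycerol-3-phosphate
# dehydrogenase as NADH-reoxidizing sinks, and a growth-coupled
# transcription/translation layer. Every metabolic reaction is
# elementally balanced; redox carriers are written as explicit
# H-carrying pairs (NADH = NAD + 2H, QH2 = Q + 2H, reduced ferredoxin =
# oxidized + H) so that balance is checkable from formulas alone.

SUBSTRATE_TABLE <- tibble::tibble(
  name    = c("acetate", "succinate", "butyrate", "p-coumarate"),
  id      = c("ac", "succ", "but", "pcou"),
  formula = c("C2H4O2", "C4H6O4", "C4H8O2", "C9H8O3"),
  ## carbons lost as CO2 during TCA-route anabolism of each molecule;
  ## the released CO2 + NADH create the internal refixation pressure
  anabolic_co2 = c(1L, 2L, 1L, 2L)
)

#' Configuration for the toy photoheterotroph network
#'
#' @param seed integer seed; a fixed seed gives byte-identical models.
#' @param n_filler_reactions number of inert filler conversions carrying
#'   the generic enzyme (default 10).
#' @param substrates subset of acetate, succinate, butyrate, p-coumarate.
#' @param include_expression_layer add genes, transcription, translation
#'   and enzyme coupling (TRUE gives an ME model, FALSE a plain M model).
#' @param nitrogenase_atp_costs named vector of ATP consumed per N2 for
#'   Mo, V and Fe nitrogenase; the ordering Mo < V < Fe is enforced.
#' @param photon_uptake_cap maximal photon uptake, mmol/gDW/day.
#' @param atp_caps named vector of maximal photosynthetic ATP production
#'   per substrate, mmol/gDW/day.
#' @param params list of overrides for the lumped-network free
#'   parameters (see Details in the package vignette): \code{pmf_per_qh2},
#'   \code{pmf_per_atp}, \code{gam_atp}, \code{biomass} composition,
#'   \code{gc_fraction}, \code{kcat}, \code{coupling}.
#' @return object of class \code{toy_network_config}.
#' @export
toy_network_config <- function(seed = 1L,
                               n_filler_reactions = 10L,
                               substrates = SUBSTRATE_TABLE$name,
                               include_expression_layer = TRUE,
                               nitrogenase_atp_costs = c(Mo = 16, V = 24, Fe = 40),
                               photon_uptake_cap = 150,
                               atp_caps = c(acetate = 54.0, succinate = 45.7,
                                            butyrate = 56.7, `p-coumarate` = 85.4),
                               params = list()) {
  substrates <- match.arg(substrates, SUBSTRATE_TABLE$name, several.ok = TRUE)
  costs <- nitrogenase_atp_costs[c("Mo", "V", "Fe")]
  if (anyNA(costs)) stop("nitrogenase_atp_costs must name Mo, V and Fe")
  if (!(costs[["Mo"]] < costs[["V"]] && costs[["V"]] < costs[["Fe"]])) {
    stop("nitrogenase ATP costs must be ordered Mo < V < Fe")
  }
  defaults <- list(
    pmf_per_qh2 = 3, pmf_per_atp = 2, gam_atp = 15,
    transport_atp = 1, hyd_cap = 2,
    nitrogenase_fd = c(Mo = 8, V = 12, Fe = 20),
    biomass = c(biomass_protein = 0.55, biomass_mrna = 0.03,
                aa_c = 1.8, r5p_c = 0.35, g3p_c = 0.45),
    gc_fraction = 0.65,
    ntp_syn_atp = 2,
    kcat = kcat_defaults(),
    coupling = coupling_params()
  )
  params <- utils::modifyList(defaults, params)
  structure(list(
    seed = as.integer(seed), n_filler_reactions = as.integer(n_filler_reactions),
    substrates = substrates,
    include_expression_layer = isTRUE(include_expression_layer),
    nitrogenase_atp_costs = costs, photon_uptake_cap = photon_uptake_cap,
    atp_caps = atp_caps, params = params
  ), class = "toy_network_config")
}

## run code under a local RNG state so model building never perturbs the
## caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## seeded coding sequence: ATG start, no stop codons, GC-biased codon draw
random_coding_sequence <- function(n_nt, gc_fraction = 0.65) {
  stopifnot(n_nt %% 3 == 0, n_nt >= 6)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  gc_count <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), 0L)
  w <- (gc_fraction / (1 - gc_fraction))^(gc_count - 1.5)
  body <- sample(codons, n_nt / 3 - 1, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""))
}

## adjust water and the NAD/NADH pair so a reaction balances in H and O;
## all other elements must already balance
auto_balance <- function(stoich, formulas) {
  imb <- stoich_element_imbalance(stoich, formulas)
  w <- if ("O" %in% names(imb)) -imb[["O"]] else 0
  h <- (if ("H" %in% names(imb)) imb[["H"]] else 0) + 2 * w
  d <- -h / 2
  add <- c(h2o_c = w, nadh_c = d, nad_c = -d)
  for (sp in names(add)) {
    if (add[[sp]] != 0) {
      stoich[sp] <- (if (sp %in% names(stoich)) stoich[[sp]] else 0) + add[[sp]]
    }
  }
  stoich <- stoich[stoich != 0]
  resid <- stoich_element_imbalance(stoich, formulas)
  if (length(resid)) {
    stop("auto_balance failed: residual ", paste(names(resid), resid, collapse = " "))
  }
  stoich
}

#' Register the three nitrogenase isozymes on a model
#'
#' Adds (or replaces) three independent nitrogen-fixation reactions
#' consuming reduced ferredoxin and ATP and producing ammonia plus
#' obligatory hydrogen, with ATP costs ordered Mo < V < Fe. When enzyme
#' complexes \code{nase_mo}/\code{nase_v}/\code{nase_fe} exist, the
#' reactions are coupled to them and the enzymes receive SASA-normalized
#' turnover numbers unless explicit kcats are supplied.
#'
#' @param model an \code{me_model} with species \code{n2_c},
#'   \code{fd_red_c}, \code{fd_ox_c}, \code{atp_c}, \code{adp_c},
#'   \code{pi_c}, \code{h2o_c}, \code{nh3_c}, \code{h2_c}.
#' @param costs named ATP cost per N2 (Mo, V, Fe); must be increasing.
#' @param kcats optional named turnover overrides (day^-1).
#' @param fd_costs named reduced-ferredoxin cost per N2 (electron
#'   carriers; defaults Mo 8, V 12, Fe 20).
#' @param strict require strictly increasing ATP costs (the default);
#'   \code{FALSE} permits ties, which make the parsimonious isozyme
#'   choice degenerate (report [flux_range()] instead of a winner).
#' @return the model with reactions \code{NFIX_Mo}, \code{NFIX_V},
#'   \code{NFIX_Fe}.
#' @export
register_nitrogenases <- function(model, costs = c(Mo = 16, V = 24, Fe = 40),
                                  kcats = NULL,
                                  fd_costs = c(Mo = 8, V = 12, Fe = 20),
                                  strict = TRUE) {
  costs <- costs[c("Mo", "V", "Fe")]
  if (anyNA(costs)) stop("costs must name Mo, V and Fe")
  ordered <- if (strict) {
    costs[["Mo"]] < costs[["V"]] && costs[["V"]] < costs[["Fe"]]
  } else {
    costs[["Mo"]] <= costs[["V"]] && costs[["V"]] <= costs[["Fe"]]
  }
  if (!ordered) stop("nitrogenase ATP costs must be ordered Mo < V < Fe")
  enz_ids <- c(Mo = "nase_mo", V = "nase_v", Fe = "nase_fe")
  for (iso in c("Mo", "V", "Fe")) {
    a <- costs[[iso]]; e <- fd_costs[[iso]]
    stoich <- c(n2_c = -1, fd_red_c = -e, atp_c = -a, h2o_c = -a,
                nh3_c = 2, h2_c = (e - 6) / 2, fd_ox_c = e,
                adp_c = a, pi_c = a)
    rid <- paste0("NFIX_", iso)
    ri <- match(rid, model$reactions$id)
    if (!is.na(ri)) {
      model$reactions$stoich[[ri]] <- stoich
    } else {
      model <- add_reaction(model, rid, stoich,
                            name = paste0(iso, "-nitrogenase"),
                            gpr = NA_character_)
    }
    eid <- enz_ids[[iso]]
    if (eid %in% model$enzymes$id) {
      if (!is.null(kcats) && iso %in% names(kcats)) {
        model <- set_enzyme_kcat(model, eid, kcats[[iso]])
      }
      ri2 <- match(rid, model$reactions$id)
      if (!eid %in% names(model$reactions$mu_coupled[[ri2]])) {
        model <- attach_enzyme_usage(model, rid, eid)
      }
    }
  }
  model
}

#' Change an enzyme's turnover number
#'
#' Updates the registered kcat and every mu-coupled usage term that
#' references the enzyme (coefficients are stored as 1/kcat).
#'
#' @param model an \code{me_model}.
#' @param enzyme_id enzyme to modify.
#' @param kcat new turnover, day^-1; positive.
#' @return the updated model.
#' @export
set_enzyme_kcat <- function(model, enzyme_id, kcat) {
  i <- match(enzyme_id, model$enzymes$id)
  if (is.na(i)) stop("unknown enzyme: ", enzyme_id)
  if (!is.finite(kcat) || kcat <= 0) stop("kcat must be positive")
  model$enzymes$kcat[i] <- kcat
  for (ri in seq_len(nrow(model$reactions))) {
    mc <- model$reactions$mu_coupled[[ri]]
    if (enzyme_id %in% names(mc)) {
      mc[[enzyme_id]] <- 1 / kcat
      model$reactions$mu_coupled[[ri]] <- mc
    }
  }
  model
}

#' Build a seeded toy ME model of a photoheterotroph
#'
#' See the package vignette for the full network map and the rationale
#' behind each lumped stoichiometry. The returned model is validated:
#' every metabolic reaction conserves elements, the nitrogenase ATP
#' ordering holds, and a fixed seed reproduces the model byte for byte.
#'
#' @param config a [toy_network_config()].
#' @return a validated \code{me_model}.
#' @export
build_toy_me_model <- function(config = toy_network_config()) {
  stopifnot(inherits(config, "toy_network_config"))
  with_local_seed(config$seed, build_toy_impl(config))
}

build_toy_impl <- function(config) {
  p <- config$params
  m <- me_model(id = sprintf("toy_me_seed%d", config$seed),
                coupling = p$coupling)
  subs <- SUBSTRATE_TABLE[SUBSTRATE_TABLE$name %in% config$substrates, ]

  ## ---- species ----------------------------------------------------------
  sm <- function(mod, id, f, comp = "c", name = id) {
    add_metabolite(mod, id, name = name, formula = f, compartment = comp)
  }
  m <- sm(m, "co2_c", "CO2"); m <- sm(m, "co2_e", "CO2", "e")
  m <- sm(m, "h2o_c", "H2O"); m <- sm(m, "h2o_e", "H2O", "e")
  m <- sm(m, "nad_c", "C21H27N7O14P2"); m <- sm(m, "nadh_c", "C21H29N7O14P2")
  m <- sm(m, "atp_c", "C10H16N5O13P3"); m <- sm(m, "adp_c", "C10H15N5O10P2")
  m <- sm(m, "pi_c", "H3PO4"); m <- sm(m, "pi_e", "H3PO4", "e")
  m <- sm(m, "photon_c", ""); m <- sm(m, "photon_e", "", "e")
  m <- sm(m, "pmf_c", "")
  m <- sm(m, "q_c", "C6H4O2"); m <- sm(m, "qh2_c", "C6H6O2")
  m <- sm(m, "cytc_ox_c", "Fe"); m <- sm(m, "cytc_red_c", "HFe")
  m <- sm(m, "fd_ox_c", "Fe2S2"); m <- sm(m, "fd_red_c", "HFe2S2")
  m <- sm(m, "n2_c", "N2"); m <- sm(m, "n2_e", "N2", "e")
  m <- sm(m, "nh3_c", "H3N"); m <- sm(m, "nh3_e", "H3N", "e")
  m <- sm(m, "h2_c", "H2"); m <- sm(m, "h2_e", "H2", "e")
  m <- sm(m, "cu_c", "CH2O")
  m <- sm(m, "oaa_c", "C4H4O5")
  m <- sm(m, "mal_c", "C4H6O5"); m <- sm(m, "mal_e", "C4H6O5", "e")
  m <- sm(m, "aa_c", "C4H11NO4")
  m <- sm(m, "ru5p_c", "C5H10O5"); m <- sm(m, "r5p_c", "C5H10O5")
  m <- sm(m, "rubp_c", "C5H12O11P2"); m <- sm(m, "pga_c", "C3H7O7P")
  m <- sm(m, "gap_c", "C3H7O6P"); m <- sm(m, "dhap_c", "C3H7O6P")
  m <- sm(m, "g3p_c", "C3H9O6P")
  m <- sm(m, "glyc_c", "C3H8O3"); m <- sm(m, "glyc_e", "C3H8O3", "e")
  m <- sm(m, "ntp_a", "C10H14N5O7P"); m <- sm(m, "ntp_c", "C9H14N3O8P")
  m <- sm(m, "ntp_g", "C10H14N5O8P"); m <- sm(m, "ntp_u", "C9H13N2O9P")
  for (i in seq_len(nrow(subs))) {
    m <- sm(m, paste0(subs$id[i], "_e"), subs$formula[i], "e", subs$name[i])
    m <- sm(m, paste0(subs$id[i], "_c"), subs$formula[i], "c", subs$name[i])
  }
  m <- add_metabolite(m, "biomass_protein", kind = "biomass-component")
  m <- add_metabolite(m, "biomass_mrna", kind = "biomass-component")

  formulas <- stats::setNames(lapply(m$metabolites$formula, parse_formula),
                              m$metabolites$id)

  ## ---- exchanges and transport -----------------------------------------
  ex <- function(mod, sp, lb, ub, id = paste0("EX_", sub("_e$", "", sp))) {
    add_reaction(mod, id, stats::setNames(-1, sp), lb = lb, ub = ub,
                 rclass = "exchange")
  }
  for (i in seq_len(nrow(subs))) {
    m <- ex(m, paste0(subs$id[i], "_e"), 0, 0)  # uptake opened per solve
    ## active transport: one ATP equivalent per molecule imported
    st <- stats::setNames(
      c(-1, 1, -p$transport_atp, -p$transport_atp,
        p$transport_atp, p$transport_atp),
      c(paste0(subs$id[i], c("_e", "_c")), "atp_c", "h2o_c", "adp_c", "pi_c"))
    m <- add_reaction(m, paste0("UPT_", subs$id[i]), st,
                      name = paste0(subs$name[i], " uptake (active transport)"))
  }
  m <- ex(m, "photon_e", -config$photon_uptake_cap, 0)
  m <- add_reaction(m, "UPT_photon", c(photon_e = -1, photon_c = 1))
  m <- ex(m, "co2_e", 0, 1000)       # net CO2 secretion only
  m <- ex(m, "h2o_e", -1000, 1000)
  m <- ex(m, "n2_e", -1000, 1000)
  m <- add_reaction(m, "UPT_n2", c(n2_e = -1, n2_c = 1))
  m <- ex(m, "pi_e", -1000, 1000)
  m <- add_reaction(m, "UPT_pi", c(pi_e = -1, pi_c = 1))
  m <- ex(m, "nh3_e", 0, 1000)
  m <- ex(m, "h2_e", 0, 1000)
  m <- ex(m, "mal_e", 0, 1000)
  m <- ex(m, "glyc_e", 0, 1000)
  m <- add_reaction(m, "SEC_co2", c(co2_c = -1, co2_e = 1))
  m <- add_reaction(m, "TR_h2o", c(h2o_e = -1, h2o_c = 1), lb = -1000)
  m <- add_reaction(m, "SEC_nh3", c(nh3_c = -1, nh3_e = 1))
  m <- add_reaction(m, "SEC_h2", c(h2_c = -1, h2_e = 1))
  m <- add_reaction(m, "SEC_mal", c(mal_c = -1, mal_e = 1))
  m <- add_reaction(m, "SEC_glyc", c(glyc_c = -1, glyc_e = 1))

  ## ---- catabolism and assimilation -------------------------------------
  for (i in seq_len(nrow(subs))) {
    f <- parse_formula(subs$formula[i])
    x <- f[["C"]]; y <- f[["H"]]; z <- f[["O"]]
    ne <- 4 * x + y - 2 * z              # electrons on full oxidation
    cid <- paste0(subs$id[i], "_c")
    m <- add_reaction(m, paste0("CAT_", subs$id[i]),
      auto_balance(stats::setNames(c(-1, x), c(cid, "co2_c")), formulas),
      name = paste0(subs$name[i], " oxidation (TCA-like)"))
    ## anabolism runs through the TCA route: a fixed number of carbons per
    ## molecule is lost as CO2 and the corresponding reducing equivalents
    ## are released as NADH, so refixation through the CBB module is
    ## required to recover maximal yield
    k <- subs$anabolic_co2[i]
    st <- auto_balance(stats::setNames(c(-1, x - k, k),
                                       c(cid, "cu_c", "co2_c")), formulas)
    m <- add_reaction(m, paste0("ASM_", subs$id[i]), st,
                      name = paste0(subs$name[i], " assimilation"))
  }

  ## ---- cyclic photophosphorylation and ETFD ----------------------------
  m <- add_reaction(m, "NDH", c(nadh_c = -1, q_c = -1, nad_c = 1, qh2_c = 1),
                    name = "NADH dehydrogenase (quinone reduction)")
  m <- add_reaction(m, "BC1",
    c(qh2_c = -1, cytc_ox_c = -2, q_c = 1, cytc_red_c = 2,
      pmf_c = p$pmf_per_qh2),
    name = "bc1 complex (proton-pumping quinol oxidation)")
  m <- add_reaction(m, "ATPS",
    c(pmf_c = -p$pmf_per_atp, adp_c = -1, pi_c = -1, atp_c = 1, h2o_c = 1),
    name = "pmf-driven ATP synthase")
  m <- add_reaction(m, "PMF_LEAK", c(pmf_c = -1),
    name = "proton leak (pmf dissipation)")
  m <- add_reaction(m, "PS_Q",
    c(photon_c = -1, cytc_red_c = -2, q_c = -1, cytc_ox_c = 2, qh2_c = 1),
    name = "photosystem (cyclic, quinone-reducing)")
  m <- add_reaction(m, "ETFD",
    c(photon_c = -1, cytc_red_c = -2, fd_ox_c = -2,
      cytc_ox_c = 2, fd_red_c = 2),
    name = "electron transport through ferredoxin")
  ## capacity-limited ferredoxin hydrogenase: vents excess reductant as H2
  m <- add_reaction(m, "HYD",
    c(fd_red_c = -2, h2_c = 1, fd_ox_c = 2), ub = p$hyd_cap,
    name = "ferredoxin hydrogenase (H2 evolution)")

  ## ---- CBB module, pentose drain, sinks --------------------------------
  m <- add_reaction(m, "RU5P_SYN",
    c(cu_c = -5, atp_c = -1, h2o_c = -1, ru5p_c = 1, adp_c = 1, pi_c = 1),
    name = "ribulose-5-phosphate synthesis")
  m <- add_reaction(m, "PRK",
    c(ru5p_c = -1, atp_c = -2, rubp_c = 1, adp_c = 2),
    name = "phosphoribulokinase")
  m <- add_reaction(m, "RBC_I",
    c(rubp_c = -1, co2_c = -1, h2o_c = -1, pga_c = 2),
    name = "rubisco form I carboxylation")
  m <- add_reaction(m, "RBC_II",
    c(rubp_c = -1, co2_c = -1, h2o_c = -1, pga_c = 2),
    name = "rubisco form II carboxylation")
  m <- add_reaction(m, "PGARED",
    c(pga_c = -1, atp_c = -1, nadh_c = -1, gap_c = 1, adp_c = 1,
      pi_c = 1, nad_c = 1),
    name = "phosphoglycerate reduction (NADH)")
  m <- add_reaction(m, "PGARED_FD",
    c(pga_c = -1, atp_c = -1, fd_red_c = -2, gap_c = 1, adp_c = 1,
      pi_c = 1, fd_ox_c = 2),
    name = "phosphoglycerate reduction (ferredoxin)")
  m <- add_reaction(m, "GAPCU",
    c(gap_c = -1, h2o_c = -1, cu_c = 3, pi_c = 1),
    name = "triose to carbon units")
  m <- add_reaction(m, "RPI", c(ru5p_c = -1, r5p_c = 1),
    name = "ribulose-5P to ribose-5P (pentose drain)")
  m <- add_reaction(m, "CU_GAP",
    c(cu_c = -3, pi_c = -1, gap_c = 1, h2o_c = 1),
    name = "triose phosphate synthesis")
  m <- add_reaction(m, "TPI", c(gap_c = -1, dhap_c = 1),
    name = "triose phosphate isomerase")
  m <- add_reaction(m, "G3PDH",
    c(dhap_c = -1, nadh_c = -1, g3p_c = 1, nad_c = 1),
    name = "glycerol-3-phosphate dehydrogenase")
  m <- add_reaction(m, "G3P_SEC",
    c(g3p_c = -1, h2o_c = -1, glyc_c = 1, pi_c = 1),
    name = "glycerol release")
  ## two amino-acid routes: the direct ATP-dependent one, and the
  ## ATP-free TCA-style detour through oxaloacetate/malate whose MDH step
  ## reoxidizes NADH; the cell switches to the malate route when the
  ## photosynthetic ATP cap binds
  m <- add_reaction(m, "OAA_SYN",
    c(cu_c = -4, h2o_c = -1, nad_c = -3, oaa_c = 1, nadh_c = 3),
    name = "oxaloacetate synthesis (oxidative TCA route)")
  m <- add_reaction(m, "MDH",
    c(oaa_c = -1, nadh_c = -1, mal_c = 1, nad_c = 1),
    name = "malate dehydrogenase")
  m <- add_reaction(m, "AAS",
    c(mal_c = -1, nh3_c = -1, nadh_c = -2, aa_c = 1, nad_c = 2, h2o_c = 1),
    name = "amino-acid synthesis via malate")
  m <- add_reaction(m, "PREC",
    c(cu_c = -4, nh3_c = -1, atp_c = -2, h2o_c = -2,
      aa_c = 1, adp_c = 2, pi_c = 2),
    name = "amino-acid synthesis (direct)")

  ## NTP-equivalent synthesis from ribose-5P, carbon units and ammonia
  for (base in c("a", "c", "g", "u")) {
    sp <- paste0("ntp_", base)
    f <- formulas[[sp]]
    st <- stats::setNames(
      c(-1, -(f[["C"]] - 5), -f[["N"]], -1, -p$ntp_syn_atp, 1,
        p$ntp_syn_atp, p$ntp_syn_atp),
      c("r5p_c", "cu_c", "nh3_c", "pi_c", "atp_c", sp, "adp_c", "pi_c"))
    ## duplicated pi entries: collapse
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    m <- add_reaction(m, paste0("NTPSYN_", base),
                      auto_balance(st, formulas),
                      name = paste0("NTP synthesis (", toupper(base), ")"))
  }

  ## ---- nitrogenases -----------------------------------------------------
  m <- register_nitrogenases(m, costs = config$nitrogenase_atp_costs,
                             fd_costs = p$nitrogenase_fd)

  ## ---- filler reactions -------------------------------------------------
  nf <- config$n_filler_reactions
  n_sp <- max(0L, ceiling(nf / 2))
  made <- 0L
  for (i in seq_len(n_sp)) {
    fm <- paste0("fm", i, "_c")
    m <- sm(m, fm, "CH2O")
    if (made < nf) {
      m <- add_reaction(m, paste0("FIL", i, "_f"),
                        stats::setNames(c(-1, 1), c("cu_c", fm)))
      made <- made + 1L
    }
    if (made < nf) {
      m <- add_reaction(m, paste0("FIL", i, "_b"),
                        stats::setNames(c(-1, 1), c(fm, "cu_c")))
      made <- made + 1L
    }
  }

  ## ---- biomass ----------------------------------------------------------
  bio <- p$biomass
  if (!config$include_expression_layer) {
    ## M-style biomass: protein and RNA demands folded into precursor and
    ## energy terms
    prot_aa <- bio[["biomass_protein"]] * 1000 / (p$coupling$m_aa * 1000)
    comp <- c(aa_c = unname(bio[["aa_c"]] + prot_aa),
              r5p_c = unname(bio[["r5p_c"]] + 0.1),
              g3p_c = unname(bio[["g3p_c"]]),
              atp_c = p$gam_atp + p$coupling$atp_per_aa * prot_aa,
              h2o_c = p$gam_atp + p$coupling$atp_per_aa * prot_aa,
              adp_c = -(p$gam_atp + p$coupling$atp_per_aa * prot_aa),
              pi_c = -(p$gam_atp + p$coupling$atp_per_aa * prot_aa))
    m <- add_biomass_dilution(m, comp)
  } else {
    comp <- c(bio,
              atp_c = p$gam_atp, h2o_c = p$gam_atp,
              adp_c = -p$gam_atp, pi_c = -p$gam_atp)
    m <- add_biomass_dilution(m, comp)
  }

  ## ---- expression layer -------------------------------------------------
  if (config$include_expression_layer) {
    m <- add_expression_layer(m, config)
  }

  validate_me_model(m)
  m
}

## gene roster: fixed lengths for the named machinery, seeded fillers
toy_gene_lengths <- function() {
  c(rbcL1 = 810L, rbcS1 = 330L, rbcL2 = 840L,
    nifH = 540L, nifD = 900L, vnfH = 540L, vnfD = 900L,
    anfH = 540L, anfD = 900L,
    mdh = 600L, gpsA = 630L,
    rpoA = 600L, rpoB = 900L, rpoC = 900L, rpoZ = 210L,
    rplX = 330L, rpsX = 300L, genP = 849L,
    fillerA_1 = 450L, fillerA_2 = 450L)
}

add_expression_layer <- function(m, config) {
  p <- config$params
  cp <- m$coupling
  lens <- toy_gene_lengths()
  gc <- p$gc_fraction

  ## genes with seeded sequences
  for (g in names(lens)) {
    m <- add_gene(m, g, random_coding_sequence(lens[[g]], gc),
                  product = paste0("P_", g))
  }
  ## structural rRNA genes: seeded sequence, no translation product
  rrna_len <- c(rrna_5s = cp$ribosome_composition$rrna_5s_nt,
                rrna_23s = cp$ribosome_composition$rrna_23s_nt,
                rrna_16s = cp$ribosome_composition$rrna_16s_nt)
  for (g in names(rrna_len)) {
    n <- rrna_len[[g]]
    seqc <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                  collapse = "")
    m <- add_gene(m, g, seqc, product = NA_character_)
  }

  ## protein species first (so machinery complexes can be registered
  ## before their own expression reactions exist)
  for (g in names(lens)) {
    prot <- translate_dna(m$genes$sequence[match(g, m$genes$locus_tag)])
    mw <- if (g == "genP") 31.09 else molecular_weight(prot, "protein")
    m <- add_metabolite(m, paste0("P_", g), name = paste0(g, " protein"),
                        kind = "protein", mw = mw)
  }

  mwof <- function(mod, sp) mod$metabolites$mw[match(sp, mod$metabolites$id)]
  kd <- p$kcat

  ## machinery
  m <- add_enzyme(m, "rnap",
                  c(P_rpoA = 2, P_rpoB = 1, P_rpoC = 1, P_rpoZ = 1),
                  kcat = cp$k_rnap_nt)
  m <- add_enzyme(m, "ribosome", c(P_rplX = 31, P_rpsX = 21),
                  kcat = cp$k_ribosome_aa,
                  mw = 31 * mwof(m, "P_rplX") + 21 * mwof(m, "P_rpsX") + cp$m_rr)
  ## catalytic complexes
  m <- add_enzyme(m, "rubisco_I", c(P_rbcL1 = 8, P_rbcS1 = 8),
                  kcat = convert_per_site_kcat(kd$rubisco_I_kcat, 8),
                  active_sites = 8L)
  m <- add_enzyme(m, "rubisco_II", c(P_rbcL2 = 2),
                  kcat = convert_per_site_kcat(kd$rubisco_II_kcat, 2),
                  active_sites = 2L)
  m <- add_enzyme(m, "nase_mo", c(P_nifH = 2, P_nifD = 2), defaults = kd)
  m <- add_enzyme(m, "nase_v", c(P_vnfH = 2, P_vnfD = 2), defaults = kd)
  m <- add_enzyme(m, "nase_fe", c(P_anfH = 2, P_anfD = 2), defaults = kd)
  m <- add_enzyme(m, "mdh_enz", c(P_mdh = 2), defaults = kd)
  m <- add_enzyme(m, "g3pdh_enz", c(P_gpsA = 2), defaults = kd)
  m <- add_enzyme(m, "generic", c(P_genP = 1), kcat = kd$kcat_mean,
                  mw = 31.09)
  m <- add_enzyme(m, "filler_enzA1", c(P_fillerA_1 = 1), defaults = kd)
  m <- add_enzyme(m, "filler_enzA2", c(P_fillerA_2 = 1), defaults = kd)

  ## transcription (rnap now registered), then translation
  for (g in names(lens)) m <- build_transcription_reaction(m, g)
  for (g in names(rrna_len)) {
    m <- build_transcription_reaction(m, g, rna_species = g, structural = TRUE)
  }
  for (g in names(lens)) {
    m <- build_translation_reaction(
      m, g, protein_mw = if (g == "genP") 31.09 else NULL)
  }

  ## complex assembly (ribosome additionally consumes its rRNAs)
  m <- add_complex_formation(m, "rnap")
  m <- add_complex_formation(m, "ribosome",
                             extra = c(rrna_5s = 1, rrna_23s = 1, rrna_16s = 1))
  for (e in c("rubisco_I", "rubisco_II", "nase_mo", "nase_v", "nase_fe",
              "mdh_enz", "g3pdh_enz", "generic", "filler_enzA1",
              "filler_enzA2")) {
    m <- add_complex_formation(m, e)
  }

  ## couple named reactions to their enzymes
  m <- attach_enzyme_usage(m, "RBC_I", "rubisco_I")
  m$reactions$gpr[reaction_index(m, "RBC_I")] <- "rbcL1 and rbcS1"
  m <- attach_enzyme_usage(m, "RBC_II", "rubisco_II")
  m$reactions$gpr[reaction_index(m, "RBC_II")] <- "rbcL2"
  m <- attach_enzyme_usage(m, "NFIX_Mo", "nase_mo")
  m$reactions$gpr[reaction_index(m, "NFIX_Mo")] <- "nifH and nifD"
  m <- attach_enzyme_usage(m, "NFIX_V", "nase_v")
  m$reactions$gpr[reaction_index(m, "NFIX_V")] <- "vnfH and vnfD"
  m <- attach_enzyme_usage(m, "NFIX_Fe", "nase_fe")
  m$reactions$gpr[reaction_index(m, "NFIX_Fe")] <- "anfH and anfD"
  m <- attach_enzyme_usage(m, "MDH", "mdh_enz")
  m$reactions$gpr[reaction_index(m, "MDH")] <- "mdh"
  m <- attach_enzyme_usage(m, "G3PDH", "g3pdh_enz")
  m$reactions$gpr[reaction_index(m, "G3PDH")] <- "gpsA"

  ## filler reaction 1 gets an isozyme pair: duplicate catalysed copies
  if ("FIL1_f" %in% model_rids(m)) {
    ri <- reaction_index(m, "FIL1_f")
    m <- add_reaction(m, "FIL1_f_iso2", m$reactions$stoich[[ri]],
                      name = "filler 1 (isozyme 2)")
    m <- attach_enzyme_usage(m, "FIL1_f", "filler_enzA1")
    m$reactions$gpr[reaction_index(m, "FIL1_f")] <- "fillerA_1"
    m <- attach_enzyme_usage(m, "FIL1_f_iso2", "filler_enzA2")
    m$reactions$gpr[reaction_index(m, "FIL1_f_iso2")] <- "fillerA_2"
  }

  ## everything else catalysed carries the generic enzyme
  generic_rxns <- c(paste0("UPT_", c(subs_ids(config), "photon", "n2", "pi")),
                    paste0("CAT_", subs_ids(config)),
                    paste0("ASM_", subs_ids(config)),
                    "SEC_co2", "SEC_nh3", "SEC_h2", "SEC_mal", "SEC_glyc",
                    "NDH", "BC1", "ATPS", "PS_Q", "ETFD", "HYD",
                    "RU5P_SYN", "PRK", "PGARED", "PGARED_FD", "GAPCU", "RPI",
                    "CU_GAP", "TPI", "G3P_SEC", "OAA_SYN", "AAS", "PREC",
                    paste0("NTPSYN_", c("a", "c", "g", "u")),
                    grep("^FIL[0-9]+_[fb]$", model_rids(m), value = TRUE))
  generic_rxns <- setdiff(generic_rxns, c("FIL1_f"))
  for (r in intersect(generic_rxns, model_rids(m))) {
    m <- attach_enzyme_usage(m, r, "generic")
  }

  ## turnover sinks so excess machinery and transcripts are allowed
  for (g in names(lens)) {
    m <- add_reaction(m, paste0("DM_P_", g),
                      stats::setNames(-1, paste0("P_", g)),
                      rclass = "demand", name = paste0(g, " protein turnover"))
    m <- add_reaction(m, paste0("DM_mrna_", g),
                      stats::setNames(-1, paste0("mrna_", g)),
                      rclass = "demand", name = paste0(g, " mRNA turnover"))
  }
  m
}

subs_ids <- function(config) {
  SUBSTRATE_TABLE$id[SUBSTRATE_TABLE$name %in% config$substrates]
}

model_rids <- function(model) model$reactions$id

#' Substrate lookup: display name to internal id
#' @keywords internal
substrate_id <- function(substrate) {
  i <- match(substrate, SUBSTRATE_TABLE$name)
  if (is.na(i)) stop("unknown substrate: ", substrate,
                     " (expected one of ",
                     paste(SUBSTRATE_TABLE$name, collapse = ", "), ")")
  SUBSTRATE_TABLE$id[i]
}

#' Build an expression fixture with a known validation accuracy
#'
#' Draws seeded per-gene transcription fluxes for two conditions and an
#' experimental fold-change direction table that contradicts the
#' simulated direction for exactly \code{n_mismatches} genes, so the
#' downstream accuracy equals \code{(n_genes - n_mismatches)/n_genes}.
#'
#' @param model an \code{me_model} with an expression layer (protein-coding
#'   genes), or \code{NULL} with \code{gene_ids} given explicitly.
#' @param seed integer seed.
#' @param n_mismatches number of genes whose experimental direction is
#'   flipped relative to the simulated one; at most the number of genes.
#' @param gene_ids optional explicit gene id vector (overrides the model).
#' @return tibble with columns \code{gene_id}, \code{flux_A},
#'   \code{flux_B}, \code{experimental_direction}, and attribute
#'   \code{n_injected_mismatches}.
#' @export
make_expression_fixture <- function(model = NULL, seed = 1L, n_mismatches = 0L,
                                    gene_ids = NULL) {
  if (is.null(gene_ids)) {
    if (is.null(model) || !nrow(model$genes)) {
      stop("model with an expression layer (or explicit gene_ids) required")
    }
    gene_ids <- model$genes$locus_tag[!is.na(model$genes$product)]
  }
  n <- length(gene_ids)
  if (n_mismatches > n) stop("n_mismatches exceeds the number of genes (", n, ")")
  with_local_seed(seed, {
    flux_A <- stats::runif(n, 0.1, 10)
    flux_B <- stats::runif(n, 0.1, 10)
    ## avoid exact ties so every gene has a defined direction
    tie <- abs(flux_A / flux_B - 1) < 1e-8
    flux_A[tie] <- flux_A[tie] * 1.5
    model_dir <- ifelse(flux_A / flux_B > 1, "up", "down")
    exp_dir <- model_dir
    if (n_mismatches > 0) {
      flip <- sample.int(n, n_mismatches)
      exp_dir[flip] <- ifelse(model_dir[flip] == "up", "down", "up")
    }
    out <- tibble::tibble(gene_id = gene_ids, flux_A = flux_A,
                          flux_B = flux_B, experimental_direction = exp_dir)
    attr(out, "n_injected_mismatches") <- as.integer(n_mismatches)
    out
  })
}
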