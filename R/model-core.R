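# The ME data model: metabolites, reactions, genes, enzymes, and the
# builders that bolt a growth-coupled expression layer onto a metabolic
# skeleton. One cytosolic compartment plus extracellular space; coupling
# terms are stored per-reaction as coefficient-per-mu maps and
# instantiated at solve time (usage = mu/kcat per unit flux).

METABOLITE_KINDS <- c("small-molecule", "mrna", "protein",
                      "enzyme-complex", "biomass-component")
REACTION_CLASSES <- c("metabolic", "transcription", "translation",
                      "exchange", "biomass-dilution", "demand",
                      "complex-formation")

#' Expression-machinery coupling parameters
#'
#' Bundles the machinery composition and rate constants behind the
#' mu/kcat coupling terms: ribosome composition (5S 120 nt, 23S 2900 nt
#' and 31 proteins in the large subunit; 16S 1542 nt and 21 proteins in
#' the small), RNA polymerase composition (two alpha, beta, beta-prime,
#' omega), the mean amino-acid mass, the rRNA fraction of total RNA, and
#' effective machine rates.
#'
#' @param m_aa mean amino-acid residue mass, kDa. The default 0.109 is
#'   consistent with a 31.09 kDa generic enzyme of 283 residues.
#' @param f_rRNA fraction of cellular RNA that is rRNA (0 < f < 1).
#' @param m_rr mass of rRNA per ribosome, kDa; by default computed from
#'   the stated rRNA lengths (120 + 2900 + 1542 nt) at the mean RNA
#'   residue mass.
#' @param k_ribosome_aa ribosome elongation capacity, amino acids per
#'   ribosome per day (default 12 aa/s).
#' @param k_rnap_nt RNA-polymerase elongation capacity, nucleotides per
#'   polymerase per day (default 55 nt/s).
#' @param k_mrna_translations translations supported per mRNA per day
#'   (effective mRNA turnover coupling).
#' @param atp_per_aa ATP equivalents hydrolysed per peptide bond.
#' @return object of class \code{coupling_params}.
#' @export
coupling_params <- function(m_aa = 0.109, f_rRNA = 0.86, m_rr = NULL,
                            k_ribosome_aa = 12 * 86400,
                            k_rnap_nt = 55 * 86400,
                            k_mrna_translations = 10000,
                            atp_per_aa = 4) {
  stopifnot(m_aa > 0, f_rRNA > 0, f_rRNA < 1,
            k_ribosome_aa > 0, k_rnap_nt > 0, k_mrna_translations > 0)
  rib <- list(rrna_5s_nt = 120L, rrna_23s_nt = 2900L, large_proteins = 31L,
              rrna_16s_nt = 1542L, small_proteins = 21L)
  if (is.null(m_rr)) {
    mean_nt <- mean(RNA_RESIDUE_MASS) / 1000
    m_rr <- (rib$rrna_5s_nt + rib$rrna_23s_nt + rib$rrna_16s_nt) * mean_nt
  }
  structure(list(
    m_aa = m_aa, f_rRNA = f_rRNA, m_rr = m_rr,
    ribosome_composition = rib,
    rnap_composition = c(alpha = 2L, beta = 1L, beta_prime = 1L, omega = 1L),
    k_ribosome_aa = k_ribosome_aa, k_rnap_nt = k_rnap_nt,
    k_mrna_translations = k_mrna_translations, atp_per_aa = atp_per_aa
  ), class = "coupling_params")
}

#' Create an empty ME model
#'
#' @param id model identifier.
#' @param coupling a [coupling_params()] object.
#' @return an object of class \code{me_model} with empty component tables.
#' @export
me_model <- function(id = "me_model", coupling = coupling_params()) {
  structure(list(
    id = id,
    metabolites = tibble::tibble(
      id = character(), name = character(), formula = character(),
      charge = integer(), compartment = character(), kind = character(),
      mw = numeric()),
    reactions = tibble::tibble(
      id = character(), name = character(), stoich = list(),
      mu_coupled = list(), lb = numeric(), ub = numeric(),
      rclass = character(), gpr = character(), enzyme = character()),
    genes = tibble::tibble(
      locus_tag = character(), sequence = character(), product = character()),
    enzymes = tibble::tibble(
      id = character(), subunits = list(), mw = numeric(), sasa = numeric(),
      kcat = numeric(), active_sites = integer()),
    coupling = coupling,
    biomass_dilution_id = NA_character_,
    constraints = list(),
    notes = list()
  ), class = "me_model")
}

#' @export
print.me_model <- function(x, ...) {
  cat("<me_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", nrow(x$genes),
      "  enzymes: ", nrow(x$enzymes), "\n",
      "  biomass dilution: ", x$biomass_dilution_id,
      "  extra constraints: ", length(x$constraints), "\n", sep = "")
  invisible(x)
}

#' Add a metabolite species
#'
#' @param model an \code{me_model}.
#' @param id unique species id (convention: \code{_c} cytosol, \code{_e}
#'   extracellular).
#' @param name human-readable name.
#' @param formula molecular formula string (may be \code{""} for massless
#'   pseudo-species such as photons and the proton-motive quantum).
#' @param charge formal charge.
#' @param compartment \code{"c"} or \code{"e"}.
#' @param kind one of small-molecule, mrna, protein, enzyme-complex,
#'   biomass-component.
#' @param mw molecular weight in kDa (macromolecules; \code{NA} otherwise).
#' @return the model with the species added.
#' @export
add_metabolite <- function(model, id, name = id, formula = "", charge = 0L,
                           compartment = "c", kind = "small-molecule",
                           mw = NA_real_) {
  stopifnot(inherits(model, "me_model"))
  if (id %in% model$metabolites$id) stop("duplicate metabolite id: ", id)
  if (!kind %in% METABOLITE_KINDS) stop("unknown metabolite kind: ", kind)
  if (!compartment %in% c("c", "e")) stop("compartment must be 'c' or 'e'")
  f <- parse_formula(formula)
  if (any(f < 0)) stop("formula counts must be >= 0 for ", id)
  model$metabolites <- tibble::add_row(
    model$metabolites, id = id, name = name,
    formula = if (is.character(formula)) formula else formula_string(f),
    charge = as.integer(charge), compartment = compartment, kind = kind,
    mw = mw)
  model
}

#' Add a reaction
#'
#' @param model an \code{me_model}.
#' @param id unique reaction id.
#' @param stoich named numeric vector, species id -> coefficient
#'   (negative = consumed).
#' @param lb,ub flux bounds, mmol/gDW/day.
#' @param rclass reaction class (see \code{REACTION_CLASSES}).
#' @param gpr gene-protein-reaction rule as a boolean string over locus
#'   tags, or \code{NA}.
#' @param enzyme id of the catalysing enzyme complex, or \code{NA}.
#' @param mu_coupled named numeric vector, species id -> coefficient per
#'   unit growth rate: at growth rate mu the reaction consumes
#'   \code{mu * coef} of the species per unit flux (the mu/kcat usage
#'   terms; store \code{1/kcat}).
#' @param name human-readable name.
#' @return the model with the reaction added.
#' @export
add_reaction <- function(model, id, stoich, lb = 0, ub = 1000,
                         rclass = "metabolic", gpr = NA_character_,
                         enzyme = NA_character_, mu_coupled = NULL,
                         name = id) {
  stopifnot(inherits(model, "me_model"))
  if (id %in% model$reactions$id) stop("duplicate reaction id: ", id)
  if (!rclass %in% REACTION_CLASSES) stop("unknown reaction class: ", rclass)
  if (lb > ub) stop("lower bound exceeds upper bound for ", id)
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) stop("empty stoichiometry for ", id)
  if (length(mu_coupled) && lb < 0) {
    stop("mu-coupled (catalysed) reactions must be irreversible: ", id)
  }
  model$reactions <- tibble::add_row(
    model$reactions, id = id, name = name, stoich = list(stoich),
    mu_coupled = list(mu_coupled %||% stats::setNames(numeric(0), character(0))),
    lb = lb, ub = ub, rclass = rclass, gpr = gpr, enzyme = enzyme)
  model
}

#' Add a gene
#'
#' @param model an \code{me_model}.
#' @param locus_tag unique gene id.
#' @param sequence coding nucleotide sequence over A/C/G/T.
#' @param product id of the protein (or structural RNA) species the gene
#'   encodes.
#' @return the model with the gene added.
#' @export
add_gene <- function(model, locus_tag, sequence, product = NA_character_) {
  stopifnot(inherits(model, "me_model"))
  if (locus_tag %in% model$genes$locus_tag) stop("duplicate gene: ", locus_tag)
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence)) {
    stop("gene sequence must be nonempty over A/C/G/T: ", locus_tag)
  }
  model$genes <- tibble::add_row(model$genes, locus_tag = locus_tag,
                                 sequence = sequence, product = product)
  model
}

#' Register an enzyme complex
#'
#' Molecular weight defaults to the sum of subunit protein masses times
#' copy numbers; SASA is always recomputed as mw^(3/4); kcat defaults to
#' the SASA-scaled mean via [assign_kcat()].
#'
#' @param model an \code{me_model} whose subunit protein species exist.
#' @param id enzyme id; a species of kind enzyme-complex is created.
#' @param subunits named numeric vector, protein species id -> copies.
#' @param kcat turnover, day^-1 (default SASA-scaled).
#' @param active_sites catalytic site count.
#' @param mw override for the complex mass in kDa.
#' @param defaults a [kcat_defaults()] object for the SASA scaling.
#' @return the model with the enzyme registered (no formation reaction yet;
#'   see [add_complex_formation()]).
#' @export
add_enzyme <- function(model, id, subunits, kcat = NULL, active_sites = 1L,
                       mw = NULL, defaults = kcat_defaults()) {
  stopifnot(inherits(model, "me_model"))
  if (id %in% model$enzymes$id) stop("duplicate enzyme id: ", id)
  missing_sub <- setdiff(names(subunits), model$metabolites$id)
  if (length(missing_sub)) {
    stop("unknown subunit species: ", paste(missing_sub, collapse = ", "))
  }
  if (is.null(mw)) {
    mwtab <- stats::setNames(model$metabolites$mw, model$metabolites$id)
    mw <- sum(mwtab[names(subunits)] * subunits)
    if (is.na(mw)) stop("subunit molecular weights unavailable for ", id)
  }
  if (is.null(kcat)) kcat <- assign_kcat(mw, defaults)
  if (kcat <= 0) stop("kcat must be positive for ", id)
  if (!id %in% model$metabolites$id) {
    model <- add_metabolite(model, id, name = paste0(id, " complex"),
                            formula = "", compartment = "c",
                            kind = "enzyme-complex", mw = mw)
  }
  model$enzymes <- tibble::add_row(
    model$enzymes, id = id, subunits = list(subunits), mw = mw,
    sasa = sasa(mw), kcat = kcat, active_sites = as.integer(active_sites))
  model
}

#' Add the stoichiometric assembly reaction of an enzyme complex
#'
#' Consumes the subunit proteins (and any extra structural components,
#' e.g. rRNAs for the ribosome) and produces one unit of the complex.
#'
#' @param model an \code{me_model}.
#' @param enzyme_id registered enzyme id.
#' @param extra named numeric vector of additional consumed species.
#' @return the model with a \code{FORM_<enzyme>} reaction.
#' @export
add_complex_formation <- function(model, enzyme_id, extra = NULL) {
  i <- match(enzyme_id, model$enzymes$id)
  if (is.na(i)) stop("unknown enzyme: ", enzyme_id)
  sub <- model$enzymes$subunits[[i]]
  stoich <- c(-sub, stats::setNames(1, enzyme_id))
  if (length(extra)) stoich <- c(-extra, stoich)
  add_reaction(model, paste0("FORM_", enzyme_id), stoich,
               rclass = "complex-formation",
               name = paste0(enzyme_id, " assembly"))
}

#' Translate a coding DNA sequence with the standard genetic code
#'
#' @param sequence nucleotide string, length divisible by 3, no internal
#'   stop codons.
#' @return one-letter amino-acid string.
#' @export
translate_dna <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0 || n %% 3 != 0) stop("sequence length must be a positive multiple of 3")
  codons <- substring(sequence, seq(1, n, 3), seq(3, n, 3))
  code <- Biostrings::GENETIC_CODE
  aa <- code[chartr("U", "T", codons)]
  if (anyNA(aa)) stop("unknown codon in sequence")
  if (any(aa == "*")) stop("internal stop codon in coding sequence")
  paste(aa, collapse = "")
}

#' Add a transcription reaction for a gene
#'
#' Consumes one NTP-equivalent species per template base, carries an RNA
#' polymerase usage term mu * L / k_rnap, and produces one unit of the
#' gene's mRNA species plus biomass mRNA with stoichiometric coefficient
#' equal to the transcript molecular weight in kDa.
#'
#' @param model an \code{me_model} containing the gene, the \code{rnap}
#'   enzyme, NTP species \code{ntp_a/c/g/u} and the \code{biomass_mrna}
#'   species.
#' @param locus_tag gene to transcribe.
#' @param rna_species optional id for the transcript species (default
#'   \code{mrna_<locus>}).
#' @param structural if \code{TRUE} the transcript is a structural RNA
#'   (e.g. rRNA): no translation will consume it, but it still counts
#'   toward biomass RNA.
#' @return the model with species \code{mrna_<locus>} (or
#'   \code{rna_species}) and reaction \code{TX_<locus>}.
#' @export
build_transcription_reaction <- function(model, locus_tag,
                                         rna_species = NULL,
                                         structural = FALSE) {
  gi <- match(locus_tag, model$genes$locus_tag)
  if (is.na(gi)) stop("unknown gene: ", locus_tag)
  if (!"rnap" %in% model$enzymes$id) stop("RNA polymerase enzyme 'rnap' missing")
  seq <- model$genes$sequence[gi]
  rna_seq <- chartr("T", "U", seq)
  mw <- molecular_weight(rna_seq, "rna")
  L <- nchar(seq)
  counts <- table(strsplit(tolower(chartr("T", "U", seq)), "")[[1]])
  ntp_ids <- paste0("ntp_", names(counts))
  missing_ntp <- setdiff(ntp_ids, model$metabolites$id)
  if (length(missing_ntp)) stop("missing NTP species: ",
                                paste(missing_ntp, collapse = ", "))
  sp <- rna_species %||% paste0("mrna_", locus_tag)
  model <- add_metabolite(model, sp, name = paste0(locus_tag, " transcript"),
                          kind = "mrna", mw = mw)
  stoich <- c(stats::setNames(-as.numeric(counts), ntp_ids),
              stats::setNames(c(1, mw), c(sp, "biomass_mrna")))
  add_reaction(model, paste0("TX_", locus_tag), stoich,
               rclass = "transcription", gpr = locus_tag,
               mu_coupled = c(rnap = L / model$coupling$k_rnap_nt),
               name = paste0("transcription of ", locus_tag))
}

#' Add a translation reaction for a gene
#'
#' Consumes one amino-acid pool unit per residue and ATP for peptide-bond
#' formation, carries ribosome usage mu * L_aa / k_ribosome and an mRNA
#' usage term mu / k_mrna (the transcript is diluted, not consumed
#' stoichiometrically), and produces one unit of the protein species plus
#' biomass protein with coefficient equal to the protein molecular weight
#' in kDa.
#'
#' @param model an \code{me_model} with the gene, its transcript, a
#'   \code{ribosome} enzyme, and species \code{aa_c}, \code{atp_c},
#'   \code{adp_c}, \code{pi_c}, \code{biomass_protein}.
#' @param locus_tag gene to translate.
#' @param protein_mw override for the protein mass in kDa (used for the
#'   generic enzyme whose mass is fixed by the literature value rather
#'   than its cosmetic sequence).
#' @return the model with species \code{P_<locus>} and reaction
#'   \code{TL_<locus>}.
#' @export
build_translation_reaction <- function(model, locus_tag, protein_mw = NULL) {
  gi <- match(locus_tag, model$genes$locus_tag)
  if (is.na(gi)) stop("unknown gene: ", locus_tag)
  if (!"ribosome" %in% model$enzymes$id) stop("'ribosome' enzyme missing")
  mrna_sp <- paste0("mrna_", locus_tag)
  if (!mrna_sp %in% model$metabolites$id) {
    stop("transcript ", mrna_sp, " missing; transcribe first")
  }
  seq <- model$genes$sequence[gi]
  prot <- translate_dna(seq)
  L_aa <- nchar(prot)
  psp <- paste0("P_", locus_tag)
  if (psp %in% model$metabolites$id) {
    mw <- protein_mw %||% model$metabolites$mw[match(psp, model$metabolites$id)]
  } else {
    mw <- protein_mw %||% molecular_weight(prot, "protein")
    model <- add_metabolite(model, psp, name = paste0(locus_tag, " protein"),
                            kind = "protein", mw = mw)
  }
  cp <- model$coupling
  stoich <- c(stats::setNames(-L_aa, "aa_c"),
              stats::setNames(-cp$atp_per_aa * L_aa, "atp_c"),
              stats::setNames(cp$atp_per_aa * L_aa, "adp_c"),
              stats::setNames(cp$atp_per_aa * L_aa, "pi_c"),
              stats::setNames(c(1, mw), c(psp, "biomass_protein")))
  mu_terms <- c(stats::setNames(L_aa / cp$k_ribosome_aa, "ribosome"),
                stats::setNames(1 / cp$k_mrna_translations, mrna_sp))
  add_reaction(model, paste0("TL_", locus_tag), stoich,
               rclass = "translation", gpr = locus_tag,
               mu_coupled = mu_terms,
               name = paste0("translation of ", locus_tag))
}

#' Couple a reaction's flux to the dilution of its catalysing enzyme
#'
#' At growth rate mu, a reaction with flux v consumes the enzyme complex
#' at rate (mu/kcat) * v: the enzyme made for catalysis is diluted by
#' growth. At mu = 0 the usage vanishes; at mu = kcat one enzyme unit is
#' consumed per flux unit; doubling kcat halves the usage.
#'
#' @param model an \code{me_model}.
#' @param reaction_id reaction to couple (must be irreversible).
#' @param enzyme_id registered enzyme with positive kcat.
#' @return the model with the usage term attached.
#' @export
attach_enzyme_usage <- function(model, reaction_id, enzyme_id) {
  ri <- match(reaction_id, model$reactions$id)
  if (is.na(ri)) stop("unknown reaction: ", reaction_id)
  ei <- match(enzyme_id, model$enzymes$id)
  if (is.na(ei)) stop("unknown enzyme: ", enzyme_id)
  kcat <- model$enzymes$kcat[ei]
  if (!is.finite(kcat) || kcat <= 0) stop("kcat must be positive")
  if (model$reactions$lb[ri] < 0) {
    stop("cannot couple a reversible reaction; split it first: ", reaction_id)
  }
  mc <- model$reactions$mu_coupled[[ri]]
  mc[enzyme_id] <- (if (enzyme_id %in% names(mc)) mc[[enzyme_id]] else 0) + 1 / kcat
  model$reactions$mu_coupled[[ri]] <- mc
  model$reactions$enzyme[ri] <- enzyme_id
  model
}

#' Add the biomass dilution reaction
#'
#' One reaction consumes the biomass components (including the
#' biomass-protein and biomass-mRNA bookkeeping species); its flux is
#' pinned to the growth rate mu by the solver, so total biomass component
#' production must equal biomass dilution at steady state.
#'
#' @param model an \code{me_model} without an existing dilution reaction.
#' @param composition named numeric vector of consumed amounts per unit
#'   growth (positive values; products may be included with negative
#'   values, e.g. ADP from growth-associated maintenance).
#' @return the model with reaction \code{BIOMASS_DILUTION}.
#' @export
add_biomass_dilution <- function(model, composition) {
  if (!is.na(model$biomass_dilution_id)) {
    stop("model already has a biomass dilution reaction")
  }
  stoich <- -composition
  model <- add_reaction(model, "BIOMASS_DILUTION", stoich,
                        rclass = "biomass-dilution",
                        name = "biomass dilution")
  model$biomass_dilution_id <- "BIOMASS_DILUTION"
  model
}

#' Knock out genes
#'
#' Bounds the translation reaction of each gene's product to zero, making
#' every complex containing that product unproducible. Structural-RNA
#' genes have their transcription bounded instead.
#'
#' @param model an \code{me_model}.
#' @param locus_tags character vector of genes to delete.
#' @return the knocked-out model.
#' @export
knockout <- function(model, locus_tags) {
  for (g in locus_tags) {
    if (!g %in% model$genes$locus_tag) stop("unknown gene: ", g)
    tl <- paste0("TL_", g)
    tx <- paste0("TX_", g)
    hit <- FALSE
    for (rid in c(tl)) {
      ri <- match(rid, model$reactions$id)
      if (!is.na(ri)) {
        model$reactions$lb[ri] <- 0; model$reactions$ub[ri] <- 0; hit <- TRUE
      }
    }
    if (!hit) {
      ri <- match(tx, model$reactions$id)
      if (!is.na(ri)) { model$reactions$lb[ri] <- 0; model$reactions$ub[ri] <- 0 }
    }
  }
  model
}

#' Validate an ME model
#'
#' Checks referential integrity (every reaction species exists, coupled
#' enzymes registered), uniqueness of ids, presence of exactly one
#' biomass-dilution reaction, bound sanity, and elemental balance of every
#' metabolic reaction whose participants all carry formulas (expression
#' and assembly reactions involve macromolecule pseudo-formulas and are
#' balanced by construction instead).
#'
#' @param model an \code{me_model}.
#' @param check_balance verify C/H/O/N/P/S conservation of metabolic
#'   reactions.
#' @return invisibly \code{TRUE}; stops with a message listing all
#'   problems otherwise.
#' @export
validate_me_model <- function(model, check_balance = TRUE) {
  errs <- character()
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids)) errs <- c(errs, "duplicate metabolite ids")
  if (anyDuplicated(model$reactions$id)) errs <- c(errs, "duplicate reaction ids")
  if (anyDuplicated(model$genes$locus_tag)) errs <- c(errs, "duplicate genes")
  formulas <- stats::setNames(lapply(model$metabolites$formula, parse_formula),
                              met_ids)
  kinds <- stats::setNames(model$metabolites$kind, met_ids)
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    sp <- names(rx$stoich[[1]])
    missing <- setdiff(sp, met_ids)
    if (length(missing)) {
      errs <- c(errs, paste0(rx$id, ": unknown species ",
                             paste(missing, collapse = ",")))
      next
    }
    mc <- rx$mu_coupled[[1]]
    if (length(mc)) {
      miss2 <- setdiff(names(mc), met_ids)
      if (length(miss2)) errs <- c(errs, paste0(rx$id, ": unknown coupled species"))
      if (rx$lb < 0) errs <- c(errs, paste0(rx$id, ": coupled but reversible"))
    }
    if (rx$lb > rx$ub) errs <- c(errs, paste0(rx$id, ": lb > ub"))
    if (check_balance && rx$rclass == "metabolic" &&
        all(kinds[sp] == "small-molecule")) {
      imb <- stoich_element_imbalance(rx$stoich[[1]], formulas)
      if (length(imb)) {
        errs <- c(errs, paste0(rx$id, ": element imbalance ",
                               paste(names(imb), round(unname(imb), 6),
                                     collapse = " ", sep = ":")))
      }
    }
  }
  ndil <- sum(model$reactions$rclass == "biomass-dilution")
  if (ndil != 1L) errs <- c(errs, paste0("expected exactly 1 biomass-dilution reaction, found ", ndil))
  if (ndil == 1L && (is.na(model$biomass_dilution_id) ||
      !model$biomass_dilution_id %in% model$reactions$id)) {
    errs <- c(errs, "biomass_dilution_id does not point at the dilution reaction")
  }
  enz_missing <- setdiff(stats::na.omit(model$reactions$enzyme), model$enzymes$id)
  if (length(enz_missing)) {
    errs <- c(errs, paste0("reactions reference unregistered enzymes: ",
                           paste(unique(enz_missing), collapse = ", ")))
  }
  if (length(errs)) {
    stop("invalid ME model:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  i
}

#' Set flux bounds of a reaction
#'
#' @param model an \code{me_model}.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be omitted).
#' @return the model with bounds updated.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- reaction_index(model, id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i]) {
    stop("lb > ub for ", id)
  }
  model
}
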