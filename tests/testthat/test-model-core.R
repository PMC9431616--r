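# Builders of the expression layer: transcription/translation reactions,
# coupling terms, biomass dilution, knockouts, validation.

test_that("transcription consumes NTPs per base and books biomass mRNA mass", {
  m <- toy_model()
  g <- "mdh"
  seqn <- m$genes$sequence[match(g, m$genes$locus_tag)]
  tx <- m$reactions$stoich[[match(paste0("TX_", g), m$reactions$id)]]
  counts <- table(strsplit(tolower(chartr("T", "U", seqn)), "")[[1]])
  for (base in names(counts)) {
    expect_equal(-tx[[paste0("ntp_", base)]], as.numeric(counts[[base]]),
                 label = paste("NTP", base))
  }
  # biomass mRNA coefficient equals the transcript molecular weight
  mw <- molecular_weight(chartr("T", "U", seqn), "rna")
  expect_equal(tx[["biomass_mrna"]], mw)
  expect_equal(tx[[paste0("mrna_", g)]], 1)
  # RNA polymerase usage is length / elongation capacity per unit mu
  mc <- m$reactions$mu_coupled[[match(paste0("TX_", g), m$reactions$id)]]
  expect_equal(mc[["rnap"]], nchar(seqn) / m$coupling$k_rnap_nt)
})

test_that("translation consumes one amino acid per residue with ribosome usage", {
  m <- toy_model()
  g <- "gpsA"
  seqn <- m$genes$sequence[match(g, m$genes$locus_tag)]
  prot <- translate_dna(seqn)
  tl <- m$reactions$stoich[[match(paste0("TL_", g), m$reactions$id)]]
  expect_equal(-tl[["aa_c"]], nchar(prot))
  expect_equal(tl[["biomass_protein"]], molecular_weight(prot, "protein"))
  expect_equal(tl[[paste0("P_", g)]], 1)
  mc <- m$reactions$mu_coupled[[match(paste0("TL_", g), m$reactions$id)]]
  expect_equal(mc[["ribosome"]], nchar(prot) / m$coupling$k_ribosome_aa)
  # mRNA is diluted through a usage term, not consumed stoichiometrically
  expect_false(paste0("mrna_", g) %in% names(tl))
  expect_true(paste0("mrna_", g) %in% names(mc))
})

test_that("translation requires an in-frame coding sequence", {
  expect_error(translate_dna("ATGA"), "multiple of 3")
  expect_error(translate_dna("ATGTAAGGG"), "stop codon")
  expect_equal(translate_dna("ATGGGC"), "MG")
})

test_that("enzyme usage follows mu/kcat algebra", {
  m <- me_model()
  m <- add_metabolite(m, "a_c", formula = "C")
  m <- add_metabolite(m, "b_c", formula = "C")
  m <- add_metabolite(m, "P_x", kind = "protein", mw = 10)
  m <- add_enzyme(m, "enz_x", c(P_x = 1), kcat = 4)
  m <- add_reaction(m, "CONV", c(a_c = -1, b_c = 1))
  m <- attach_enzyme_usage(m, "CONV", "enz_x")
  mc <- m$reactions$mu_coupled[[match("CONV", m$reactions$id)]]
  # at mu = kcat the usage coefficient is one enzyme per unit flux
  expect_equal(4 * mc[["enz_x"]], 1)
  # at mu = 0 the instantiated coefficient vanishes
  lp0 <- assemble_lp(m, 0)
  expect_equal(lp0$A["enz_x", "CONV"], 0)
  lp1 <- assemble_lp(m, 1)
  expect_equal(lp1$A["enz_x", "CONV"], -0.25)
  # doubling kcat halves the usage coefficient
  m2 <- set_enzyme_kcat(m, "enz_x", 8)
  mc2 <- m2$reactions$mu_coupled[[match("CONV", m2$reactions$id)]]
  expect_equal(mc2[["enz_x"]], mc[["enz_x"]] / 2)
  expect_error(add_enzyme(m, "enz_bad", c(P_x = 1), kcat = 0), "positive")
})

test_that("biomass dilution is unique and pinned to mu at solve time", {
  m <- toy_model()
  expect_error(add_biomass_dilution(m, c(aa_c = 1)), "already")
  lp <- assemble_lp(m, 0.2)
  j <- match("BIOMASS_DILUTION", lp$ids)
  expect_equal(lp$lb[j], 0.2)
  expect_equal(lp$ub[j], 0.2)
  # at a solved point the dilution flux equals mu and biomass protein is
  # balanced (production equals dilution draw)
  mc <- capped(m)
  sol <- pfba_fluxes(mc, 0.1, c(succinate = 3))
  expect_equal(unname(sol$fluxes["BIOMASS_DILUTION"]), 0.1, tolerance = 1e-8)
  lp2 <- assemble_lp(mc, 0.1, c(succinate = 3))
  bp <- as.vector(lp2$A["biomass_protein", , drop = FALSE] %*%
                    sol$fluxes[lp2$ids])
  expect_lt(abs(bp), 1e-6)
})

test_that("removing the dilution reaction is caught by validation", {
  m <- toy_model()
  broken <- m
  keep <- broken$reactions$id != "BIOMASS_DILUTION"
  broken$reactions <- broken$reactions[keep, ]
  expect_error(validate_me_model(broken), "biomass-dilution")
})

test_that("validation detects elemental imbalance", {
  m <- toy_model(expression_layer = FALSE)
  bad <- add_reaction(m, "BROKEN", c(co2_c = -1, cu_c = 2))
  expect_error(validate_me_model(bad), "imbalance")
})

test_that("knockouts silence translation and propagate to growth", {
  m <- toy_model()
  ko <- knockout(m, "nifH")
  i <- match("TL_nifH", ko$reactions$id)
  expect_equal(ko$reactions$ub[i], 0)
  expect_error(knockout(m, "not_a_gene"), "unknown gene")
  # filler isozyme redundancy: deleting one of the pair leaves growth alone
  mc <- capped(m)
  mu0 <- max_growth(mc, c(succinate = 3), tol = 1e-3, guard_scan = FALSE,
                    compute_fluxes = FALSE)$mu
  mu1 <- max_growth(capped(knockout(m, "fillerA_1")), c(succinate = 3),
                    tol = 1e-3, guard_scan = FALSE, compute_fluxes = FALSE)$mu
  expect_equal(mu1, mu0, tolerance = 2e-3)
})
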