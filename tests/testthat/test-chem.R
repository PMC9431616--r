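test_that("formula parsing handles counts, multi-letter elements and errors", {
  expect_equal(parse_formula("C4H6O4"), c(C = 4, H = 6, O = 4))
  expect_equal(parse_formula("HFe2S2"), c(Fe = 2, H = 1, S = 2))
  expect_equal(unname(parse_formula("CH2O")["C"]), 1)
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("C4h6"), "parse")
})

test_that("molecular weight sums residue masses plus one water", {
  # dipeptide checked against a hand-summed monomer table built from
  # atomic compositions (independent oracle)
  expected <- (residue_mass_oracle("A") + residue_mass_oracle("G") +
                 18.01528) / 1000
  expect_equal(molecular_weight("AG", "protein"), expected, tolerance = 1e-4)
  # single glycine: residue + water = free glycine (75.07 Da)
  expect_equal(molecular_weight("G", "protein") * 1000, 75.067,
               tolerance = 1e-2)
  # every residue mass agrees with the composition oracle
  for (aa in names(AA_RESIDUE_FORMULA)) {
    expect_equal(palme:::AA_RESIDUE_MASS[[aa]], residue_mass_oracle(aa),
                 tolerance = 2e-4, label = paste("residue", aa))
  }
  # rna alphabet, T read as U
  expect_equal(molecular_weight("AUG", "rna"), molecular_weight("ATG", "rna"))
  expect_error(molecular_weight("", "protein"), "nonempty")
  expect_error(molecular_weight("AXG", "protein"), "unknown")
})

test_that("generic enzyme constants anchor the expression layer", {
  # 283 residues at the mean residue mass give the 31.09 kDa generic enzyme
  m <- toy_model()
  i <- match("generic", m$enzymes$id)
  expect_equal(m$enzymes$mw[i], 31.09)
  gene <- m$genes$sequence[match("genP", m$genes$locus_tag)]
  expect_equal(nchar(gene) / 3, 283)
})

test_that("mean carbon oxidation state matches per-atom assignments", {
  # library of small molecules with structurally assigned oxidation states
  oracle <- list(
    list("CO2", 0, 4), list("CH4", 0, -4),
    list("CH2O2", 0, 2),              # formic acid
    list("CH4O", 0, -2),              # methanol
    list("C2H6O", 0, -2),             # ethanol: -3 (CH3) and -1 (CH2OH)
    list("C6H12O6", 0, 0),            # glucose
    list("C2H2O4", 0, 3),             # oxalic acid
    list("C2H5NO2", 0, 1),            # glycine: +3 (COOH), -1 (CH2)
    list("C3H8O3", 0, -2/3),          # glycerol: -1, 0, -1
    list("C3H6O", 0, -4/3)            # acetone: -3, +2, -3
  )
  for (case in oracle) {
    expect_equal(mean_carbon_oxidation_state(case[[1]], case[[2]]),
                 case[[3]], tolerance = 1e-12, label = case[[1]])
  }
  # charge is honoured: acetate anion CH3COO- has mean +0 on carbon?
  # (2*2 - 3 + (-1)) / 2 = 0: same as the neutral acid
  expect_equal(mean_carbon_oxidation_state("C2H3O2", charge = -1), 0)
  expect_error(mean_carbon_oxidation_state("H2O"), "carbon")
})
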