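# Elemental bookkeeping: formulas, monomer masses, oxidation states.

# IUPAC conventional atomic weights (Da).
ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, Fe = 55.845, Mo = 95.95, V = 50.942
)

# Average residue masses (monomer minus condensation water, Da).
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
RNA_RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
WATER_MASS <- 18.01528

#' Parse a molecular formula string
#'
#' Turns \code{"C4H6O4"} into a named count vector \code{c(C=4, H=6, O=4)}.
#' Element symbols are one capital letter optionally followed by a lower-case
#' letter; counts default to 1 and may be fractional (used for lumped
#' biomass pseudo-species).
#'
#' @param x formula string, or a named numeric vector (returned unchanged).
#' @return named numeric vector of element counts.
#' @examples
#' parse_formula("C9H8O3")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("numeric formula must be named by element")
    return(x)
  }
  if (is.na(x) || !nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula: ", x)
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' @keywords internal
formula_string <- function(f) {
  f <- f[f != 0]
  if (!length(f)) return("")
  ord <- c(intersect(c("C", "H"), names(f)), sort(setdiff(names(f), c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- f[[e]]
    paste0(e, if (n == 1) "" else format(n, scientific = FALSE))
  }, ""), collapse = "")
}

#' @keywords internal
formula_mass <- function(f) {
  f <- parse_formula(f)
  unknown <- setdiff(names(f), names(ATOMIC_MASS))
  if (length(unknown)) stop("no atomic mass for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(f * ATOMIC_MASS[names(f)])
}

#' Molecular weight of a biopolymer from its residue sequence
#'
#' Sums average monomer (residue) masses and adds one water for the free
#' termini, returning kilodaltons. Deterministic: the same sequence always
#' yields the same mass.
#'
#' @param sequence character string of one-letter residues (amino acids or
#'   RNA bases; for \code{alphabet = "rna"}, \code{T} is read as \code{U}).
#' @param alphabet \code{"protein"} or \code{"rna"}.
#' @return molecular weight in kDa.
#' @examples
#' molecular_weight("AG", "protein")
#' molecular_weight("AUGC", "rna")
#' @export
molecular_weight <- function(sequence, alphabet = c("protein", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a nonempty character scalar")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  tab <- if (alphabet == "protein") AA_RESIDUE_MASS else RNA_RESIDUE_MASS
  if (alphabet == "rna") chars[chars == "T"] <- "U"
  bad <- setdiff(unique(chars), names(tab))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  (sum(tab[chars]) + WATER_MASS) / 1000
}

#' Mean carbon oxidation state of a molecule
#'
#' Computes the average formal oxidation state of carbon with the usual
#' assignments H = +1, O = -2, N = -3, S = -2, honouring net molecular
#' charge. For a neutral CxHyOz molecule this reduces to \code{(2z - y)/x},
#' the quantity used to rank photoheterotrophic substrates by reducing
#' power (succinic acid +0.5, acetic acid 0, butyric acid -1, p-coumaric
#' acid -2/9).
#'
#' @param formula formula string or named element-count vector; must
#'   contain at least one carbon.
#' @param charge net molecular charge (default 0, i.e. the neutral acid).
#' @return mean carbon oxidation state (dimensionless).
#' @examples
#' mean_carbon_oxidation_state("C4H6O4")   # succinic acid: +0.5
#' mean_carbon_oxidation_state("C4H8O2")   # butyric acid:  -1
#' @export
mean_carbon_oxidation_state <- function(formula, charge = 0) {
  f <- parse_formula(formula)
  nC <- if ("C" %in% names(f)) f[["C"]] else 0
  if (nC < 1) stop("molecule has no carbon")
  get <- function(e) if (e %in% names(f)) f[[e]] else 0
  other <- setdiff(names(f), c("C", "H", "O", "N", "S"))
  if (length(other)) stop("unsupported element(s) for oxidation state: ",
                          paste(other, collapse = ", "))
  (charge - get("H") + 2 * get("O") + 3 * get("N") + 2 * get("S")) / nC
}

#' @keywords internal
stoich_element_imbalance <- function(stoich, formulas) {
  ## stoich: named numeric (species -> coefficient)
  ## formulas: named list of element-count vectors
  tot <- c()
  for (sp in names(stoich)) {
    f <- formulas[[sp]]
    if (is.null(f)) next
    for (e in names(f)) {
      tot[e] <- (if (e %in% names(tot)) tot[[e]] else 0) + stoich[[sp]] * f[[e]]
    }
  }
  if (is.null(tot)) tot <- numeric(0)
  tot[abs(tot) > 1e-9]
}
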