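# Analysis pipelines: growth profiling with region classification, the
# ferredoxin electron-distribution sweep, nitrogenase temperature scans,
# and expression fold-change validation.

#' Growth profile over a substrate uptake grid
#'
#' For each uptake value, finds the maximal feasible growth rate (uptake
#' as an upper bound) and then computes parsimonious fluxes with the
#' uptake pinned to the grid value, so that surplus substrate must be
#' accommodated. Where forced consumption of the full supply is
#' infeasible (beyond the network's disposal capacity) the fluxes of the
#' bounded solve are reported and flagged.
#'
#' @param model an \code{me_model} (un-capped; the substrate ATP cap is
#'   applied internally unless \code{apply_cap = FALSE}).
#' @param substrate substrate name.
#' @param uptake_grid ascending uptake values, mmol/gDW/day.
#' @param tol bisection tolerance for the growth solve.
#' @param apply_cap apply the photosynthetic ATP cap for this substrate.
#' @param guard_scan passed to [max_growth()].
#' @param alpha,beta region-classification thresholds (see
#'   [classify_regions()]).
#' @return tibble of class \code{growth_profile} with columns
#'   \code{uptake}, \code{mu}, \code{v_nfix}, \code{v_cfix}, \code{v_mdh},
#'   \code{v_g3pdh}, \code{pinned} (whether the full supply was
#'   consumable) and \code{region}.
#' @export
growth_profile <- function(model, substrate, uptake_grid, tol = 1e-4,
                           apply_cap = TRUE, guard_scan = TRUE,
                           alpha = 0.9, beta = 0.05) {
  if (is.unsorted(uptake_grid, strictly = TRUE)) {
    stop("uptake_grid must be strictly ascending")
  }
  m <- if (apply_cap) apply_atp_cap(model, substrate) else model
  nfix_ids <- intersect(c("NFIX_Mo", "NFIX_V", "NFIX_Fe"), m$reactions$id)
  cfix_ids <- intersect(c("RBC_I", "RBC_II"), m$reactions$id)
  rows <- purrr::map(uptake_grid, function(u) {
    ub <- stats::setNames(u, substrate)
    sol <- max_growth(m, ub, tol = tol, guard_scan = guard_scan,
                      compute_fluxes = FALSE)
    pinned <- TRUE
    pf <- tryCatch(pfba_fluxes(m, sol$mu, ub, pin_uptake = TRUE),
                   error = function(e) NULL)
    if (is.null(pf)) {
      pinned <- FALSE
      pf <- pfba_fluxes(m, sol$mu, ub)
    }
    fx <- pf$fluxes
    tibble::tibble(
      uptake = u, mu = sol$mu,
      v_nfix = sum(fx[nfix_ids]), v_cfix = sum(fx[cfix_ids]),
      v_mdh = if ("MDH" %in% names(fx)) fx[["MDH"]] else NA_real_,
      v_g3pdh = if ("G3PDH" %in% names(fx)) fx[["G3PDH"]] else NA_real_,
      pinned = pinned)
  })
  out <- dplyr::bind_rows(rows)
  out$region <- classify_regions(out$uptake, out$mu, alpha = alpha,
                                 beta = beta, tol = tol)
  attr(out, "substrate") <- substrate
  class(out) <- c("growth_profile", class(out))
  out
}

#' Classify growth regions from the shape of the growth curve
#'
#' Labels each grid point strictly nutrient-limited (SNL), Janusian
#' (transition) or strictly proteome-limited (SPL) from central-difference
#' slopes: SNL where the slope is at least \code{alpha} of the maximal
#' slope, SPL where it is at most \code{beta} of it, Janusian in
#' between. Labels are made contiguous (SNL prefix, SPL suffix) and are
#' invariant to uniform rescaling of the uptake grid.
#'
#' @param uptake,mu numeric vectors (>= 4 points), mu non-decreasing.
#' @param alpha,beta slope thresholds relative to the maximal slope.
#' @param tol tolerance for the monotonicity check of mu.
#' @return character vector of labels \code{"SNL"}, \code{"Janusian"},
#'   \code{"SPL"}.
#' @export
classify_regions <- function(uptake, mu, alpha = 0.9, beta = 0.05,
                             tol = 1e-4) {
  n <- length(mu)
  if (n < 4) stop("need at least 4 grid points")
  if (any(diff(mu) < -10 * tol)) {
    stop("mu must be non-decreasing along the uptake grid")
  }
  s <- numeric(n)
  s[1] <- (mu[2] - mu[1]) / (uptake[2] - uptake[1])
  s[n] <- (mu[n] - mu[n - 1]) / (uptake[n] - uptake[n - 1])
  for (i in 2:(n - 1)) {
    s[i] <- (mu[i + 1] - mu[i - 1]) / (uptake[i + 1] - uptake[i - 1])
  }
  smax <- max(s)
  if (smax <= 0) return(rep("SPL", n))
  snl_raw <- s >= alpha * smax
  spl_raw <- s <= beta * smax
  ## contiguity: maximal SNL prefix, maximal SPL suffix
  snl_end <- if (snl_raw[1]) max(which(cumprod(snl_raw) == 1)) else 0L
  spl_start <- if (spl_raw[n]) min(which(rev(cumprod(rev(spl_raw)) == 1))) else n + 1L
  labs <- rep("Janusian", n)
  if (snl_end >= 1) labs[1:snl_end] <- "SNL"
  if (spl_start <= n) labs[spl_start:n] <- "SPL"
  labs
}

#' Electron-distribution sweep through ferredoxin (ETFD)
#'
#' Reproduces the electron-partitioning experiment: growth rate and
#' substrate uptake are held constant, the flux through the
#' ferredoxin-reduction step (ETFD) is pinned at its parsimonious value
#' and at elevated multiples of it, and the carbon-fixation flux is
#' pinned across a grid while the nitrogen-fixation flux is recorded.
#' At the parsimonious ETFD level the nitrogenase flux is invariant to
#' the carbon-fixation pin; at elevated levels carbon and nitrogen
#' fixation compete for ferredoxin electrons and correlate negatively.
#' Infeasible (ETFD, cfix) combinations are recorded as missing.
#'
#' @param model an \code{me_model}.
#' @param substrate substrate name.
#' @param uptake pinned substrate uptake, mmol/gDW/day.
#' @param mu_pin pinned growth rate; default \code{mu_frac} of the
#'   maximal growth at this uptake.
#' @param mu_frac fraction of the maximal growth rate used when
#'   \code{mu_pin} is NULL (default 0.5, leaving the network slack to
#'   redistribute electrons).
#' @param etfd_multipliers multiples of the parsimonious ETFD flux to
#'   pin (1 = the ME solution level).
#' @param cfix_fracs carbon-fixation pins as fractions of the
#'   parsimonious carbon-fixation flux at the operating point.
#' @param apply_cap apply the substrate ATP cap.
#' @param tol growth-solve tolerance.
#' @return tibble of class \code{etfd_sweep} with columns
#'   \code{etfd_multiplier}, \code{etfd_level}, \code{cfix}, \code{v_nfix}
#'   and \code{feasible}.
#' @export
etfd_sweep <- function(model, substrate, uptake, mu_pin = NULL,
                       mu_frac = 0.5, etfd_multipliers = c(1, 2, 3),
                       cfix_fracs = seq(0.25, 1.5, by = 0.25),
                       apply_cap = TRUE, tol = 1e-4) {
  m <- if (apply_cap) apply_atp_cap(model, substrate) else model
  ub <- stats::setNames(uptake, substrate)
  if (is.null(mu_pin)) {
    sol <- max_growth(m, ub, tol = tol, guard_scan = FALSE,
                      compute_fluxes = FALSE)
    mu_pin <- mu_frac * sol$mu
  }
  base <- pfba_fluxes(m, mu_pin, ub, pin_uptake = TRUE)
  etfd0 <- unname(base$fluxes["ETFD"])
  cfix0 <- unname(sum(base$fluxes[intersect(c("RBC_I", "RBC_II"),
                                            names(base$fluxes))]))
  nfix_ids <- intersect(c("NFIX_Mo", "NFIX_V", "NFIX_Fe"), m$reactions$id)
  grid <- tidyr::expand_grid(etfd_multiplier = etfd_multipliers,
                             cfix_frac = cfix_fracs)
  rows <- purrr::pmap(grid, function(etfd_multiplier, cfix_frac) {
    cf <- cfix0 * cfix_frac
    r <- tryCatch(
      pfba_fluxes(m, mu_pin, ub, pin_uptake = TRUE,
                  pins = c(ETFD = etfd0 * etfd_multiplier),
                  extra_rows = list(list(
                    coeffs = c(RBC_I = 1, RBC_II = 1), op = "=", rhs = cf))),
      error = function(e) NULL)
    tibble::tibble(etfd_multiplier = etfd_multiplier,
                   etfd_level = etfd0 * etfd_multiplier,
                   cfix = cf,
                   v_nfix = if (is.null(r)) NA_real_ else sum(r$fluxes[nfix_ids]),
                   feasible = !is.null(r))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "substrate") <- substrate
  attr(out, "mu_pin") <- mu_pin
  attr(out, "uptake") <- uptake
  attr(out, "etfd_base") <- etfd0
  attr(out, "cfix_base") <- cfix0
  class(out) <- c("etfd_sweep", class(out))
  out
}

#' Validate predicted expression fold-change directions
#'
#' Computes per-gene fold changes \code{flux_A / flux_B} (condition B is
#' the baseline), calls each gene up- or downregulated (fold change
#' greater resp. smaller than one), compares with the experimental
#' directions, and reports the accuracy as a percentage rounded to the
#' nearest integer. Genes whose baseline flux is below \code{epsilon}
#' use a pseudo-flux (epsilon added to both conditions) and are flagged;
#' exact ties (fold change 1) are classified "unchanged" and excluded
#' from the accuracy denominator.
#'
#' @param flux_A,flux_B named per-gene fluxes (names are gene ids), or a
#'   fixture tibble from [make_expression_fixture()] as \code{flux_A}
#'   with \code{flux_B} missing.
#' @param experimental_directions named character vector ("up"/"down").
#' @param epsilon pseudo-flux floor.
#' @return object of class \code{validation_result}: list with the
#'   per-gene \code{table} (tibble) and summary fields \code{n_compared},
#'   \code{n_correct}, \code{accuracy_percent}, \code{n_ties},
#'   \code{n_pseudo}.
#' @export
fold_change_validation <- function(flux_A, flux_B = NULL,
                                   experimental_directions = NULL,
                                   epsilon = 1e-9) {
  if (is.data.frame(flux_A)) {
    fx <- flux_A
    stopifnot(all(c("gene_id", "flux_A", "flux_B",
                    "experimental_direction") %in% names(fx)))
    flux_B <- stats::setNames(fx$flux_B, fx$gene_id)
    experimental_directions <- stats::setNames(fx$experimental_direction,
                                               fx$gene_id)
    flux_A <- stats::setNames(fx$flux_A, fx$gene_id)
  }
  genes <- intersect(intersect(names(flux_A), names(flux_B)),
                     names(experimental_directions))
  if (!length(genes)) stop("no overlapping gene ids between inputs")
  a <- flux_A[genes]; b <- flux_B[genes]
  pseudo <- b < epsilon | a < epsilon
  fc <- (a + ifelse(pseudo, epsilon, 0)) / (b + ifelse(pseudo, epsilon, 0))
  dir <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "unchanged"))
  exp_dir <- experimental_directions[genes]
  tab <- tibble::tibble(gene_id = genes, flux_A = unname(a),
                        flux_B = unname(b), fold_change = unname(fc),
                        predicted = unname(dir),
                        experimental = unname(exp_dir),
                        pseudo_flux = unname(pseudo),
                        correct = unname(dir == exp_dir & dir != "unchanged"))
  compared <- dir != "unchanged"
  n_compared <- sum(compared)
  n_correct <- sum(tab$correct)
  acc <- if (n_compared > 0) round(100 * n_correct / n_compared) else NA_real_
  structure(list(table = tab, n_compared = n_compared, n_correct = n_correct,
                 accuracy_percent = acc, n_ties = sum(!compared),
                 n_pseudo = sum(pseudo)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result> ", x$n_correct, "/", x$n_compared,
      " directions correct (", x$accuracy_percent, "%)",
      if (x$n_ties) paste0("; ", x$n_ties, " tie(s) excluded"), "\n", sep = "")
  invisible(x)
}

#' Nitrogenase temperature scan via turnover-number multipliers
#'
#' Temperature mainly enters the model through the Arrhenius dependence
#' of kcat, so cooling is emulated by scaling the Mo-nitrogenase
#' turnover number down. For each multiplier the maximal growth rate of
#' the wild type and of the Mo-only, V-only and Fe-only mutants
#' (single-isozyme knockout strains) is computed; the crossover
#' multiplier at which the V-only strain first outgrows the Mo-only
#' strain is reported.
#'
#' @param model an \code{me_model} with the expression layer (knockouts
#'   act on translation).
#' @param kcat_multipliers multipliers applied to the Mo-nitrogenase
#'   kcat (1 = reference temperature); scanned in the given order.
#' @param substrate,uptake growth condition.
#' @param strains subset of \code{c("WT","Mo","V","Fe")}.
#' @param apply_cap apply the substrate ATP cap.
#' @param tol growth-solve tolerance.
#' @return tibble of class \code{nase_scan} with columns
#'   \code{multiplier}, \code{strain}, \code{mu_max}; attribute
#'   \code{crossover} holds the largest multiplier at which
#'   mu(V-only) > mu(Mo-only), or NA.
#' @export
nitrogenase_temperature_scan <- function(model, kcat_multipliers,
                                         substrate = "succinate", uptake = 5,
                                         strains = c("WT", "Mo", "V", "Fe"),
                                         apply_cap = TRUE, tol = 1e-3) {
  m0 <- if (apply_cap) apply_atp_cap(model, substrate) else model
  ub <- stats::setNames(uptake, substrate)
  kcat0 <- m0$enzymes$kcat[match("nase_mo", m0$enzymes$id)]
  if (is.na(kcat0)) stop("model has no Mo-nitrogenase enzyme (nase_mo)")
  rows <- list()
  for (mult in kcat_multipliers) {
    mm <- set_enzyme_kcat(m0, "nase_mo", kcat0 * mult)
    for (strain in strains) {
      ms <- nitrogenase_mutant(mm, strain)
      mu <- tryCatch(
        max_growth(ms, ub, tol = tol, guard_scan = FALSE,
                   compute_fluxes = FALSE)$mu,
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        multiplier = mult, strain = strain, mu_max = mu)
    }
  }
  out <- dplyr::bind_rows(rows)
  cross <- NA_real_
  if (all(c("Mo", "V") %in% strains)) {
    wide <- tidyr::pivot_wider(out, names_from = "strain",
                               values_from = "mu_max")
    flip <- wide$multiplier[!is.na(wide$V) & !is.na(wide$Mo) &
                              wide$V > wide$Mo + tol]
    if (length(flip)) cross <- max(flip)
  }
  attr(out, "crossover") <- cross
  attr(out, "substrate") <- substrate
  class(out) <- c("nase_scan", class(out))
  out
}

#' Single-nitrogenase mutant strains
#'
#' Returns the model with the gene sets of the other two nitrogenase
#' isozymes knocked out ("Mo" keeps Mo-nitrogenase only, etc.); "WT"
#' returns the model unchanged.
#'
#' @param model an \code{me_model} with nitrogenase genes
#'   (nifH/nifD, vnfH/vnfD, anfH/anfD).
#' @param keep \code{"WT"}, \code{"Mo"}, \code{"V"} or \code{"Fe"}.
#' @return the mutant model.
#' @export
nitrogenase_mutant <- function(model, keep = c("WT", "Mo", "V", "Fe")) {
  keep <- match.arg(keep)
  sets <- list(Mo = c("nifH", "nifD"), V = c("vnfH", "vnfD"),
               Fe = c("anfH", "anfD"))
  if (keep == "WT") return(model)
  ko <- unlist(sets[setdiff(names(sets), keep)], use.names = FALSE)
  knockout(model, ko)
}

#' Reference growth rates for nitrogen-fixing photoheterotrophic growth
#'
#' Experimentally observed growth rates (day^-1) of the wild type on
#' each substrate under anaerobic nitrogen-fixing conditions, and the
#' rates predicted by the genome-scale ME reconstruction of the same
#' organism. Used to recompute the predicted-over-experimental growth
#' excess; no experimental value is available for p-coumarate.
#'
#' @name reference_growth_rates
#' @export
EXPERIMENTAL_GROWTH_RATES <- c(succinate = 0.70, acetate = 0.74,
                               butyrate = 0.82)

#' @rdname reference_growth_rates
#' @export
ME_PREDICTED_GROWTH_RATES <- c(succinate = 0.74, acetate = 0.77,
                               butyrate = 0.86, `p-coumarate` = 1.21)

#' Predicted-over-experimental growth excess, in percent
#'
#' \code{round(100 * (predicted - experimental)/experimental)} per
#' substrate (nearest-integer percent).
#'
#' @param predicted,experimental named growth-rate vectors; names are
#'   matched.
#' @return named numeric vector of rounded percentages.
#' @export
growth_excess_percent <- function(predicted = ME_PREDICTED_GROWTH_RATES,
                                  experimental = EXPERIMENTAL_GROWTH_RATES) {
  common <- intersect(names(predicted), names(experimental))
  round(100 * (predicted[common] - experimental[common]) /
          experimental[common])
}
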