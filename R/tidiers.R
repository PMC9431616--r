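# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth solution into a reaction/flux tibble
#'
#' @param x a \code{growth_solution}.
#' @param ... unused.
#' @return tibble with columns \code{reaction}, \code{flux}.
#' @export
tidy.growth_solution <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(reaction = character(), flux = numeric()))
  }
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a growth solution
#'
#' @param x a \code{growth_solution}.
#' @param ... unused.
#' @return tibble with \code{mu}, \code{status}, \code{total_flux},
#'   \code{residual}.
#' @export
glance.growth_solution <- function(x, ...) {
  tibble::tibble(mu = x$mu, status = x$status,
                 total_flux = x$total_flux, residual = x$residual)
}

#' Per-gene table of a fold-change validation
#'
#' @param x a \code{validation_result}.
#' @param ... unused.
#' @return the per-gene tibble.
#' @export
tidy.validation_result <- function(x, ...) x$table

#' One-row summary of a fold-change validation
#'
#' @param x a \code{validation_result}.
#' @param ... unused.
#' @return tibble with \code{n_compared}, \code{n_correct},
#'   \code{accuracy_percent}, \code{n_ties}, \code{n_pseudo}.
#' @export
glance.validation_result <- function(x, ...) {
  tibble::tibble(n_compared = x$n_compared, n_correct = x$n_correct,
                 accuracy_percent = x$accuracy_percent,
                 n_ties = x$n_ties, n_pseudo = x$n_pseudo)
}

#' One-row summary of an ME model
#'
#' @param x an \code{me_model}.
#' @param ... unused.
#' @return tibble of component counts.
#' @export
glance.me_model <- function(x, ...) {
  tibble::tibble(id = x$id,
                 n_metabolites = nrow(x$metabolites),
                 n_reactions = nrow(x$reactions),
                 n_genes = nrow(x$genes),
                 n_enzymes = nrow(x$enzymes),
                 n_constraints = length(x$constraints))
}

#' Plot a growth profile
#'
#' Growth rate and the key fluxes (nitrogen fixation, carbon fixation,
#' malate dehydrogenase, glycerol-3-phosphate dehydrogenase) against
#' substrate uptake, with growth regions shaded.
#'
#' @param object a \code{growth_profile}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.growth_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("uptake", "mu", "v_nfix", "v_cfix",
                                "v_mdh", "v_g3pdh")],
    -"uptake", names_to = "quantity", values_to = "value")
  regions <- tibble::as_tibble(object)[c("uptake", "region")]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$uptake, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$uptake, xmax = dplyr::lead(.data$uptake,
                     default = max(regions$uptake)),
                   fill = .data$region),
      ymin = -Inf, ymax = Inf, alpha = 0.08, inherit.aes = FALSE) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "substrate uptake (mmol/gDW/day)", y = NULL,
                  title = paste0("Growth profile: ",
                                 attr(object, "substrate") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot an ETFD electron-distribution sweep
#'
#' Nitrogen-fixation flux against the pinned carbon-fixation flux, one
#' line per pinned ETFD level.
#'
#' @param object an \code{etfd_sweep}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.etfd_sweep <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$feasible)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cfix, y = .data$v_nfix,
                                   colour = factor(.data$etfd_multiplier))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "carbon fixation flux (mmol/gDW/day)",
                  y = "nitrogen fixation flux (mmol/gDW/day)",
                  colour = "ETFD multiple",
                  title = paste0("Electron distribution: ",
                                 attr(object, "substrate") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a nitrogenase temperature scan
#'
#' Maximal growth per strain against the Mo-nitrogenase kcat multiplier
#' (log scale); the crossover where the V-only strain overtakes the
#' Mo-only strain is marked.
#'
#' @param object a \code{nase_scan}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nase_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$multiplier,
                                        y = .data$mu_max,
                                        colour = .data$strain)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mo-nitrogenase kcat multiplier (temperature proxy)",
                  y = "maximal growth rate (1/day)") +
    ggplot2::theme_minimal()
  cross <- attr(object, "crossover")
  if (!is.null(cross) && is.finite(cross)) {
    p <- p + ggplot2::geom_vline(xintercept = cross, linetype = "dashed")
  }
  p
}
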