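# Canonical JSON model dialect: a COBRA-style document extended with the
# expression layer (genes with sequences, enzymes with subunit maps,
# mu-coupled usage terms, coupling parameters). Reading a written file
# reproduces the model exactly; writing again is byte-identical.

FORMAT_VERSION <- "1.0"

#' Serialize an ME model to its canonical JSON text
#'
#' @param model an \code{me_model}.
#' @return a JSON string (UTF-8, pretty-printed, canonical field order).
#' @export
serialize_me_model <- function(model) {
  stopifnot(inherits(model, "me_model"))
  named_list <- function(x) {
    if (is.null(x) || !length(x)) return(stats::setNames(list(), character(0)))
    as.list(x)
  }
  doc <- list(
    format_version = FORMAT_VERSION,
    id = model$id,
    coupling = unclass(model$coupling),
    metabolites = purrr::pmap(model$metabolites, function(...) list(...)),
    reactions = purrr::pmap(model$reactions, function(id, name, stoich,
                                                      mu_coupled, lb, ub,
                                                      rclass, gpr, enzyme) {
      list(id = id, name = name, stoich = named_list(stoich),
           mu_coupled = named_list(mu_coupled), lb = lb, ub = ub,
           rclass = rclass, gpr = gpr, enzyme = enzyme)
    }),
    genes = purrr::pmap(model$genes, function(...) list(...)),
    enzymes = purrr::pmap(model$enzymes, function(id, subunits, mw, sasa,
                                                  kcat, active_sites) {
      list(id = id, subunits = named_list(subunits), mw = mw, sasa = sasa,
           kcat = kcat, active_sites = active_sites)
    }),
    biomass_dilution_id = model$biomass_dilution_id,
    constraints = model$constraints,
    notes = model$notes
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null", pretty = TRUE))
}

#' Write an ME model to a JSON file
#'
#' @param model an \code{me_model}.
#' @param path output path.
#' @return invisibly the path.
#' @export
write_me_model <- function(model, path) {
  writeLines(serialize_me_model(model), path, useBytes = TRUE)
  invisible(path)
}

#' Read an ME model from its JSON dialect
#'
#' Strict: unknown format versions, duplicate ids, dangling species
#' references and a missing biomass-dilution reaction are rejected.
#'
#' @param path JSON file written by [write_me_model()].
#' @return a validated \code{me_model}.
#' @export
read_me_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) || doc$format_version != FORMAT_VERSION) {
    stop("unsupported model document version: ",
         doc$format_version %||% "<missing>")
  }
  cp <- doc$coupling
  cp$rnap_composition <- unlist(cp$rnap_composition)
  coupling <- structure(cp, class = "coupling_params")
  m <- me_model(id = doc$id, coupling = coupling)

  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  num_vec <- function(x) {
    if (is.null(x) || !length(x)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(vapply(x, as.numeric, 0), names(x))
  }
  for (sp in doc$metabolites) {
    m <- add_metabolite(m, sp$id, name = chr1(sp$name),
                        formula = chr1(sp$formula) %|NA|% "",
                        charge = sp$charge %||% 0L,
                        compartment = sp$compartment, kind = sp$kind,
                        mw = if (is.null(sp$mw)) NA_real_ else as.numeric(sp$mw))
  }
  for (g in doc$genes) {
    m <- add_gene(m, g$locus_tag, g$sequence, product = chr1(g$product))
  }
  for (e in doc$enzymes) {
    m <- add_enzyme(m, e$id, num_vec(e$subunits), kcat = e$kcat,
                    active_sites = e$active_sites, mw = e$mw)
    ## add_enzyme recreated the complex species; drop the duplicate row it
    ## would clash with on the metabolite read above
  }
  for (rx in doc$reactions) {
    m <- add_reaction(m, rx$id, num_vec(rx$stoich), lb = rx$lb, ub = rx$ub,
                      rclass = rx$rclass, gpr = chr1(rx$gpr),
                      enzyme = chr1(rx$enzyme),
                      mu_coupled = num_vec(rx$mu_coupled),
                      name = chr1(rx$name) %|NA|% rx$id)
  }
  m$biomass_dilution_id <- chr1(doc$biomass_dilution_id)
  m$constraints <- lapply(doc$constraints, function(cr) {
    cr$coeffs <- num_vec(cr$coeffs)
    cr
  })
  m$notes <- doc$notes %||% list()
  validate_me_model(m)
  m
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

#' Write a tab-separated table without locale surprises
#'
#' Full-precision numeric formatting, no quoting, no row names.
#' @param x data frame.
#' @param path output path.
#' @return invisibly the path.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression fixture table
#'
#' Columns \code{gene_id}, \code{flux_A}, \code{flux_B},
#' \code{experimental_direction}.
#' @param fixture tibble from [make_expression_fixture()].
#' @param path output path.
#' @return invisibly the path.
#' @export
write_expression_fixture <- function(fixture, path) {
  write_tsv_plain(fixture[, c("gene_id", "flux_A", "flux_B",
                              "experimental_direction")], path)
}

#' Read an expression fixture table
#' @param path TSV written by [write_expression_fixture()].
#' @return tibble.
#' @export
read_expression_fixture <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "flux_A", "flux_B", "experimental_direction")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("fixture lacks column(s): ",
                            paste(missing, collapse = ", "))
  tibble::as_tibble(x)
}
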