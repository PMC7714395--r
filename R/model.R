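#' Construct a stoichiometric metabolic model
#'
#' A `metabolic_model` is the substrate of flux balance analysis: a set of
#' metabolites, a set of reactions (each a sparse signed stoichiometry over
#' metabolite ids, with flux bounds in mmol/gDW/h), and a biomass objective
#' reaction. Consumption is negative, production positive. Exchange reactions
#' connect the network to the environment and touch exactly one metabolite;
#' by the dominant community convention, uptake is a *negative* flux through
#' an `EX_*` reaction.
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`.
#' @param reactions data frame with columns `id`, `stoichiometry` (a list
#'   column of named numeric vectors, metabolite id -> signed coefficient),
#'   `lower_bound`, `upper_bound`, `is_exchange`.
#' @param objective id of the biomass reaction to maximize.
#'
#' @return A validated object of class `metabolic_model`.
#' @seealso [read_model()], [fba()], [make_toy_model()]
#' @export
metabolic_model <- function(metabolites, reactions, objective) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         objective = objective),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model's invariants
#'
#' Checks id uniqueness, bound ordering, non-empty stoichiometries, that every
#' referenced metabolite exists, that exchange reactions touch exactly one
#' metabolite, and that the objective reaction exists.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly usable; errors describe the offending element.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites
  rxn <- model$reactions
  req_met <- c("id", "name", "compartment")
  req_rxn <- c("id", "stoichiometry", "lower_bound", "upper_bound", "is_exchange")
  if (!all(req_met %in% names(met))) {
    stop("metabolite table must have columns: ", paste(req_met, collapse = ", "))
  }
  if (!all(req_rxn %in% names(rxn))) {
    stop("reaction table must have columns: ", paste(req_rxn, collapse = ", "))
  }
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id: ", met$id[duplicated(met$id)][1])
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id: ", rxn$id[duplicated(rxn$id)][1])
  }
  if (any(!nzchar(met$id))) stop("empty metabolite id")
  if (any(!nzchar(rxn$id))) stop("empty reaction id")
  bad <- which(rxn$lower_bound > rxn$upper_bound)
  if (length(bad)) {
    stop("reaction '", rxn$id[bad[1]], "': lower_bound > upper_bound")
  }
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    if (length(s) == 0) stop("reaction '", rxn$id[i], "': empty stoichiometry")
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      stop("reaction '", rxn$id[i], "': unnamed stoichiometry entries")
    }
    missing <- setdiff(names(s), met$id)
    if (length(missing)) {
      stop("reaction '", rxn$id[i], "' references unknown metabolite '",
           missing[1], "'")
    }
    if (isTRUE(rxn$is_exchange[i]) && length(s) != 1L) {
      stop("exchange reaction '", rxn$id[i],
           "' must touch exactly one metabolite")
    }
  }
  if (!model$objective %in% rxn$id) {
    stop("objective reaction '", model$objective, "' not in model")
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return Dense numeric matrix S (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    s <- model$reactions$stoichiometry[[j]]
    S[names(s), j] <- s
  }
  S
}

# default bounds when a document omits them: reversible (-1000, 1000),
# irreversible (0, 1000)
.default_bounds <- function(reversible) {
  if (isTRUE(reversible)) c(-1000, 1000) else c(0, 1000)
}

#' Read a metabolic model from JSON or an SBML subset
#'
#' The JSON dialect is the canonical on-disk format (see [write_model()]).
#' The SBML reader imports species, reactions, stoichiometry and fbc/flux
#' bounds from Level 3 core documents and ignores annotations: the pipeline
#' needs stoichiometry, not curation metadata.
#'
#' @param source a file path, or the document text itself.
#' @param format `"json"` or `"sbml"`.
#' @return A validated [metabolic_model()].
#' @export
read_model <- function(source, format = c("json", "sbml")) {
  format <- match.arg(format)
  txt <- .slurp(source)
  if (format == "json") .model_from_json(txt) else .model_from_sbml(txt)
}

.slurp <- function(source) {
  looks_like_doc <- grepl("[{<\n]", source)
  if (!looks_like_doc && file.exists(source)) {
    return(paste(readLines(source, warn = FALSE), collapse = "\n"))
  }
  source
}

.model_from_json <- function(txt) {
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop("malformed model JSON: ", conditionMessage(e))
  )
  for (field in c("metabolites", "reactions", "objective")) {
    if (is.null(doc[[field]])) stop("model JSON missing '", field, "'")
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry without 'id'")
    tibble::tibble(
      id = as.character(m$id),
      name = as.character(m$name %||% m$id),
      compartment = as.character(m$compartment %||% "c")
    )
  })
  rxns <- purrr::map_dfr(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without 'id'")
    if (is.null(r$stoichiometry) || length(r$stoichiometry) == 0) {
      stop("reaction '", r$id, "' has no stoichiometry")
    }
    stoich <- vapply(r$stoichiometry, as.numeric, numeric(1))
    rev_default <- .default_bounds(TRUE)
    tibble::tibble(
      id = as.character(r$id),
      stoichiometry = list(stoich),
      lower_bound = as.numeric(r$lower_bound %||% rev_default[1]),
      upper_bound = as.numeric(r$upper_bound %||% rev_default[2]),
      is_exchange = isTRUE(r$is_exchange)
    )
  })
  metabolic_model(mets, rxns, as.character(doc$objective))
}

.model_from_sbml <- function(txt) {
  doc <- tryCatch(xml2::read_xml(txt),
                  error = function(e) stop("malformed SBML: ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(species) == 0) stop("SBML document contains no species")
  mets <- tibble::tibble(
    id = xml2::xml_attr(species, "id"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"),
                           xml2::xml_attr(species, "id")),
    compartment = dplyr::coalesce(xml2::xml_attr(species, "compartment"), "c")
  )
  # fbc parameters: id -> value, used by fbc:lowerFluxBound references
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0) stop("SBML document contains no reactions")
  objective <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']"), "reaction")
  rxns <- purrr::map_dfr(rxn_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    reactants <- xml2::xml_find_all(
      node, "./s:listOfReactants/s:speciesReference", ns)
    products <- xml2::xml_find_all(
      node, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st[is.na(st)] <- "1"
      stats::setNames(sign * as.numeric(st), xml2::xml_attr(nodes, "species"))
    }
    stoich <- c(coef(reactants, -1), coef(products, 1))
    if (length(stoich) == 0) stop("SBML reaction '", id, "' has no participants")
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")
    bounds <- .default_bounds(reversible)
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(pval)) bounds[1] <- pval[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(pval)) bounds[2] <- pval[[ub_ref]]
    tibble::tibble(
      id = id, stoichiometry = list(stoich),
      lower_bound = bounds[1], upper_bound = bounds[2],
      is_exchange = length(stoich) == 1L || grepl("^EX_", id)
    )
  })
  if (is.na(objective)) objective <- rxns$id[nrow(rxns)]
  metabolic_model(mets, rxns, objective)
}

#' Serialize a metabolic model to canonical JSON
#'
#' The serialization is canonical -- metabolites, reactions and stoichiometry
#' keys are sorted by id -- so two serializations of the same model are
#' byte-identical and version-control diffs are stable. `read_model()` on the
#' output reproduces the model.
#'
#' @param model a `metabolic_model`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @param format only `"json"` is supported for writing.
#' @return The JSON text (invisibly when `path` is given).
#' @export
write_model <- function(model, path = NULL, format = "json") {
  format <- match.arg(format, "json")
  validate_model(model)
  met <- dplyr::arrange(model$metabolites, .data$id)
  rxn <- dplyr::arrange(model$reactions, .data$id)
  doc <- list(
    metabolites = purrr::pmap(met, function(id, name, compartment, ...) {
      list(id = id, name = name, compartment = compartment)
    }),
    reactions = purrr::pmap(rxn, function(id, stoichiometry, lower_bound,
                                          upper_bound, is_exchange, ...) {
      s <- stoichiometry[order(names(stoichiometry))]
      list(id = id, stoichiometry = as.list(s),
           lower_bound = lower_bound, upper_bound = upper_bound,
           is_exchange = is_exchange)
    }),
    objective = model$objective
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

.rxn_index <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction id: ",
         paste(reaction_id[is.na(i)], collapse = ", "))
  }
  i
}

#' Configure a single organic carbon source
#'
#' Sets the named exchange reaction's lower bound to `-max_uptake` (uptake is
#' negative flux) and its upper bound free, and closes every *other* exchange
#' reaction to uptake (lower bound 0) except those listed in `keep_open`
#' (inorganic exchanges such as CO2). Applying a second source to the result
#' therefore closes the first: sources are exclusive. The input model is not
#' modified.
#'
#' @param model a `metabolic_model`.
#' @param exchange_id id of the exchange reaction for the carbon source.
#' @param max_uptake positive maximum uptake flux (mmol/gDW/h).
#' @param keep_open exchange ids whose uptake is left untouched; defaults to
#'   exchanges whose id contains `"co2"`, `"o2"`, `"h2o"`, `"nh4"`, `"pi"` or
#'   `"so4"` (case-insensitive).
#' @return A new `metabolic_model`.
#' @export
set_carbon_source <- function(model, exchange_id, max_uptake = 10,
                              keep_open = NULL) {
  stopifnot(inherits(model, "metabolic_model"), max_uptake > 0)
  i <- .rxn_index(model, exchange_id)
  if (!isTRUE(model$reactions$is_exchange[i])) {
    stop("'", exchange_id, "' is not an exchange reaction")
  }
  rxn <- model$reactions
  if (is.null(keep_open)) {
    keep_open <- rxn$id[rxn$is_exchange &
                          grepl("co2|o2|h2o|nh4|pi|so4", rxn$id,
                                ignore.case = TRUE)]
  }
  close_idx <- which(rxn$is_exchange & !(rxn$id %in% c(exchange_id, keep_open)))
  rxn$lower_bound[close_idx] <- pmax(rxn$lower_bound[close_idx], 0)
  rxn$lower_bound[i] <- -max_uptake
  rxn$upper_bound[i] <- Inf
  model$reactions <- rxn
  validate_model(model)
}

#' Delete reactions by fixing their flux to zero
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids (may be empty).
#' @return A new `metabolic_model` with bounds (0, 0) on the named reactions;
#'   the input model is not modified.
#' @export
apply_knockouts <- function(model, reaction_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(reaction_ids) == 0) return(model)
  i <- .rxn_index(model, reaction_ids)
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
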