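#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = substrate, positive = product). Must be
#'   non-empty with non-zero coefficients.
#' @param reversible logical; if `TRUE` the default bounds are
#'   `(-1000, 1000)`, otherwise `(0, 1000)`.
#' @param lb,ub flux bounds (arbitrary units). A reversible reaction must
#'   have `lb < 0`.
#' @param gpr a [gpr] tree, a GPR string, or `NULL`.
#' @param name display name (defaults to the id).
#' @param pathway optional pathway label.
#' @param kind one of `"internal"`, `"transport"`, `"exchange"`, `"sink"`,
#'   `"demand"`, or `NA` (meaning not yet classified; see
#'   [classify_reaction()]).
#' @return an object of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lb = if (reversible) -1000 else 0, ub = 1000,
                     gpr = NULL, name = id, pathway = NA_character_,
                     kind = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!length(stoichiometry) || is.null(names(stoichiometry)))
    stop("reaction ", id, ": stoichiometry must be a non-empty named vector",
         call. = FALSE)
  if (any(stoichiometry == 0))
    stop("reaction ", id, ": zero stoichiometric coefficient for ",
         paste(names(stoichiometry)[stoichiometry == 0], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction ", id, ": duplicated metabolite in stoichiometry", call. = FALSE)
  if (reversible && lb >= 0)
    stop("reaction ", id, ": reversible but lower bound is not negative",
         call. = FALSE)
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (!is.na(kind)) kind <- match.arg(kind, reaction_kinds())
  stoichiometry <- stats::setNames(as.numeric(stoichiometry),
                                   names(stoichiometry))
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry[order(names(stoichiometry))],
                 reversible = isTRUE(reversible),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = gpr, pathway = pathway, kind = kind),
            class = "reaction")
}

reaction_kinds <- function() c("internal", "transport", "exchange", "sink", "demand")

#' @export
print.reaction <- function(x, ...) {
  s <- x$stoichiometry
  lhs <- s[s < 0]; rhs <- s[s > 0]
  fmt <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  }
  arrow <- if (x$reversible) "<=>" else "-->"
  cat(x$id, ": ", fmt(lhs), " ", arrow, " ", fmt(rhs), "\n", sep = "")
  if (!is.null(x$gpr)) cat("  gpr: ", gpr_string(x$gpr), "\n", sep = "")
  invisible(x)
}

#' Construct a metabolic model
#'
#' The central container for draft, template and curated genome-scale
#' metabolic models: compartments, genes, metabolites and reactions with
#' gene-protein-reaction (GPR) rules, plus an optional biomass objective.
#'
#' @param id model identifier.
#' @param compartments data.frame with columns `id`, `name`, or a character
#'   vector of compartment ids.
#' @param genes data.frame with columns `locus_tag` (unique,
#'   case-insensitively), `product` (optional free text) and optionally `ec`
#'   (a list column of EC-number character vectors).
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula` (Hill notation, `NA` allowed) and `charge`
#'   (integer, `NA` allowed).
#' @param reactions list of [reaction()] objects.
#' @param objective id of the biomass/objective reaction, or `NA`.
#' @param boundary id of the boundary (extracellular) compartment used by
#'   exchange-reaction detection, or `NA`.
#' @param namespace identifier namespace of the reaction ids (e.g. `"bigg"`,
#'   `"kegg"`); used by alias-based comparison.
#' @param validate run [validate_model()] on the result (default `TRUE`).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compartments, genes = NULL, metabolites = NULL,
                            reactions = list(), objective = NA_character_,
                            boundary = NA_character_, namespace = NA_character_,
                            validate = TRUE) {
  if (is.character(compartments))
    compartments <- data.frame(id = compartments, name = compartments,
                               stringsAsFactors = FALSE)
  if (is.null(genes))
    genes <- data.frame(locus_tag = character(0), product = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(genes$product)) genes$product <- rep(NA_character_, nrow(genes))
  if (is.null(genes$ec)) genes$ec <- replicate(nrow(genes), character(0), simplify = FALSE)
  if (is.null(metabolites))
    metabolites <- data.frame(id = character(0), name = character(0),
                              compartment = character(0), stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula))
    metabolites$formula <- rep(NA_character_, nrow(metabolites))
  if (is.null(metabolites$charge))
    metabolites$charge <- rep(NA_integer_, nrow(metabolites))
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id, compartments = compartments, genes = genes,
                      metabolites = metabolites, reactions = reactions,
                      objective = objective, boundary = boundary,
                      namespace = namespace),
                 class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

#' Validate a metabolic model's invariants
#'
#' Checks identifier uniqueness and referential integrity: every metabolite's
#' compartment exists, every reaction's metabolites exist, every GPR leaf
#' references a declared gene, and the objective (if set) names a reaction.
#'
#' @param model a [metabolic_model()].
#' @return the model, invisibly; stops with an itemized message on violation.
#' @export
validate_model <- function(model) {
  errs <- model_errors(model)
  if (length(errs))
    stop("invalid model '", model$id, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(model)
}

#' @rdname validate_model
#' @return `model_errors()` returns a character vector of violations
#'   (empty when the model is valid).
#' @export
model_errors <- function(model) {
  errs <- character(0)
  if (anyDuplicated(model$compartments$id))
    errs <- c(errs, "duplicated compartment ids")
  if (anyDuplicated(model$metabolites$id))
    errs <- c(errs, paste("duplicated metabolite ids:",
                          paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]), collapse = ", ")))
  if (anyDuplicated(tolower(model$genes$locus_tag)))
    errs <- c(errs, paste("duplicated locus tags (case-insensitive):",
                          paste(unique(model$genes$locus_tag[duplicated(tolower(model$genes$locus_tag))]), collapse = ", ")))
  bad_comp <- setdiff(model$metabolites$compartment, model$compartments$id)
  if (length(bad_comp))
    errs <- c(errs, paste("metabolite compartment(s) not declared:",
                          paste(bad_comp, collapse = ", ")))
  met_ids <- model$metabolites$id
  gene_ids <- model$genes$locus_tag
  for (r in model$reactions) {
    dangling <- setdiff(names(r$stoichiometry), met_ids)
    if (length(dangling))
      errs <- c(errs, paste0("reaction ", r$id, " references undeclared metabolite(s): ",
                             paste(dangling, collapse = ", ")))
    gg <- setdiff(gpr_genes(r$gpr), gene_ids)
    if (length(gg))
      errs <- c(errs, paste0("reaction ", r$id, " GPR references undeclared gene(s): ",
                             paste(gg, collapse = ", ")))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    errs <- c(errs, "duplicated reaction ids")
  if (!is.na(model$objective) && !model$objective %in% rids)
    errs <- c(errs, paste("objective reaction not in model:", model$objective))
  if (!is.na(model$boundary) && !model$boundary %in% model$compartments$id)
    errs <- c(errs, paste("boundary compartment not declared:", model$boundary))
  errs
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  compartments: ", nrow(x$compartments),
      "  genes: ", nrow(x$genes),
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", length(x$reactions), "\n", sep = "")
  if (!is.na(x$objective)) cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  object <- classify_model(object)
  kinds <- vapply(object$reactions, `[[`, "", "kind")
  print(object)
  if (length(kinds)) print(table(kind = kinds))
  invisible(object)
}

#' Reaction ids of a model
#' @param model a [metabolic_model()].
#' @export
reaction_ids <- function(model) unname(vapply(model$reactions, `[[`, "", "id"))

# strip the "_<compartment>" suffix from a metabolite id given its compartment
base_met_id <- function(met_id, compartment) {
  suf <- paste0("_", compartment)
  ifelse(endsWith(met_id, suf),
         substr(met_id, 1L, nchar(met_id) - nchar(suf)), met_id)
}

#' Classify a reaction as internal, transport, exchange, sink or demand
#'
#' Boundary pseudo-reactions are recognized structurally: an *exchange* has a
#' single metabolite that either lives in the model's designated boundary
#' compartment or whose reaction id bears the exchange prefix; a *demand*
#' (irreversible) or *sink* (reversible) has a single non-boundary
#' metabolite; a *transport* reaction spans at least two compartments with
#' some base metabolite (id stripped of its compartment suffix) appearing on
#' both sides in different compartments. Everything else is *internal*.
#'
#' @param rxn a [reaction()] belonging to `model`.
#' @param model the containing [metabolic_model()].
#' @param exchange_prefix reaction-id prefix marking exchanges (default
#'   `"EX_"`).
#' @return one of `"internal"`, `"transport"`, `"exchange"`, `"sink"`,
#'   `"demand"`.
#' @export
classify_reaction <- function(rxn, model, exchange_prefix = "EX_") {
  mets <- names(rxn$stoichiometry)
  comp <- model$metabolites$compartment[match(mets, model$metabolites$id)]
  if (length(mets) == 1L) {
    boundary_met <- !is.na(model$boundary) && identical(comp, model$boundary)
    if (boundary_met || startsWith(rxn$id, exchange_prefix)) return("exchange")
    return(if (rxn$reversible) "sink" else "demand")
  }
  if (length(unique(comp)) >= 2L) {
    base <- base_met_id(mets, comp)
    sgn <- sign(rxn$stoichiometry)
    for (b in unique(base[duplicated(base)])) {
      idx <- which(base == b)
      if (length(unique(comp[idx])) >= 2L &&
          any(sgn[idx] < 0) && any(sgn[idx] > 0)) return("transport")
    }
  }
  "internal"
}

#' Classify every reaction in a model
#'
#' @inheritParams classify_reaction
#' @return the model with each reaction's `kind` field set.
#' @export
classify_model <- function(model, exchange_prefix = "EX_") {
  model$reactions <- lapply(model$reactions, function(r) {
    r$kind <- classify_reaction(r, model, exchange_prefix)
    r
  })
  model
}

# ids of reactions of a given kind, classifying on the fly when needed
reactions_of_kind <- function(model, kinds, exchange_prefix = "EX_") {
  k <- vapply(model$reactions, function(r) {
    if (is.na(r$kind)) classify_reaction(r, model, exchange_prefix) else r$kind
  }, "")
  reaction_ids(model)[k %in% kinds]
}
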