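#' SBML input and output
#'
#' [read_sbml()] and [write_sbml()] cover the constraint-based subset of SBML
#' level 3 (versions 1 and 2) with the `fbc` version-2 package: species with
#' chemical formula and charge, flux bounds via parameters, gene products and
#' nested gene-product associations (GPR rules), and the active objective.
#' Identifiers follow the COBRA convention (`M_`, `R_`, `G_` prefixes added
#' on write, stripped on read); gene locus tags are carried in `fbc:label`
#' so that arbitrary tag characters survive the SId restriction.
#'
#' @name sbml_io
NULL

SBML_CORE_NS <- c(`3.1` = "http://www.sbml.org/sbml/level3/version1/core",
                  `3.2` = "http://www.sbml.org/sbml/level3/version2/core")
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
META_NS <- "https://gemdraft.invalid/sbml/meta"

sbml_sid <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  bad <- out != x
  if (any(bad))
    warning("identifier(s) sanitized for SBML: ",
            paste(x[bad], collapse = ", "), call. = FALSE)
  out
}

#' Write a model as SBML level 3 with fbc
#'
#' @param model a valid [metabolic_model()].
#' @param path output file path.
#' @param level_version `"3.1"` (level 3 version 1) or `"3.2"`.
#' @return `path`, invisibly. Refuses (with an itemized message) to write a
#'   model violating its invariants.
#' @export
write_sbml <- function(model, path, level_version = c("3.1", "3.2")) {
  level_version <- match.arg(level_version)
  errs <- model_errors(model)
  if (length(errs))
    stop("refusing to write invalid model:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  version <- if (level_version == "3.1") "1" else "2"
  root <- xml2::xml_new_root("sbml",
    xmlns = unname(SBML_CORE_NS[level_version]),
    `xmlns:fbc` = FBC_NS, `xmlns:gd` = META_NS,
    level = "3", version = version, `fbc:required` = "false")
  mnode <- xml2::xml_add_child(root, "model", id = sbml_sid(model$id),
                               `fbc:strict` = "false")
  meta <- character(0)
  if (!is.na(model$boundary)) meta["gd:boundary"] <- model$boundary
  if (!is.na(model$namespace)) meta["gd:namespace"] <- model$namespace
  if (length(meta)) {
    ann <- xml2::xml_add_child(mnode, "annotation")
    do.call(xml2::xml_add_child, c(list(ann, "gd:meta"), as.list(meta)))
  }

  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments)))
    xml2::xml_add_child(lc, "compartment", id = model$compartments$id[i],
                        name = model$compartments$name[i], constant = "true")

  if (nrow(model$metabolites)) {
    ls <- xml2::xml_add_child(mnode, "listOfSpecies")
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      sp <- xml2::xml_add_child(ls, "species", id = paste0("M_", sbml_sid(m$id)),
        name = m$name, compartment = m$compartment,
        hasOnlySubstanceUnits = "false", boundaryCondition = "false",
        constant = "false")
      if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
      if (!is.na(m$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
    }
  }

  bounds <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  if (length(bounds)) {
    lp <- xml2::xml_add_child(mnode, "listOfParameters")
    par_id <- stats::setNames(paste0("par_", seq_along(bounds)), num_chr(bounds))
    for (i in seq_along(bounds))
      xml2::xml_add_child(lp, "parameter", id = unname(par_id[i]),
                          value = num_chr(bounds[i]), constant = "true")
  } else par_id <- character(0)

  if (length(model$reactions)) {
    lr <- xml2::xml_add_child(mnode, "listOfReactions")
    for (r in model$reactions) {
      rn <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", sbml_sid(r$id)),
        name = r$name, reversible = tolower(r$reversible),
        `fbc:lowerFluxBound` = unname(par_id[num_chr(r$lb)]),
        `fbc:upperFluxBound` = unname(par_id[num_chr(r$ub)]))
      if (level_version == "3.1") xml2::xml_set_attr(rn, "fast", "false")
      if (!is.na(r$pathway)) xml2::xml_set_attr(rn, "gd:pathway", r$pathway)
      s <- r$stoichiometry
      if (any(s < 0)) {
        lre <- xml2::xml_add_child(rn, "listOfReactants")
        for (met in names(s)[s < 0])
          xml2::xml_add_child(lre, "speciesReference",
                              species = paste0("M_", sbml_sid(met)),
                              stoichiometry = num_chr(-s[[met]]), constant = "true")
      }
      if (any(s > 0)) {
        lpr <- xml2::xml_add_child(rn, "listOfProducts")
        for (met in names(s)[s > 0])
          xml2::xml_add_child(lpr, "speciesReference",
                              species = paste0("M_", sbml_sid(met)),
                              stoichiometry = num_chr(s[[met]]), constant = "true")
      }
      if (!is.null(r$gpr)) {
        gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
        write_gpa(gpa, r$gpr)
      }
    }
  }

  if (!is.na(model$objective)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              `fbc:activeObjective` = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", `fbc:id` = "obj",
                              `fbc:type` = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        `fbc:reaction` = paste0("R_", sbml_sid(model$objective)),
                        `fbc:coefficient` = "1")
  }

  if (nrow(model$genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(model$genes))) {
      g <- model$genes[i, ]
      gn <- xml2::xml_add_child(lg, "fbc:geneProduct",
        `fbc:id` = paste0("G_", sbml_sid(g$locus_tag)),
        `fbc:label` = g$locus_tag)
      if (!is.na(g$product)) xml2::xml_set_attr(gn, "fbc:name", g$product)
    }
  }

  xml2::write_xml(root, path)
  invisible(path)
}

write_gpa <- function(parent, gpr) {
  if (inherits(gpr, "gpr_leaf")) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        `fbc:geneProduct` = paste0("G_", sbml_sid(gpr$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", gpr$op))
    for (a in gpr$args) write_gpa(node, a)
  }
  invisible(parent)
}

# namespace-tolerant attribute lookup: exact name first, then local-name match
xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  if (name %in% names(at)) return(unname(at[[name]]))
  local <- sub("^.*:", "", name)
  hit <- which(sub("^.*:", "", names(at)) == local)
  if (length(hit)) unname(at[[hit[1L]]]) else NA_character_
}

xfind <- function(node, local) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", local, "']"))
}

FORMULA_RE <- "^([A-Z][a-z]?[0-9]*)+$"

#' Read an SBML level 3 model
#'
#' @param path an SBML L3V1/L3V2 file, optionally using the fbc extension
#'   for bounds, formulas, charges and GPR associations.
#' @return a [metabolic_model()] with GPR strings parsed into trees.
#'   Unparseable chemical formulas are stored as `NA` with a warning.
#'   Dangling species or gene references raise an integrity error listing
#'   the offending ids.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", basename(path), ": ", conditionMessage(e),
         call. = FALSE))
  mnode <- xfind(doc, "model")
  if (!length(mnode)) stop("no <model> element in ", basename(path), call. = FALSE)
  mnode <- mnode[[1L]]

  comp_nodes <- xfind(mnode, "compartment")
  compartments <- data.frame(
    id = vapply(comp_nodes, xattr, "", "id"),
    name = vapply(comp_nodes, function(n) xattr(n, "name") %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  compartments$name[is.na(compartments$name)] <- compartments$id[is.na(compartments$name)]

  sp_nodes <- xfind(mnode, "species")
  sp_sids <- vapply(sp_nodes, xattr, "", "id")
  met_ids <- sub("^M_", "", sp_sids)
  formulas <- vapply(sp_nodes, xattr, "", "fbc:chemicalFormula")
  bad_f <- !is.na(formulas) & !grepl(FORMULA_RE, formulas)
  if (any(bad_f)) {
    warning("unparseable chemical formula(s) stored as absent: ",
            paste(formulas[bad_f], collapse = ", "), call. = FALSE)
    formulas[bad_f] <- NA_character_
  }
  metabolites <- data.frame(
    id = met_ids,
    name = vapply(sp_nodes, function(n) {
      nm <- xattr(n, "name"); if (is.na(nm)) NA_character_ else nm
    }, ""),
    compartment = vapply(sp_nodes, xattr, "", "compartment"),
    formula = formulas,
    charge = suppressWarnings(as.integer(vapply(sp_nodes, xattr, "", "fbc:charge"))),
    stringsAsFactors = FALSE)
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]

  par_nodes <- xfind(mnode, "parameter")
  par_val <- stats::setNames(
    as.numeric(vapply(par_nodes, xattr, "", "value")),
    vapply(par_nodes, xattr, "", "id"))

  gp_nodes <- xfind(mnode, "geneProduct")
  gp_sid <- vapply(gp_nodes, xattr, "", "fbc:id")
  gp_label <- vapply(gp_nodes, xattr, "", "fbc:label")
  gp_label[is.na(gp_label)] <- sub("^G_", "", gp_sid[is.na(gp_label)])
  gp_map <- stats::setNames(gp_label, gp_sid)
  genes <- data.frame(locus_tag = unname(gp_label),
                      product = vapply(gp_nodes, xattr, "", "fbc:name"),
                      stringsAsFactors = FALSE)
  genes$ec <- replicate(nrow(genes), character(0), simplify = FALSE)

  sid_lookup <- stats::setNames(met_ids, sp_sids)
  rxn_nodes <- Filter(function(n) !is.na(xattr(n, "id")),
                      xfind(mnode, "reaction"))
  dangling_sp <- character(0); dangling_gp <- character(0)
  reactions <- lapply(rxn_nodes, function(rn) {
    rid <- sub("^R_", "", xattr(rn, "id"))
    refs <- c(xml2::xml_find_all(rn, ".//*[local-name()='speciesReference']"))
    stoich <- numeric(0)
    for (ref in refs) {
      sp <- xattr(ref, "species")
      coef <- as.numeric(xattr(ref, "stoichiometry") %na% "1")
      in_products <- identical(xml2::xml_name(xml2::xml_parent(ref)), "listOfProducts")
      if (!sp %in% names(sid_lookup)) {
        dangling_sp <<- c(dangling_sp, sp)
        next
      }
      met <- sid_lookup[[sp]]
      prev <- if (met %in% names(stoich)) stoich[[met]] else 0
      stoich[met] <- prev + if (in_products) coef else -coef
    }
    rev <- identical(xattr(rn, "reversible"), "true")
    lbp <- xattr(rn, "fbc:lowerFluxBound"); ubp <- xattr(rn, "fbc:upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else 1000
    gpa <- xml2::xml_find_first(rn, ".//*[local-name()='geneProductAssociation']")
    gpr <- NULL
    if (!inherits(gpa, "xml_missing")) {
      res <- read_gpa(xml2::xml_children(gpa)[[1L]], gp_map)
      gpr <- res$gpr
      dangling_gp <<- c(dangling_gp, res$dangling)
    }
    nm <- xattr(rn, "name"); if (is.na(nm)) nm <- rid
    pw <- xattr(rn, "gd:pathway")
    list(id = rid, name = nm, stoich = stoich, rev = rev, lb = lb, ub = ub,
         gpr = gpr, pathway = pw)
  })
  if (length(dangling_sp) || length(dangling_gp)) {
    stop("integrity error in ", basename(path), ": undeclared ",
         paste(c(
           if (length(dangling_sp)) paste0("species: ", paste(unique(dangling_sp), collapse = ", ")),
           if (length(dangling_gp)) paste0("gene(s): ", paste(unique(dangling_gp), collapse = ", "))
         ), collapse = "; "), call. = FALSE)
  }
  reactions <- lapply(reactions, function(r)
    reaction(r$id, r$stoich, reversible = r$rev, lb = r$lb, ub = r$ub,
             gpr = r$gpr, name = r$name, pathway = r$pathway))

  objective <- NA_character_
  fo <- xml2::xml_find_first(mnode, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing"))
    objective <- sub("^R_", "", xattr(fo, "fbc:reaction"))

  meta <- xml2::xml_find_first(mnode, ".//*[local-name()='meta']")
  boundary <- namespace <- NA_character_
  if (!inherits(meta, "xml_missing")) {
    boundary <- xattr(meta, "gd:boundary")
    namespace <- xattr(meta, "gd:namespace")
  }

  metabolic_model(id = xattr(mnode, "id") %na% "model",
                  compartments = compartments, genes = genes,
                  metabolites = metabolites, reactions = reactions,
                  objective = objective, boundary = boundary,
                  namespace = namespace)
}

`%na%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

read_gpa <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sid <- xattr(node, "fbc:geneProduct")
    if (!sid %in% names(gp_map))
      return(list(gpr = gpr_leaf(sub("^G_", "", sid)),
                  dangling = sub("^G_", "", sid)))
    return(list(gpr = gpr_leaf(gp_map[[sid]]), dangling = character(0)))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), read_gpa, gp_map = gp_map)
    return(list(gpr = gpr_node(nm, lapply(kids, `[[`, "gpr")),
                dangling = unlist(lapply(kids, `[[`, "dangling"))))
  }
  stop("unsupported gene association construct: ", nm, call. = FALSE)
}
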