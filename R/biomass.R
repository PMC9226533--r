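#' Monomer mass tables
#'
#' Average (not monoisotopic) molecular masses in g/mol for the 20
#' proteinogenic amino acids, the four ribonucleoside monophosphates (NMPs)
#' and the four deoxyribonucleoside monophosphates (dNMPs), together with
#' the polymerized residue mass (monomer mass minus one water, 18.0153
#' g/mol). Users may supply their own table with the same columns to any
#' composition function.
#'
#' @param kind `"protein"`, `"dna"` or `"rna"`.
#' @return data.frame with columns `code` (one-letter), `met_id` (base
#'   metabolite id), `monomer_mass`, `residue_mass`.
#' @export
monomer_masses <- function(kind = c("protein", "dna", "rna")) {
  kind <- match.arg(kind)
  water <- 18.0153
  tab <- switch(kind,
    protein = data.frame(
      code = c("A","R","N","D","C","E","Q","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V"),
      met_id = c("ala","arg","asn","asp","cys","glu","gln","gly","his","ile",
                 "leu","lys","met","phe","pro","ser","thr","trp","tyr","val"),
      residue_mass = c(71.0788, 156.1875, 114.1038, 115.0886, 103.1388,
                       129.1155, 128.1307, 57.0519, 137.1411, 113.1594,
                       113.1594, 128.1741, 131.1926, 147.1766, 97.1167,
                       87.0782, 101.1051, 186.2132, 163.1760, 99.1326),
      stringsAsFactors = FALSE),
    rna = data.frame(
      code = c("A", "C", "G", "U"),
      met_id = c("amp", "cmp", "gmp", "ump"),
      residue_mass = c(347.2212, 323.1965, 363.2206, 324.1813) - water,
      stringsAsFactors = FALSE),
    dna = data.frame(
      code = c("A", "C", "G", "T"),
      met_id = c("damp", "dcmp", "dgmp", "dtmp"),
      residue_mass = c(331.2218, 307.1971, 347.2212, 322.2085) - water,
      stringsAsFactors = FALSE))
  tab$monomer_mass <- tab$residue_mass + water
  tab
}

new_composition <- function(freq, monomers, kind) {
  # freq: named by code, sums to 1; coefficients in mmol per g of polymer
  freq <- freq[monomers$code]
  freq[is.na(freq)] <- 0
  names(freq) <- monomers$code
  mean_res <- sum(freq * monomers$residue_mass)
  out <- data.frame(code = monomers$code, met_id = monomers$met_id,
                    frequency = unname(freq),
                    coefficient = unname(1000 * freq / mean_res),
                    residue_mass = monomers$residue_mass,
                    stringsAsFactors = FALSE)
  structure(out, class = c("composition", "data.frame"), kind = kind)
}

weighted_counts <- function(seqs, weights, alphabet) {
  if (!length(seqs) || all(!nzchar(seqs)))
    stop("empty sequence input", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  else {
    w <- rep(1, length(seqs))
    if (!is.null(names(weights)) && !is.null(names(seqs)))
      w[match(names(weights), names(seqs))] <- weights
    else w[seq_along(weights)] <- weights
    weights <- w
  }
  if (any(weights < 0)) stop("negative expression weight", call. = FALSE)
  if (all(weights == 0)) stop("all expression weights are zero", call. = FALSE)
  counts <- stats::setNames(numeric(length(alphabet)), alphabet)
  skipped <- 0
  for (i in seq_along(seqs)) {
    if (weights[i] == 0) next
    ch <- strsplit(toupper(seqs[[i]]), "")[[1L]]
    ok <- ch %in% alphabet
    skipped <- skipped + sum(!ok)
    tab <- table(factor(ch[ok], levels = alphabet))
    counts <- counts + weights[i] * as.numeric(tab)
  }
  if (skipped > 0)
    warning(skipped, " non-standard letter(s) skipped", call. = FALSE)
  if (sum(counts) == 0) stop("no standard letters in input", call. = FALSE)
  counts
}

#' Genome-derived protein composition
#'
#' Computes amino-acid frequencies over all CDS translations (optionally
#' weighted by gene expression) and converts them to polymerization
#' coefficients in mmol per gram of protein:
#' `f_i = sum_g w_g count_i(g) / sum_g w_g len(g)` and
#' `c_i = 1000 f_i / sum_j f_j residue_mass_j`.
#'
#' @param cds_translations named character vector of protein sequences
#'   (20 standard letters; others skipped with a warning).
#' @param expression_weights optional non-negative weights named by locus
#'   tag; loci without a weight default to 1. Scaling all weights by a
#'   constant leaves the composition unchanged.
#' @param monomers a [monomer_masses()] table.
#' @return a `composition`: data.frame `code, met_id, frequency,
#'   coefficient, residue_mass`.
#' @export
protein_composition <- function(cds_translations, expression_weights = NULL,
                                monomers = monomer_masses("protein")) {
  counts <- weighted_counts(cds_translations, expression_weights, monomers$code)
  new_composition(counts / sum(counts), monomers, "protein")
}

#' Genome-derived DNA composition
#'
#' Nucleotide frequencies are counted over both strands, so `f_A = f_T =
#' (n_A + n_T) / (2L)` and `f_G = f_C = (n_G + n_C) / (2L)` exactly.
#'
#' @param genome a nucleotide sequence (string or character vector of
#'   contigs) over ACGT; ambiguity codes are skipped with a warning.
#' @param monomers a [monomer_masses()] table (dNMP residues).
#' @return a `composition` with dNMP coefficients in mmol per g of DNA.
#' @export
dna_composition <- function(genome, monomers = monomer_masses("dna")) {
  counts <- weighted_counts(genome, NULL, monomers$code)
  # both strands: A pairs with T, G with C
  both <- counts
  both["A"] <- both["T"] <- (counts[["A"]] + counts[["T"]]) / 2
  both["G"] <- both["C"] <- (counts[["G"]] + counts[["C"]]) / 2
  new_composition(both / sum(both), monomers, "dna")
}

#' Genome-derived RNA composition
#'
#' Single-strand nucleotide frequencies over the transcript set (T read as
#' U), optionally expression-weighted like [protein_composition()].
#'
#' @param gene_transcripts named character vector of transcript sequences.
#' @param expression_weights optional weights named by locus tag.
#' @param monomers a [monomer_masses()] table (NMP residues).
#' @return a `composition` with NMP coefficients in mmol per g of RNA.
#' @export
rna_composition <- function(gene_transcripts, expression_weights = NULL,
                            monomers = monomer_masses("rna")) {
  seqs <- vapply(gene_transcripts, function(s) gsub("T", "U", toupper(s)), "")
  names(seqs) <- names(gene_transcripts)
  counts <- weighted_counts(seqs, expression_weights, monomers$code)
  new_composition(counts / sum(counts), monomers, "rna")
}

#' Biomass macromolecule templates
#'
#' Ships editable baseline macromolecule mass fractions (g/gDW) and
#' growth-associated maintenance (GAM, mmol ATP/gDW) per broad organism
#' class. These are literature-typical baselines meant to be reviewed and
#' curated for the organism at hand, not measured values.
#'
#' @param class one of the classes in the shipped YAML
#'   (`"gram_negative"`, `"gram_positive"`, `"fungus"`, `"plant"`), or the
#'   path of a user YAML with the same structure.
#' @param renormalize if the fractions do not sum to 1 within 1e-3, rescale
#'   them (default `FALSE`: refuse).
#' @return a `biomass_template`: list with `fractions` (named numeric) and
#'   `gam`.
#' @export
biomass_template <- function(class = "gram_negative", renormalize = FALSE) {
  path <- if (file.exists(class)) class
  else system.file("extdata", "biomass_templates.yaml", package = "gemdraft")
  all <- yaml::read_yaml(path)
  tpl <- if (file.exists(class) && !is.null(all$fractions)) all else all[[class]]
  if (is.null(tpl)) stop("unknown biomass template class: ", class, call. = FALSE)
  new_biomass_template(unlist(tpl$fractions), tpl$gam %||% 0, renormalize)
}

#' @rdname biomass_template
#' @param fractions named numeric vector of macromolecule mass fractions.
#' @param gam growth-associated maintenance (mmol ATP/gDW).
#' @export
new_biomass_template <- function(fractions, gam = 0, renormalize = FALSE) {
  if (any(fractions < 0)) stop("negative biomass fraction", call. = FALSE)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-3) {
    if (!renormalize)
      stop("biomass fractions sum to ", format(s),
           ", not 1 (set renormalize = TRUE to rescale)", call. = FALSE)
    fractions <- fractions / s
  }
  structure(list(fractions = fractions, gam = gam), class = "biomass_template")
}

GENOME_DERIVED <- c("protein", "dna", "rna")

#' Build biomass pseudo-reactions
#'
#' Emits one polymerization pseudo-reaction per genome-derived macromolecule
#' (`sum_i c_i monomer_i -> 1 g e-Mk + sum_i c_i byproduct`, water for
#' protein and pyrophosphate for nucleic acids by default) and one biomass
#' reaction `sum_k m_k e-Mk + GAM (ATP + H2O) -> biomass + GAM (ADP + Pi +
#' H)`. Pseudo-metabolites carry the `e_` id prefix (displayed "e-") and are
#' excluded from mass-balance auditing.
#'
#' @param compositions named list of `composition` objects; a composition is
#'   required for every genome-derived macromolecule (protein/DNA/RNA) in
#'   the template.
#' @param template a [biomass_template()].
#' @param chemistry named character vector mapping macromolecule to
#'   byproduct (`"h2o"`, `"ppi"` or `"none"`).
#' @param compartment compartment id for all participants.
#' @return a list of [reaction()] objects, the biomass reaction (id
#'   `"biomass"`) last.
#' @export
build_biomass <- function(compositions, template,
                          chemistry = c(protein = "h2o", dna = "ppi", rna = "ppi"),
                          compartment = "c") {
  fr <- template$fractions[template$fractions > 0]
  missing_comp <- setdiff(intersect(names(fr), GENOME_DERIVED),
                          names(compositions))
  if (length(missing_comp))
    stop("missing composition for macromolecule(s): ",
         paste(missing_comp, collapse = ", "), call. = FALSE)
  suffix <- function(x) paste0(x, "_", compartment)
  pseudo_id <- function(k) suffix(paste0("e_", k))
  rxns <- list()
  for (k in names(fr)) {
    if (!k %in% names(compositions)) next
    comp <- compositions[[k]]
    nz <- comp[comp$coefficient > 0, , drop = FALSE]
    s <- stats::setNames(-nz$coefficient, suffix(nz$met_id))
    s[pseudo_id(k)] <- 1
    by <- chemistry[[k]] %||% "none"
    if (by != "none") {
      bymet <- suffix(by)
      s[bymet] <- (if (bymet %in% names(s)) s[[bymet]] else 0) + sum(nz$coefficient)
    }
    rxns[[paste0(k, "_synthesis")]] <- reaction(
      id = paste0(k, "_synthesis"), stoichiometry = s,
      name = paste0("e-", k, " polymerization"))
  }
  s <- stats::setNames(-unname(fr), pseudo_id(names(fr)))
  if (template$gam > 0) {
    gam <- template$gam
    add <- c(atp = -gam, h2o = -gam, adp = gam, pi = gam, h = gam)
    for (nm in names(add)) {
      met <- suffix(nm)
      s[met] <- (if (met %in% names(s)) s[[met]] else 0) + add[[nm]]
    }
  }
  s[suffix("e_Biomass")] <- 1
  rxns[["biomass"]] <- reaction("biomass", s, name = "biomass assembly")
  rxns
}

#' Insert biomass reactions into a model
#'
#' Adds any missing monomer and pseudo-metabolites, appends the reactions,
#' and sets the biomass reaction as the model objective.
#'
#' @param model a [metabolic_model()].
#' @param biomass_reactions output of [build_biomass()].
#' @param compartment compartment the reactions live in (added if new).
#' @export
add_biomass <- function(model, biomass_reactions, compartment = "c") {
  if (!compartment %in% model$compartments$id)
    model$compartments <- rbind(model$compartments,
                                data.frame(id = compartment, name = compartment))
  mets <- unique(unlist(lapply(biomass_reactions, function(r) names(r$stoichiometry))))
  new <- setdiff(mets, model$metabolites$id)
  if (length(new)) {
    add <- data.frame(id = new,
                      name = sub("^e_", "e-", base_met_id(new, compartment)),
                      compartment = compartment, formula = NA_character_,
                      charge = NA_integer_, stringsAsFactors = FALSE)
    model$metabolites <- rbind(model$metabolites, add)
  }
  for (r in biomass_reactions) model$reactions[[r$id]] <- r
  model$objective <- "biomass"
  validate_model(model)
}
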