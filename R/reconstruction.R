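#' Bidirectional best hits (BBH) orthology
#'
#' Given alignment tables in both directions between a target genome and a
#' template genome, keeps the reciprocal best pairs: after discarding hits
#' below `min_bitscore` or above `max_evalue`, `(a, b)` is retained iff `b`
#' is `a`'s top surviving forward hit and `a` is `b`'s top surviving reverse
#' hit. "Top" means maximal bitscore, ties broken by minimal e-value, then
#' lexicographic subject id.
#'
#' @param fwd,rev hit tables ([read_alignment_hits()] format or any
#'   data.frame with `query`, `subject`, `bitscore`, `evalue`): target
#'   queries vs template subjects, and the reverse.
#' @param min_bitscore,max_evalue retention filters (defaults 50 and 1e-5,
#'   common practice for protein BBH searches).
#' @return an `ortholog_map`: data.frame `target_gene, template_gene,
#'   bitscore_fwd, bitscore_rev`, one row per reciprocal pair.
#' @export
bidirectional_best_hits <- function(fwd, rev, min_bitscore = 50,
                                    max_evalue = 1e-5) {
  best_of <- function(h) {
    h <- h[h$bitscore >= min_bitscore & h$evalue <= max_evalue, , drop = FALSE]
    if (!nrow(h)) return(h[0, c("query", "subject", "bitscore")])
    h <- h[order(h$query, -h$bitscore, h$evalue, h$subject), , drop = FALSE]
    h[!duplicated(h$query), c("query", "subject", "bitscore")]
  }
  bf <- best_of(fwd)
  br <- best_of(rev)
  if (!nrow(bf) || !nrow(br)) return(empty_ortholog_map())
  rev_best <- stats::setNames(br$subject, br$query)
  keep <- !is.na(rev_best[bf$subject]) & rev_best[bf$subject] == bf$query
  pairs <- bf[keep, , drop = FALSE]
  out <- data.frame(target_gene = pairs$query, template_gene = pairs$subject,
                    bitscore_fwd = pairs$bitscore,
                    bitscore_rev = br$bitscore[match(pairs$subject, br$query)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ortholog_map", "data.frame"))
}

empty_ortholog_map <- function() {
  structure(data.frame(target_gene = character(0), template_gene = character(0),
                       bitscore_fwd = numeric(0), bitscore_rev = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"))
}

#' Construct an ortholog map from explicit pairs
#'
#' @param target_gene,template_gene character vectors of equal length.
#' @param bitscore_fwd,bitscore_rev optional score vectors.
#' @export
ortholog_map <- function(target_gene, template_gene,
                         bitscore_fwd = NA_real_, bitscore_rev = NA_real_) {
  out <- data.frame(target_gene = target_gene, template_gene = template_gene,
                    bitscore_fwd = bitscore_fwd, bitscore_rev = bitscore_rev,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("target_gene", "template_gene")]))
    stop("duplicated ortholog pair", call. = FALSE)
  structure(out, class = c("ortholog_map", "data.frame"))
}

#' Identity ortholog map over a gene set
#' @param genes character vector of locus tags.
#' @export
identity_orthologs <- function(genes)
  ortholog_map(genes, genes, bitscore_fwd = 100, bitscore_rev = 100)

# template gene -> character vector of target orthologs
ortholog_lookup <- function(orthologs) {
  split(orthologs$target_gene, orthologs$template_gene)
}

#' Propagate a template GPR rule onto target genes
#'
#' Each template-gene leaf is replaced by the OR of its target orthologs.
#' Under the `strict` policy an AND node with any unresolved child collapses
#' to unresolved (complexes are not asserted with missing subunits) while OR
#' nodes drop unresolved children; under `permissive`, AND nodes also drop
#' unresolved children as long as at least one child resolves. Returns
#' `NULL` when the whole tree is unresolved. Resulting trees are simplified
#' (no single-child AND/OR nodes).
#'
#' @param rule a [gpr] tree over template genes (or a GPR string).
#' @param orthologs an `ortholog_map` (see [bidirectional_best_hits()]).
#' @param policy `"strict"` (default) or `"permissive"`.
#' @return a [gpr] tree over target genes, or `NULL`.
#' @export
propagate_gpr <- function(rule, orthologs, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(NULL)
  lut <- ortholog_lookup(orthologs)
  walk <- function(node) {
    if (inherits(node, "gpr_leaf")) {
      targets <- lut[[node$gene]]
      if (is.null(targets) || !length(targets)) return(NULL)
      return(gpr_node("or", lapply(sort(targets), gpr_leaf)))
    }
    kids <- lapply(node$args, walk)
    resolved <- !vapply(kids, is.null, TRUE)
    if (node$op == "or") {
      if (!any(resolved)) return(NULL)
      return(gpr_node("or", kids[resolved]))
    }
    # and node
    if (policy == "strict") {
      if (!all(resolved)) return(NULL)
      return(gpr_node("and", kids))
    }
    if (!any(resolved)) return(NULL)
    gpr_node("and", kids[resolved])
  }
  walk(rule)
}

#' Reconstruct a draft model from a template via orthology
#'
#' The template's reactions are inherited exactly when their GPR rule,
#' propagated through the ortholog map ([propagate_gpr()]), is non-absent;
#' inherited reactions keep their stoichiometry, bounds and compartments and
#' carry the propagated rule. Template reactions without any GPR are copied
#' only when `include_orphans = TRUE`. Metabolites and compartments are
#' pruned to those referenced; the draft's gene set is exactly the target
#' genes appearing in some propagated rule.
#'
#' @param template a valid [metabolic_model()].
#' @param orthologs an `ortholog_map` of (target gene, template gene) pairs.
#' @param policy GPR propagation policy, see [propagate_gpr()].
#' @param include_orphans copy template reactions lacking a GPR (default
#'   `FALSE`: inheritance follows homologous genes only).
#' @param id id for the draft model.
#' @return a draft [metabolic_model()].
#' @export
reconstruct_from_template <- function(template, orthologs,
                                      policy = c("strict", "permissive"),
                                      include_orphans = FALSE,
                                      id = paste0(template$id, "_draft")) {
  policy <- match.arg(policy)
  kept <- list()
  for (r in template$reactions) {
    if (is.null(r$gpr)) {
      if (include_orphans) kept[[r$id]] <- r
      next
    }
    new_gpr <- propagate_gpr(r$gpr, orthologs, policy)
    if (is.null(new_gpr)) next
    r$gpr <- new_gpr
    kept[[r$id]] <- r
  }
  used_mets <- unique(unlist(lapply(kept, function(r) names(r$stoichiometry))))
  mets <- template$metabolites[template$metabolites$id %in% used_mets, , drop = FALSE]
  comps <- template$compartments[template$compartments$id %in% mets$compartment, , drop = FALSE]
  gene_ids <- sort(unique(as.character(unlist(
    lapply(kept, function(r) gpr_genes(r$gpr))))))
  genes <- data.frame(locus_tag = gene_ids,
                      product = rep(NA_character_, length(gene_ids)),
                      stringsAsFactors = FALSE)
  genes$ec <- replicate(nrow(genes), character(0), simplify = FALSE)
  metabolic_model(id = id, compartments = comps, genes = genes,
                  metabolites = mets, reactions = unname(kept),
                  boundary = if (!is.na(template$boundary) &&
                                 template$boundary %in% comps$id)
                    template$boundary else NA_character_,
                  namespace = template$namespace)
}

#' Assemble a de novo draft from annotations and a catalogue
#'
#' A catalogue entry is included iff its EC set intersects the annotated EC
#' set (exact four-field comparison; wildcard ECs such as `"2.7.1.-"` in the
#' annotations match catalogue ECs by prefix only when
#' `expand_wildcards = TRUE`). Each included reaction's GPR is the OR over
#' the genes annotated with a matching EC; all metabolites are placed in the
#' given compartment and pathway labels are copied.
#'
#' @param annotations an annotation table ([annotate_genes()] /
#'   [read_annotation_table()]).
#' @param catalogue a [reaction_catalogue()].
#' @param compartment compartment id for the single-compartment draft.
#' @param expand_wildcards match wildcard annotation ECs by prefix
#'   (default `FALSE`).
#' @param id model id.
#' @return a draft [metabolic_model()] in the catalogue's namespace.
#' @export
assemble_denovo <- function(annotations, catalogue, compartment = "c",
                            expand_wildcards = FALSE, id = "denovo_draft") {
  gene_ecs <- stats::setNames(annotations$ec, annotations$locus_tag)
  gene_ecs <- gene_ecs[lengths(gene_ecs) > 0]
  ec_match <- function(annot_ec, cat_ec) {
    if (grepl("-", annot_ec, fixed = TRUE)) {
      if (!expand_wildcards) return(FALSE)
      prefix <- sub("(\\.-)+$", ".", annot_ec)
      return(any(startsWith(cat_ec, prefix)))
    }
    annot_ec %in% cat_ec
  }
  kept <- list()
  gene_set <- character(0)
  for (i in seq_len(nrow(catalogue))) {
    cat_ec <- catalogue$ec[[i]]
    genes_i <- names(gene_ecs)[vapply(gene_ecs, function(ecs)
      any(vapply(ecs, ec_match, TRUE, cat_ec = cat_ec)), TRUE)]
    if (!length(genes_i)) next
    s <- catalogue$stoichiometry[[i]]
    names(s) <- paste0(names(s), "_", compartment)
    kept[[catalogue$id[i]]] <- reaction(
      id = catalogue$id[i], stoichiometry = s,
      reversible = catalogue$reversible[i],
      gpr = gpr_node("or", lapply(sort(genes_i), gpr_leaf)),
      name = catalogue$name[i], pathway = catalogue$pathway[i])
    gene_set <- union(gene_set, genes_i)
  }
  used_mets <- sort(unique(as.character(unlist(
    lapply(kept, function(r) names(r$stoichiometry))))))
  mets <- data.frame(id = used_mets,
                     name = as.character(base_met_id(used_mets, compartment)),
                     compartment = rep(compartment, length(used_mets)),
                     stringsAsFactors = FALSE)
  gene_set <- sort(gene_set)
  genes <- data.frame(locus_tag = gene_set,
                      product = rep(NA_character_, length(gene_set)),
                      stringsAsFactors = FALSE)
  genes$ec <- unname(gene_ecs[gene_set])
  metabolic_model(id = id, compartments = compartment, genes = genes,
                  metabolites = mets, reactions = unname(kept),
                  namespace = "catalogue")
}

#' Rewrite GPRs from a protein-complex subunit table
#'
#' For each listed reaction the GPR is rewritten as an OR over isoforms,
#' each isoform an AND over its subunit genes; unlisted reactions are left
#' untouched.
#'
#' @param model a [metabolic_model()].
#' @param subunit_table named list: reaction id -> list of character vectors
#'   (each vector one isoform's subunit genes).
#' @return the model with rewritten GPRs; a table citing an unknown
#'   reaction or gene raises an integrity error naming it.
#' @export
build_complex_gprs <- function(model, subunit_table) {
  if (!length(subunit_table)) return(model)
  unknown_rxn <- setdiff(names(subunit_table), reaction_ids(model))
  if (length(unknown_rxn))
    stop("subunit table cites unknown reaction(s): ",
         paste(unknown_rxn, collapse = ", "), call. = FALSE)
  unknown_gene <- setdiff(unique(unlist(subunit_table)), model$genes$locus_tag)
  if (length(unknown_gene))
    stop("subunit table cites unknown gene(s): ",
         paste(unknown_gene, collapse = ", "), call. = FALSE)
  for (rid in names(subunit_table)) {
    isoforms <- lapply(subunit_table[[rid]], function(genes)
      gpr_node("and", lapply(genes, gpr_leaf)))
    model$reactions[[rid]]$gpr <- gpr_node("or", isoforms)
  }
  model
}
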