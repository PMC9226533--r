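#' Deterministic synthetic fixtures
#'
#' Generators for structurally consistent synthetic inputs (genomes,
#' catalogues, template models, alignment tables, alias tables) with the
#' planted ground truth recorded in a manifest, so every pipeline stage can
#' be tested end to end without downloads. The fixtures are structural, not
#' biological: sequences are random codons, lineages and scores are
#' hand-planted.
#'
#' @name fixtures
NULL

# evaluate expr under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_codons <- function(n) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

fixture_lineages <- function() {
  target <- c("Bacteria", "Pseudomonadota", "Gammaproteobacteria",
              "Enterobacterales", "Enterobacteriaceae", "Escherichia",
              "Escherichia coli")
  list(
    target = target,
    near = list(organism = "Escherichia coli", lineage = target),
    mid = list(organism = "Salmonella enterica",
               lineage = c(target[1:5], "Salmonella", "Salmonella enterica")),
    far = list(organism = "Bacillus subtilis",
               lineage = c("Bacteria", "Bacillota", "Bacilli", "Bacillales",
                           "Bacillaceae", "Bacillus", "Bacillus subtilis")))
}

random_ec_pool <- function(n) {
  sprintf("%d.%d.%d.%d", sample(1:6, n, TRUE), sample(1:9, n, TRUE),
          sample(1:9, n, TRUE), seq_len(n))
}

# minimal GenBank flat-file emitter for fixture genomes
write_genbank <- function(genome, features, path, locus_name = "TOYGENOME") {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("LOCUS       %s %d bp    DNA     linear   BCT\n",
              locus_name, nchar(genome)), file = con)
  cat("DEFINITION  synthetic fixture genome.\n", file = con)
  cat("FEATURES             Location/Qualifiers\n", file = con)
  cat(sprintf("     source          1..%d\n", nchar(genome)), file = con)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$complement) loc <- sprintf("complement(%s)", loc)
    cat(sprintf("     CDS             %s\n", loc), file = con)
    cat(sprintf("                     /locus_tag=\"%s\"\n", f$locus_tag), file = con)
    if (!is.na(f$product))
      cat(sprintf("                     /product=\"%s\"\n", f$product), file = con)
  }
  cat("ORIGIN\n", file = con)
  pos <- seq(1L, nchar(genome), by = 60L)
  for (p in pos) {
    chunk <- substr(genome, p, min(p + 59L, nchar(genome)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    cat(sprintf("%9d %s\n", p, paste(groups, collapse = " ")), file = con)
  }
  cat("//\n", file = con)
  invisible(path)
}

#' Generate a consistent synthetic "toy world"
#'
#' Writes, under one directory, a mutually consistent fixture set: a genome
#' (FASTA + GenBank with CDS), a reaction catalogue TSV, a template model
#' SBML whose GPR rules reference template genes, forward/reverse alignment
#' tables consistent with a planted ortholog map, an annotation alignment
#' table supporting planted EC assignments, an alias table linking the
#' catalogue (kegg-style) and template (bigg-style) namespaces through hub
#' ids, and a YAML manifest recording every planted ground truth.
#'
#' The same seed always produces a byte-identical directory.
#'
#' @param dir output directory.
#' @param seed integer seed driving all randomness.
#' @param n_genes number of target genes (>= 1).
#' @param n_reactions number of catalogue/template internal reactions (>= 1).
#' @return the manifest, invisibly.
#' @export
make_toy_world <- function(dir, seed = 1L, n_genes = 12L, n_reactions = 10L) {
  stopifnot(n_genes >= 1, n_reactions >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    tags <- sprintf("g%03d", seq_len(n_genes))
    tmpl_genes <- sprintf("T%03d", seq_len(n_genes))
    lin <- fixture_lineages()

    ## genome: random CDS with spacers, every 4th CDS on the minus strand
    cds <- vapply(seq_len(n_genes), function(i)
      paste0("ATG", random_codons(sample(20:40, 1)), "TAA"), "")
    names(cds) <- tags
    genome <- ""
    feats <- list()
    for (i in seq_len(n_genes)) {
      genome <- paste0(genome, random_codons(sample(8:16, 1)))
      compl <- i %% 4L == 0L
      start <- nchar(genome) + 1L
      genome <- paste0(genome, if (compl) revcomp(cds[[i]]) else cds[[i]])
      feats[[i]] <- data.frame(locus_tag = tags[i], start = start,
                               end = nchar(genome), complement = compl,
                               product = sprintf("enzyme %d", i),
                               stringsAsFactors = FALSE)
    }
    genome <- paste0(genome, random_codons(10))
    features <- do.call(rbind, feats)
    write_fasta(stats::setNames(genome, "toy_genome"), file.path(dir, "genome.fna"))
    write_genbank(genome, features, file.path(dir, "genome.gb"))
    write_fasta(stats::setNames(vapply(cds, translate_cds, ""), tags),
                file.path(dir, "proteins.faa"))

    ## catalogue: one EC per entry, compartment-free equations
    ec_pool <- random_ec_pool(n_reactions)
    n_mets <- max(4L, n_reactions + 2L)
    met_pool <- sprintf("m%02d", seq_len(n_mets))
    cat_rows <- lapply(seq_len(n_reactions), function(i) {
      subs <- sample(met_pool, sample(1:2, 1))
      prods <- sample(setdiff(met_pool, subs), sample(1:2, 1))
      s <- c(stats::setNames(-sample(1:2, length(subs), TRUE), subs),
             stats::setNames(sample(1:2, length(prods), TRUE), prods))
      rev <- stats::runif(1) < 0.4
      data.frame(id = sprintf("K%05d", i), name = sprintf("reaction %d", i),
                 equation = format_equation(s, rev), reversible = rev,
                 ec = ec_pool[i], pathway = sprintf("path%d", (i %% 3L) + 1L),
                 spontaneous = FALSE, stringsAsFactors = FALSE)
    })
    catalogue <- reaction_catalogue(do.call(rbind, cat_rows))
    write_catalogue(catalogue, file.path(dir, "catalogue.tsv"))

    ## planted EC assignments: ~80% of genes carry a catalogue EC
    annotated <- sort(sample(seq_len(n_genes), max(1L, round(0.8 * n_genes))))
    ec_assign <- stats::setNames(
      ec_pool[(annotated - 1L) %% n_reactions + 1L], tags[annotated])

    ## annotation alignment table: planted EC dominates each gene's hits
    ann_rows <- list()
    for (g in tags) {
      n_hits <- sample(4:6, 1)
      planted <- if (g %in% names(ec_assign)) ec_assign[[g]] else NA_character_
      for (h in seq_len(n_hits)) {
        src <- if (h <= ceiling(0.7 * n_hits)) lin$near
               else if (h %% 2L == 0L) lin$mid else lin$far
        carries_planted <- !is.na(planted) && h <= ceiling(0.7 * n_hits)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          query = g, subject = sprintf("%s_h%d", g, h),
          bitscore = round(200 - 15 * h + stats::runif(1, 0, 5), 1),
          evalue = signif(10^(-80 + 6 * h), 3),
          identity = round(stats::runif(1, 40, 95), 1),
          subject_organism = src$organism,
          subject_lineage = paste(src$lineage, collapse = ";"),
          subject_ec = if (carries_planted) planted else "",
          subject_product = sprintf("enzyme %s", sub("^g0*", "", g)),
          reviewed = h == 1L, stringsAsFactors = FALSE)
      }
    }
    write_tsv(do.call(rbind, ann_rows), file.path(dir, "annotation_hits.tsv"))

    ## planted orthologs: about two thirds of the genes are reciprocal best
    planted_idx <- sort(sample(seq_len(n_genes), ceiling(2 / 3 * n_genes)))
    pairs <- data.frame(target_gene = tags[planted_idx],
                        template_gene = tmpl_genes[planted_idx],
                        stringsAsFactors = FALSE)
    aln_row <- function(q, s, bits, eval) data.frame(
      query = q, subject = s, bitscore = bits, evalue = eval,
      identity = 80, subject_organism = lin$near$organism,
      subject_lineage = paste(lin$near$lineage, collapse = ";"),
      subject_ec = "", subject_product = "homolog", reviewed = FALSE,
      stringsAsFactors = FALSE)
    fwd <- list(); rev <- list()
    for (i in planted_idx) {
      fwd[[length(fwd) + 1L]] <- aln_row(tags[i], tmpl_genes[i], 150 + i, 1e-60)
      rev[[length(rev) + 1L]] <- aln_row(tmpl_genes[i], tags[i], 140 + i, 1e-55)
      # sub-optimal decoys in both directions
      j <- planted_idx[(match(i, planted_idx) %% length(planted_idx)) + 1L]
      if (j != i) {
        fwd[[length(fwd) + 1L]] <- aln_row(tags[i], tmpl_genes[j], 80, 1e-20)
        rev[[length(rev) + 1L]] <- aln_row(tmpl_genes[i], tags[j], 75, 1e-18)
      }
    }
    for (i in setdiff(seq_len(n_genes), planted_idx)) {
      # unplanted genes: best forward hit is non-reciprocal or filtered out
      j <- planted_idx[1L]
      fwd[[length(fwd) + 1L]] <- aln_row(tags[i], tmpl_genes[j], 60, 1e-12)
      fwd[[length(fwd) + 1L]] <- aln_row(tags[i], tmpl_genes[i], 30, 1e-3)
    }
    write_tsv(do.call(rbind, fwd), file.path(dir, "aln_fwd.tsv"))
    write_tsv(do.call(rbind, rev), file.path(dir, "aln_rev.tsv"))

    ## template model: same stoichiometry as the catalogue, bigg-style ids,
    ## GPRs over template genes with generator-computed resolvability
    planted_set <- tmpl_genes[planted_idx]
    tr_ids <- sprintf("TR%03d", seq_len(n_reactions))
    gprs <- list()
    resolvable <- logical(n_reactions)
    for (i in seq_len(n_reactions)) {
      form <- sample(c("leaf", "or", "and"), 1)
      gs <- sample(tmpl_genes, if (form == "leaf") 1 else 2)
      gprs[[i]] <- switch(form,
        leaf = gpr_leaf(gs[1]),
        or = gpr_or(gs[1], gs[2]),
        and = gpr_and(gs[1], gs[2]))
      resolvable[i] <- switch(form,
        leaf = gs[1] %in% planted_set,
        or = any(gs %in% planted_set),
        and = all(gs %in% planted_set))
    }
    orphan <- n_reactions >= 4L
    mets_c <- data.frame(id = paste0(met_pool, "_c"), name = met_pool,
                         compartment = "c", stringsAsFactors = FALSE)
    mets_e <- data.frame(id = paste0(met_pool[1:2], "_e"), name = met_pool[1:2],
                         compartment = "e", stringsAsFactors = FALSE)
    rxns <- lapply(seq_len(n_reactions), function(i) {
      s <- catalogue$stoichiometry[[i]]
      names(s) <- paste0(names(s), "_c")
      reaction(tr_ids[i], s, reversible = catalogue$reversible[i],
               gpr = if (orphan && i == n_reactions) NULL else gprs[[i]],
               pathway = catalogue$pathway[i])
    })
    if (orphan) resolvable[n_reactions] <- FALSE
    # boundary machinery: exchange + transport for the first two metabolites
    rxns <- c(rxns, list(
      reaction("EX_m01_e", c(m01_e = -1), reversible = TRUE),
      reaction("EX_m02_e", c(m02_e = -1), reversible = TRUE),
      reaction("T_m01", c(m01_e = -1, m01_c = 1), reversible = TRUE),
      reaction("T_m02", c(m02_e = -1, m02_c = 1), reversible = TRUE)))
    tgenes <- data.frame(locus_tag = tmpl_genes, product = NA_character_,
                         stringsAsFactors = FALSE)
    tgenes$ec <- replicate(n_genes, character(0), simplify = FALSE)
    template <- metabolic_model(
      id = "toy_template", compartments = c("c", "e"), genes = tgenes,
      metabolites = rbind(mets_c, mets_e), reactions = rxns,
      boundary = "e", namespace = "bigg")
    write_sbml(template, file.path(dir, "template.xml"))

    ## alias table: kegg and bigg ids share a hub
    aliases <- alias_table(data.frame(
      namespace = rep(c("kegg", "bigg"), each = n_reactions),
      external_id = c(catalogue$id, tr_ids),
      hub_id = rep(sprintf("MNXR%04d", seq_len(n_reactions)), 2),
      stringsAsFactors = FALSE))
    write_alias_table(aliases, file.path(dir, "aliases.tsv"))

    manifest <- list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_reactions = as.integer(n_reactions),
      target_lineage = lin$target,
      ortholog_pairs = unname(Map(c, pairs$target_gene, pairs$template_gene)),
      ec_assignments = as.list(ec_assign),
      expected_draft_reactions = tr_ids[resolvable],
      files = list(genome_fasta = "genome.fna", genome_genbank = "genome.gb",
                   proteins = "proteins.faa", catalogue = "catalogue.tsv",
                   annotation_hits = "annotation_hits.tsv",
                   aln_fwd = "aln_fwd.tsv", aln_rev = "aln_rev.tsv",
                   template = "template.xml", aliases = "aliases.tsv"))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    invisible(manifest)
  })
}

#' Generate a random valid metabolic model
#'
#' Small random fixture models for property tests and round trips: two
#' compartments, internal/transport/exchange reactions, random GPR trees,
#' mixed present/absent formulas and charges.
#'
#' @param seed integer seed.
#' @param n_genes,n_mets,n_rxns sizes.
#' @param namespace declared reaction-id namespace.
#' @return a valid, classified [metabolic_model()].
#' @export
random_model <- function(seed = 1L, n_genes = 6L, n_mets = 10L, n_rxns = 12L,
                         namespace = "toy") {
  with_seed(seed, {
    genes <- sprintf("rg%02d", seq_len(n_genes))
    base <- sprintf("x%02d", seq_len(n_mets))
    mets_c <- data.frame(id = paste0(base, "_c"), name = base, compartment = "c",
      formula = ifelse(stats::runif(n_mets) < 0.7,
                       sprintf("C%dH%dO%d", sample(1:10, n_mets, TRUE),
                               sample(1:20, n_mets, TRUE), sample(1:8, n_mets, TRUE)),
                       NA_character_),
      charge = ifelse(stats::runif(n_mets) < 0.6,
                      sample(-3:3, n_mets, TRUE), NA_integer_),
      stringsAsFactors = FALSE)
    n_ext <- min(3L, n_mets)
    mets_e <- mets_c[seq_len(n_ext), ]
    mets_e$id <- paste0(base[seq_len(n_ext)], "_e")
    mets_e$compartment <- "e"
    mets <- rbind(mets_c, mets_e)

    random_gpr <- function() {
      if (!length(genes) || stats::runif(1) < 0.25) return(NULL)
      k <- sample(1:3, 1)
      gs <- sample(genes, min(k, length(genes)))
      if (length(gs) == 1L) return(gpr_leaf(gs))
      op <- sample(c("and", "or"), 1)
      tree <- gpr_node(op, lapply(gs, gpr_leaf))
      if (stats::runif(1) < 0.3 && length(genes) > 1L) {
        extra <- gpr_leaf(sample(genes, 1))
        tree <- gpr_node(if (op == "and") "or" else "and", list(tree, extra))
      }
      tree
    }

    rxns <- list()
    for (i in seq_len(n_rxns)) {
      kind <- sample(c("internal", "transport", "exchange"), 1,
                     prob = c(0.7, 0.15, 0.15))
      rid <- sprintf("RX%03d", i)
      if (kind == "exchange") {
        met <- sample(mets_e$id, 1)
        rxns[[i]] <- reaction(paste0("EX_", met), stats::setNames(-1, met),
                              reversible = TRUE)
      } else if (kind == "transport") {
        b <- sample(base[seq_len(n_ext)], 1)
        rev <- stats::runif(1) < 0.5
        rxns[[i]] <- reaction(rid, stats::setNames(c(-1, 1),
                                                   paste0(b, c("_e", "_c"))),
                              reversible = rev, gpr = random_gpr())
      } else {
        subs <- sample(mets_c$id, sample(1:3, 1))
        prods <- sample(setdiff(mets_c$id, subs), sample(1:3, 1))
        s <- c(stats::setNames(-sample(1:2, length(subs), TRUE), subs),
               stats::setNames(sample(1:2, length(prods), TRUE), prods))
        rev <- stats::runif(1) < 0.4
        lb <- if (rev) -1000 else 0
        ub <- sample(c(1000, 500.25), 1)
        rxns[[i]] <- reaction(rid, s, reversible = rev, lb = lb, ub = ub,
                              gpr = random_gpr(),
                              pathway = sample(c(NA, "pathA", "pathB"), 1))
      }
    }
    # de-duplicate exchange ids that may collide
    ids <- vapply(rxns, `[[`, "", "id")
    rxns <- rxns[!duplicated(ids)]
    gdf <- data.frame(locus_tag = genes, product = NA_character_,
                      stringsAsFactors = FALSE)
    gdf$ec <- replicate(n_genes, character(0), simplify = FALSE)
    classify_model(metabolic_model(
      id = sprintf("random_%d", seed), compartments = c("c", "e"),
      genes = gdf, metabolites = mets, reactions = rxns,
      boundary = "e", namespace = namespace))
  })
}

#' Mutate a model into a draft with known TP/FP/FN
#'
#' Removes `n_remove` random internal reactions and adds `n_add` novel
#' internal reactions whose ids are absent from any alias table, returning
#' the mutated model together with the comparison expected against the
#' original (tp = kept internals, fp = `n_add`, fn = `n_remove`).
#'
#' @param model a [metabolic_model()].
#' @param n_remove,n_add mutation counts; `n_remove` must not exceed the
#'   number of internal reactions.
#' @param seed integer seed.
#' @return list with elements `model` and `expected` (a
#'   [set_comparison()]).
#' @export
mutate_model <- function(model, n_remove, n_add, seed = 1L) {
  internal <- reactions_of_kind(model, "internal")
  if (n_remove > length(internal))
    stop("n_remove (", n_remove, ") exceeds the ", length(internal),
         " internal reactions", call. = FALSE)
  with_seed(seed, {
    removed <- if (n_remove > 0) sort(sample(internal, n_remove)) else character(0)
    kept <- setdiff(internal, removed)
    model$reactions <- model$reactions[setdiff(reaction_ids(model), removed)]
    if (!is.na(model$objective) && model$objective %in% removed)
      model$objective <- NA_character_
    comp <- model$compartments$id[1L]
    cmets <- model$metabolites$id[model$metabolites$compartment == comp]
    added <- character(0)
    if (n_add > 0) {
      if (length(cmets) < 2L) stop("too few metabolites to add reactions",
                                   call. = FALSE)
      for (i in seq_len(n_add)) {
        rid <- sprintf("XNOV%03d", i)
        pair <- sample(cmets, 2L)
        model$reactions[[rid]] <- reaction(rid,
          stats::setNames(c(-1, 1), pair), reversible = FALSE)
        added <- c(added, rid)
      }
    }
    model <- classify_model(model)
    list(model = model,
         expected = set_comparison(tp = length(kept), fp = length(added),
                                   fn = length(removed), tp_items = kept,
                                   fp_items = added, fn_items = removed))
  })
}
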