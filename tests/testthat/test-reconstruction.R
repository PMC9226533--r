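mk_aln <- function(query, subject, bitscore, evalue = 1e-20) {
  data.frame(query = query, subject = subject, bitscore = bitscore,
             evalue = evalue, stringsAsFactors = FALSE)
}

test_that("bidirectional best hits keep exactly the reciprocal top pairs", {
  fwd <- mk_aln(c("a1", "a1"), c("b1", "b2"), c(50, 40))
  rev <- mk_aln("b1", "a1", 49)
  bbh <- bidirectional_best_hits(fwd, rev, min_bitscore = 40)
  expect_identical(as.data.frame(bbh)[, 1:2],
                   data.frame(target_gene = "a1", template_gene = "b1",
                              stringsAsFactors = FALSE))
  # reciprocity failure: b1's best is a2
  rev2 <- mk_aln(c("b1", "b1"), c("a2", "a1"), c(60, 55))
  expect_identical(nrow(bidirectional_best_hits(fwd, rev2)), 0L)
  # filters remove sub-threshold hits entirely
  expect_identical(nrow(bidirectional_best_hits(
    mk_aln("a1", "b1", 10), mk_aln("b1", "a1", 10))), 0L)
  expect_identical(nrow(bidirectional_best_hits(fwd[0, ], rev[0, ])), 0L)
})

test_that("a genome against itself pairs every gene with itself", {
  genes <- sprintf("g%d", 1:6)
  self <- do.call(rbind, lapply(genes, function(g) rbind(
    mk_aln(g, g, 200),
    mk_aln(g, sample(setdiff(genes, g), 1), 90))))
  bbh <- bidirectional_best_hits(self, self)
  expect_identical(sort(bbh$target_gene), sort(genes))
  expect_identical(bbh$target_gene, bbh$template_gene)
})

test_that("BBH matches the brute-force reciprocal-best oracle with ties", {
  for (s in 1:25) {
    case <- random_bbh_case(s)
    got <- bidirectional_best_hits(case$fwd, case$rev)
    exp <- oracle_bbh(case$fwd, case$rev)
    got <- got[order(got$target_gene), c("target_gene", "template_gene")]
    rownames(got) <- rownames(exp) <- NULL
    expect_identical(as.data.frame(got), exp, label = paste("seed", s))
  }
})

test_that("GPR propagation follows the strict and permissive policies", {
  orth <- ortholog_map(c("t1", "t3"), c("g1", "g3"))
  # strict: AND with an unresolved child collapses; OR drops it
  out <- propagate_gpr("(g1 and g2) or g3", orth, "strict")
  expect_true(gpr_equal(out, gpr_leaf("t3")))
  # permissive: the AND keeps its resolved child
  out2 <- propagate_gpr("(g1 and g2) or g3", orth, "permissive")
  expect_true(gpr_equal(out2, parse_gpr("t1 or t3")))
  # a leaf with several orthologs becomes their OR
  orth2 <- ortholog_map(c("t1", "t4"), c("g1", "g1"))
  expect_true(gpr_equal(propagate_gpr("g1 or g2", orth2),
                        parse_gpr("t1 or t4")))
  # nothing resolves -> absent
  expect_null(propagate_gpr("g7 and g8", orth, "strict"))
  expect_null(propagate_gpr("g7 or g8", orth, "permissive"))
})

test_that("template reconstruction keeps reactions with resolvable GPRs", {
  w <- get_toy_world()
  template <- read_sbml(file.path(w$dir, "template.xml"))
  pairs <- do.call(rbind, w$manifest$ortholog_pairs)
  orth <- ortholog_map(pairs[, 1], pairs[, 2])
  draft <- reconstruct_from_template(template, orth)
  expect_setequal(reaction_ids(draft),
                  unlist(w$manifest$expected_draft_reactions))
  # all draft genes are target genes appearing in some propagated rule
  used <- unique(unlist(lapply(draft$reactions, function(r) gpr_genes(r$gpr))))
  expect_setequal(draft$genes$locus_tag, used)
  expect_true(all(startsWith(used, "g")))

  # empty ortholog map, orphans excluded -> no gene-associated reactions
  empty <- reconstruct_from_template(template, empty_ortholog_map())
  expect_length(empty$reactions, 0L)
})

test_that("template vs itself recovers its gene-associated reactions exactly", {
  m <- random_model(seed = 21)
  orth <- identity_orthologs(m$genes$locus_tag)
  draft <- reconstruct_from_template(m, orth)
  with_gpr <- Filter(function(r) !is.null(r$gpr), m$reactions)
  expect_setequal(reaction_ids(draft), vapply(with_gpr, `[[`, "", "id"))
  for (r in with_gpr)
    expect_true(gpr_equal(draft$reactions[[r$id]]$gpr, r$gpr))
})

test_that("enlarging the ortholog map never removes inherited reactions", {
  m <- random_model(seed = 22)
  genes <- m$genes$locus_tag
  set.seed(22)
  small_idx <- sample(length(genes), 2)
  small <- ortholog_map(paste0("tg", small_idx), genes[small_idx])
  big <- ortholog_map(paste0("tg", seq_along(genes)), genes)
  for (pol in c("strict", "permissive")) {
    d_small <- reconstruct_from_template(m, small, policy = pol)
    d_big <- reconstruct_from_template(m, big, policy = pol)
    expect_true(all(reaction_ids(d_small) %in% reaction_ids(d_big)))
    # permissive inherits at least what strict does
    d_strict <- reconstruct_from_template(m, small, policy = "strict")
    d_perm <- reconstruct_from_template(m, small, policy = "permissive")
    expect_true(all(reaction_ids(d_strict) %in% reaction_ids(d_perm)))
  }
})

test_that("de novo assembly includes catalogue entries matching annotated ECs", {
  cat_ <- reaction_catalogue(data.frame(
    id = c("R00754", "R99999"), name = c("adh", "other"),
    equation = c("etoh + nad <=> acald + nadh + h", "a => b"),
    reversible = c(TRUE, FALSE), ec = c("1.1.1.1", "9.9.9.9"),
    pathway = c("glycolysis", "misc"), stringsAsFactors = FALSE))
  ann <- structure(data.frame(locus_tag = c("gA", "gB"),
                              product = NA_character_, score = 1,
                              status = "annotated", stringsAsFactors = FALSE),
                   class = c("annotation_table", "data.frame"))
  ann$ec <- list("1.1.1.1", "1.1.1.1")
  draft <- assemble_denovo(ann, cat_, compartment = "c")
  expect_identical(reaction_ids(draft), "R00754")
  expect_true(gpr_equal(draft$reactions[["R00754"]]$gpr, parse_gpr("gA or gB")))
  expect_true(all(endsWith(draft$metabolites$id, "_c")))
  expect_identical(draft$reactions[["R00754"]]$pathway, "glycolysis")

  # disjoint EC sets -> empty model
  ann$ec <- list("5.5.5.5", "5.5.5.5")
  expect_length(assemble_denovo(ann, cat_)$reactions, 0L)

  # wildcards only match when expansion is enabled
  ann$ec <- list("1.1.1.-", "1.1.1.-")
  expect_length(assemble_denovo(ann, cat_)$reactions, 0L)
  expect_identical(reaction_ids(assemble_denovo(ann, cat_,
                                                expand_wildcards = TRUE)),
                   "R00754")
})

test_that("subunit tables rewrite GPRs as OR-of-AND isoforms", {
  mets <- data.frame(id = c("A_c", "B_c"), name = NA, compartment = "c")
  genes <- data.frame(locus_tag = c("g1", "g2", "g3"), product = NA_character_)
  m <- metabolic_model("m", "c", genes = genes, metabolites = mets,
    reactions = list(reaction("r1", c(A_c = -1, B_c = 1),
                              gpr = "g1 or g2 or g3")))
  m2 <- build_complex_gprs(m, list(r1 = list(c("g1", "g2"), "g3")))
  expect_true(gpr_equal(m2$reactions[["r1"]]$gpr,
                        parse_gpr("(g1 and g2) or g3")))
  expect_identical(build_complex_gprs(m, list()), m)
  expect_error(build_complex_gprs(m, list(r1 = list("gZ"))), "gZ")
  expect_error(build_complex_gprs(m, list(rX = list("g1"))), "rX")
})
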