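toy_alias <- function() {
  alias_table(data.frame(
    namespace = c("kegg", "bigg", "kegg", "kegg", "bigg", "bigg"),
    external_id = c("R00754", "ALCD2x", "R2", "R3", "B2", "B3b"),
    hub_id = c("MNXR1", "MNXR1", "MNXR2", "MNXR3", "MNXR2", "MNXR3")))
}

test_that("reaction ids convert through hub ids to the target namespace", {
  mets <- data.frame(id = c("a_c", "b_c"), name = NA, compartment = "c")
  m <- metabolic_model("m", "c", metabolites = mets, namespace = "kegg",
    reactions = list(reaction("R00754", c(a_c = -1, b_c = 1)),
                     reaction("R2", c(b_c = -1, a_c = 1)),
                     reaction("RX", c(a_c = -2, b_c = 1))))
  conv <- convert_reaction_ids(m, toy_alias(), "bigg")
  expect_identical(conv$map[["R00754"]], "ALCD2x")
  expect_identical(conv$map[["R2"]], "B2")
  expect_identical(conv$map[["RX"]], character(0))
  expect_identical(conv$n_converted, 2L)
  expect_identical(conv$n_unconverted, 1L)
  expect_error(convert_reaction_ids(m, toy_alias(), "bigg",
                                    source_namespace = "nope"),
               "unknown source namespace")
  # an id with two hubs unions the target ids
  al2 <- alias_table(data.frame(
    namespace = c("kegg", "kegg", "bigg", "bigg"),
    external_id = c("R9", "R9", "B9a", "B9b"),
    hub_id = c("MNX1", "MNX2", "MNX1", "MNX2")))
  m2 <- metabolic_model("m2", "c", metabolites = mets, namespace = "kegg",
    reactions = list(reaction("R9", c(a_c = -1, b_c = 1))))
  expect_setequal(convert_reaction_ids(m2, al2, "bigg")$map[["R9"]],
                  c("B9a", "B9b"))
})

test_that("reaction comparison applies the alias TP/FP/FN rules", {
  mets <- data.frame(id = c("a_c", "b_c"), name = NA, compartment = "c")
  draft <- metabolic_model("d", "c", metabolites = mets, namespace = "kegg",
    reactions = list(reaction("R00754", c(a_c = -1, b_c = 1)),  # -> c1 present
                     reaction("R2", c(b_c = -1, a_c = 1)),      # -> B2 absent
                     reaction("RX", c(a_c = -2, b_c = 1))))     # no alias
  curated <- metabolic_model("c", "c", metabolites = mets, namespace = "bigg",
    reactions = list(reaction("ALCD2x", c(a_c = -1, b_c = 1)),
                     reaction("B3b", c(b_c = -1, a_c = 1))))
  cmp <- compare_reactions(draft, curated, toy_alias())
  expect_identical(cmp$tp, 1L)
  expect_identical(cmp$fp, 2L)
  expect_identical(cmp$fn, 1L)
  expect_identical(cmp$tp_items, "R00754")
  expect_identical(cmp$fn_items, "B3b")
})

test_that("boundary reactions are excluded from both sides before counting", {
  mets <- data.frame(id = c("a_c", "a_e", "b_c"), name = NA,
                     compartment = c("c", "e", "c"), stringsAsFactors = FALSE)
  mk <- function(id, ns, extra = list()) metabolic_model(id, c("c", "e"),
    metabolites = mets, namespace = ns, boundary = "e",
    reactions = c(list(reaction("R00754", c(a_c = -1, b_c = 1)),
                       reaction("EX_a", c(a_e = -1), reversible = TRUE),
                       reaction("Ta", c(a_e = -1, a_c = 1))), extra))
  draft <- mk("d", "kegg")
  curated <- metabolic_model("c", "c",
    metabolites = mets[c(1, 3), ], namespace = "bigg",
    reactions = list(reaction("ALCD2x", c(a_c = -1, b_c = 1))))
  cmp <- compare_reactions(draft, curated, toy_alias())
  # the exchange and transport never enter the count
  expect_identical(cmp$tp + cmp$fp, 1L)
  expect_identical(cmp$tp, 1L)
  expect_identical(cmp$fn, 0L)
})

test_that("self-comparison with identity aliases is perfect", {
  m <- random_model(seed = 31)
  al <- identity_aliases(reaction_ids(m), m$namespace)
  cmp <- compare_reactions(m, m, al)
  expect_identical(cmp$fp, 0L)
  expect_identical(cmp$fn, 0L)
  met <- compute_metrics(cmp)
  expect_equal(met$f1, 1)
  expect_equal(met$jaccard_distance, 0)
  # empty draft: everything curated is missed
  empty <- metabolic_model("e", "c", namespace = m$namespace)
  cmp2 <- compare_reactions(empty, m, al)
  expect_identical(cmp2$tp, 0L)
  expect_identical(cmp2$fp, 0L)
  expect_identical(cmp2$fn, length(gemdraft:::reactions_of_kind(m, "internal")))
})

test_that("gene comparison folds case on locus tags", {
  mk <- function(id, tags) {
    g <- data.frame(locus_tag = tags, product = NA_character_,
                    stringsAsFactors = FALSE)
    metabolic_model(id, "c", genes = g)
  }
  cmp <- compare_genes(mk("d", c("abc_001", "ABC_002")),
                       mk("c", c("ABC_001", "abc_003")))
  expect_identical(cmp$tp, 1L)
  expect_identical(cmp$fp, 1L)
  expect_identical(cmp$fn, 1L)
  same <- compare_genes(mk("d", c("g1", "g2")), mk("c", c("G1", "G2")))
  expect_identical(same$fp + same$fn, 0L)
  disj <- compare_genes(mk("d", "g1"), mk("c", "g2"))
  expect_identical(disj$tp, 0L)
})

test_that("metrics match hand-computed and degenerate-corner values", {
  m <- compute_metrics(set_comparison(2, 1, 1))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$ratio, 2)
  expect_equal(m$jaccard_distance, 0.5)
  perfect <- compute_metrics(set_comparison(5, 0, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$jaccard_distance, 0)
  expect_identical(perfect$ratio, Inf)
  zero <- compute_metrics(set_comparison(0, 3, 2))
  expect_equal(zero$f1, 0)
  expect_equal(zero$jaccard_distance, 1)
  expect_equal(zero$ratio, 0)
})

test_that("1 - JD equals TP/(TP+FP+FN) on every comparison produced", {
  set.seed(41)
  for (k in 1:50) {
    cmp <- set_comparison(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    m <- compute_metrics(cmp)
    denom <- cmp$tp + cmp$fp + cmp$fn
    expect_equal(1 - m$jaccard_distance,
                 if (denom == 0) 1 else cmp$tp / denom)
  }
})

test_that("removing a false positive never hurts precision, F1 or ratio", {
  set.seed(42)
  for (k in 1:30) {
    tp <- sample(1:20, 1); fp <- sample(1:20, 1); fn <- sample(0:20, 1)
    before <- compute_metrics(set_comparison(tp, fp, fn))
    after <- compute_metrics(set_comparison(tp, fp - 1L, fn))
    expect_gte(after$precision, before$precision)
    expect_gte(after$f1, before$f1)
    expect_gte(after$ratio, before$ratio)
    expect_equal(after$recall, before$recall)
  }
})

test_that("the benchmark report ranks drafts by F1 within entity type", {
  w <- get_toy_world()
  template <- read_sbml(file.path(w$dir, "template.xml"))
  al <- read_alias_table(file.path(w$dir, "aliases.tsv"))
  pairs <- do.call(rbind, w$manifest$ortholog_pairs)
  full <- reconstruct_from_template(template, ortholog_map(pairs[, 1], pairs[, 2]))
  partial <- full
  drop <- reaction_ids(partial)[1]
  partial$reactions <- partial$reactions[setdiff(reaction_ids(partial), drop)]
  rep_ <- benchmark_report(list(full = full, partial = partial), template, al,
                           draft_ns = "bigg", curated_ns = "bigg")
  rx <- rep_[rep_$entity == "reactions", ]
  expect_identical(rx$draft[1], "full")  # superset TP set ranks first
  expect_true(all(diff(rx$f1) <= 0))
  expect_identical(nrow(rep_), 4L)
  expect_error(benchmark_report(list(), template, al), "at least one")
  single <- benchmark_report(list(d = full), template, al,
                             draft_ns = "bigg", curated_ns = "bigg")
  expect_identical(nrow(single), 2L)
})
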