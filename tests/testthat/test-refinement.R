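test_that("PSORTb long-format reports parse and rescale to [0,1]", {
  f <- tempfile()
  writeLines(c("SeqID: g1",
               "  Analysis Report:",
               "  Final Prediction:",
               "    Cytoplasmic 9.97",
               "",
               "SeqID: g2",
               "  Final Prediction:",
               "    Extracellular 6.50"), f)
  rep_ <- parse_localization_report(f, "psortb_long")
  expect_equal(rep_$score[rep_$locus_tag == "g1"], 0.997)
  expect_identical(rep_$compartment[rep_$locus_tag == "g1"], "c")
  expect_equal(rep_$score[rep_$locus_tag == "g2"], 0.65)
  # truncated / malformed prediction line errors with its position
  writeLines(c("SeqID: g1", "  Final Prediction:", "    Cytoplasmic"), f)
  expect_error(parse_localization_report(f, "psortb_long"), "line 3")
})

test_that("generic TSV reports pass through and validate their range", {
  f <- tempfile()
  writeLines(c("locus_tag\tcompartment\tscore", "g1\tc\t0.9", "g2\tp\t0.4"), f)
  rep_ <- parse_localization_report(f, "generic_tsv")
  expect_identical(nrow(rep_), 2L)
  writeLines(c("locus_tag\tcompartment\tscore", "g1\tc\t1.9"), f)
  expect_error(parse_localization_report(f, "generic_tsv"), "outside")
})

test_that("wolfpsort votes normalize per gene and loctree3 scores by 100", {
  f <- tempfile()
  writeLines(c("g1 details extr: 24, plas: 8"), f)
  rep_ <- parse_localization_report(f, "wolfpsort")
  expect_equal(rep_$score, c(0.75, 0.25))
  expect_identical(rep_$compartment, c("e", "p"))
  f2 <- tempfile()
  writeLines(c("# notes", "g1\t88\tcytosol"), f2)
  rep2 <- parse_localization_report(f2, "loctree3")
  expect_equal(rep2$score, 0.88)
})

loc_fixture_model <- function() {
  mets <- data.frame(id = c("A_c", "B_c", "C_c", "D_c"), name = NA,
                     compartment = "c", stringsAsFactors = FALSE)
  genes <- data.frame(locus_tag = c("g1", "g2", "g3"), product = NA_character_)
  metabolic_model("loc", c("c", "p"), genes = genes, metabolites = mets,
    reactions = list(
      reaction("r1", c(A_c = -1, B_c = 1), gpr = "g1"),
      reaction("r2", c(B_c = -1, C_c = 1), gpr = "g2"),
      reaction("r3", c(C_c = -1, D_c = 1), gpr = "g1 or g2")))
}

mk_report <- function(df) {
  structure(df[order(df$locus_tag, -df$score), ],
            class = c("localization_report", "data.frame"),
            dialect = "generic_tsv")
}

test_that("compartment integration re-homes reactions by GPR majority", {
  m <- loc_fixture_model()
  rep_ <- mk_report(data.frame(
    locus_tag = c("g1", "g2"), compartment = c("p", "c"),
    score = c(0.997, 0.9), stringsAsFactors = FALSE))
  out <- integrate_compartments(m, rep_, threshold = 0.5,
                                default_compartment = "c")
  # g1's reaction moves to p, g2's stays in c
  expect_identical(names(out$reactions[["r1"]]$stoichiometry),
                   c("A_p", "B_p"))
  expect_identical(names(out$reactions[["r2"]]$stoichiometry),
                   c("B_c", "C_c"))
  # r3 is split 1-1 between p and c: tie goes to the default
  expect_identical(names(out$reactions[["r3"]]$stoichiometry),
                   c("C_c", "D_c"))
  # below-threshold predictions fall back to the default compartment
  rep2 <- mk_report(data.frame(locus_tag = "g1", compartment = "p",
                               score = 0.3, stringsAsFactors = FALSE))
  out2 <- integrate_compartments(m, rep2, 0.5, "c")
  expect_identical(names(out2$reactions[["r1"]]$stoichiometry),
                   c("A_c", "B_c"))
  expect_error(integrate_compartments(m, rep_, 0.5, "zz"), "default")
})

test_that("compartment integration is idempotent at fixed inputs", {
  m <- loc_fixture_model()
  rep_ <- mk_report(data.frame(
    locus_tag = c("g1", "g2", "g3"), compartment = c("p", "p", "c"),
    score = c(0.9, 0.8, 0.95), stringsAsFactors = FALSE))
  once <- integrate_compartments(m, rep_, 0.5, "c")
  twice <- integrate_compartments(once, rep_, 0.5, "c")
  expect_identical(lapply(twice$reactions, `[[`, "stoichiometry"),
                   lapply(once$reactions, `[[`, "stoichiometry"))
})

test_that("mass balance audit reports balanced, unbalanced and unknown", {
  mets <- data.frame(
    id = c("h2_c", "o2_c", "h2o_c", "glc_c", "etoh_c", "mys_c"),
    name = NA, compartment = "c",
    formula = c("H2", "O2", "H2O", "C6H12O6", "C2H6O", NA),
    charge = 0L, stringsAsFactors = FALSE)
  m <- metabolic_model("bal", "c", metabolites = mets, reactions = list(
    reaction("water", c(h2_c = -2, o2_c = -1, h2o_c = 2)),
    reaction("ferm", c(glc_c = -1, etoh_c = 2)),
    reaction("myst", c(glc_c = -1, mys_c = 1)),
    reaction("EX_glc", c(glc_c = -1), reversible = TRUE)))
  bal <- check_mass_balance(m)
  expect_identical(bal$status[bal$reaction == "water"], "balanced")
  expect_identical(bal$status[bal$reaction == "ferm"], "unbalanced")
  # element deficit computed by independent arithmetic:
  # products 2x C2H6O minus glucose C6H12O6 = C -2, O -4
  imb <- bal$imbalance[[which(bal$reaction == "ferm")]]
  expect_equal(imb[["C"]], -2)
  expect_equal(imb[["O"]], -4)
  expect_false("H" %in% names(imb))
  expect_identical(bal$status[bal$reaction == "myst"], "unknown")
  # exchanges are skipped
  expect_false("EX_glc" %in% bal$reaction)
})

test_that("dead ends follow the admissible-direction definition", {
  m <- chain_model()
  de <- find_dead_ends(m)
  expect_identical(de$never_produced, "A_c")
  expect_identical(de$never_consumed, "C_c")
  # a reversible reaction produces and consumes both its metabolites
  m2 <- metabolic_model("rev", "c",
    metabolites = data.frame(id = c("A_c", "B_c"), name = NA, compartment = "c"),
    reactions = list(reaction("r", c(A_c = -1, B_c = 1), reversible = TRUE)))
  de2 <- find_dead_ends(m2)
  expect_length(de2$never_produced, 0L)
  expect_length(de2$never_consumed, 0L)
})

test_that("an orphan metabolite is the only dead end in a closed fixture", {
  w <- get_toy_world()
  m <- read_sbml(file.path(w$dir, "template.xml"))
  # add an orphan metabolite consumed by a demand but never produced
  m$metabolites <- rbind(m$metabolites,
    data.frame(id = "orphan_c", name = "orphan", compartment = "c",
               formula = NA_character_, charge = NA_integer_))
  m$reactions[["DM_orphan"]] <- reaction("DM_orphan", c(orphan_c = -1))
  de <- find_dead_ends(m)
  expect_true("orphan_c" %in% de$never_produced)
})

test_that("blocked-reaction search reaches the fixpoint on chains", {
  m <- chain_model()
  expect_setequal(find_blocked_reactions(m), c("r1", "r2"))
  # exchanges at both ends unblock the chain
  m$reactions[["EX_A"]] <- reaction("EX_A", c(A_c = -1), reversible = TRUE)
  m$reactions[["EX_C"]] <- reaction("EX_C", c(C_c = -1), reversible = TRUE)
  expect_length(find_blocked_reactions(m), 0L)
  # empty model
  expect_length(find_blocked_reactions(metabolic_model("e", "c")), 0L)
})

test_that("universal exchanges empty the blocked set on random models", {
  for (s in 1:10) {
    m <- random_model(seed = s)
    for (met in m$metabolites$id)
      m$reactions[[paste0("EX_all_", met)]] <-
        reaction(paste0("EX_all_", met), stats::setNames(-1, met),
                 reversible = TRUE)
    expect_length(find_blocked_reactions(m), 0L)
  }
})
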