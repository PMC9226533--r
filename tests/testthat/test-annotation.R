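mk_hit <- function(query, ec = character(0), lineage, organism = "org",
                   bitscore = 100, evalue = 1e-20, product = "prod",
                   subject = paste0("s", bitscore)) {
  h <- data.frame(query = query, subject = subject, bitscore = bitscore,
                  evalue = evalue, identity = 50, subject_organism = organism,
                  subject_product = product, reviewed = FALSE,
                  stringsAsFactors = FALSE)
  h$subject_lineage <- list(lineage)
  h$subject_ec <- list(ec)
  h
}

lin8 <- paste0("rank", 1:8)

test_that("alignment tables load grouped and sorted, bad rows rejected", {
  w <- get_toy_world()
  hits <- read_alignment_hits(file.path(w$dir, "annotation_hits.tsv"))
  expect_identical(length(unique(hits$query)), w$manifest$n_genes)
  # within each query, bitscores descend
  for (g in unique(hits$query)) {
    b <- hits$bitscore[hits$query == g]
    expect_true(all(diff(b) <= 0))
  }
  # negative e-value rejected with its line number
  f <- tempfile(fileext = ".tsv")
  df <- utils::read.delim(file.path(w$dir, "annotation_hits.tsv"))
  df$evalue[3] <- -1
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_alignment_hits(f), "line\\(s\\): 4")
  # missing mandatory column named in the error
  df$bitscore <- NULL
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_alignment_hits(f), "bitscore")
})

test_that("an empty alignment file yields an empty hit list", {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(c("query", "subject", "bitscore", "evalue", "identity",
                     "subject_organism", "subject_lineage", "subject_ec",
                     "subject_product", "reviewed"), collapse = "\t"), f)
  expect_identical(nrow(read_alignment_hits(f)), 0L)
})

test_that("candidate scores follow the frequency/taxonomy blend", {
  # all hits carry the EC and share the full target lineage -> score 1
  hits <- do.call(rbind, lapply(1:10, function(i)
    mk_hit("q", ec = "1.1.1.1", lineage = lin8, bitscore = 100 + i)))
  for (a in c(0, 0.3, 1)) {
    cand <- score_candidates(hits, lin8, alpha = a)
    expect_equal(cand$score, 1.0)
  }
  # alpha = 1: pure frequency; 3 of 4 hits carry the EC
  hits <- rbind(mk_hit("q", "2.7.1.2", lin8, bitscore = 101),
                mk_hit("q", "2.7.1.2", lin8, bitscore = 102),
                mk_hit("q", "2.7.1.2", lin8, bitscore = 103),
                mk_hit("q", character(0), lin8, bitscore = 104))
  cand <- score_candidates(hits, lin8, alpha = 1)
  expect_equal(cand$score[cand$label == "2.7.1.2"], 0.75)
  # alpha = 0: pure taxonomy; 4 of 8 ranks shared
  hits <- mk_hit("q", "1.2.3.4", lineage = c(lin8[1:4], paste0("x", 5:8)))
  cand <- score_candidates(hits, lin8, alpha = 0)
  expect_equal(cand$score, 0.5)
})

test_that("scores are invariant under permutation of the hit list", {
  set.seed(11)
  hits <- do.call(rbind, lapply(1:12, function(i)
    mk_hit("q", sample(c("1.1.1.1", "2.2.2.2"), 1),
           lineage = lin8[1:sample(4:8, 1)], bitscore = 90 + i)))
  a <- score_candidates(hits, lin8, alpha = 0.5)
  b <- score_candidates(hits[sample(nrow(hits)), ], lin8, alpha = 0.5)
  expect_equal(a, b)
})

test_that("duplicating a hit never lowers its label's frequency or score", {
  set.seed(12)
  for (k in 1:10) {
    hits <- do.call(rbind, lapply(1:6, function(i)
      mk_hit("q", sample(c("1.1.1.1", "2.2.2.2", "3.3.3.3"), 1),
             lineage = lin8[1:sample(3:8, 1)], bitscore = 80 + i)))
    base <- score_candidates(hits, lin8, alpha = 0.5)
    dup <- score_candidates(rbind(hits, hits[1, ]), lin8, alpha = 0.5)
    lab <- hits$subject_ec[[1]]
    expect_gte(dup$frequency[dup$label == lab], base$frequency[base$label == lab])
  }
})

test_that("selection applies the threshold and the lexicographic tie-break", {
  hits <- rbind(mk_hit("q", "1.1.1.2", lin8, bitscore = 101, subject = "sA"),
                mk_hit("q", "1.1.1.1", lin8, bitscore = 102, subject = "sB"))
  cand <- score_candidates(hits, lin8, alpha = 0.5)
  expect_identical(cand$label[1], "1.1.1.1")  # equal score+freq: lexicographic
  sel <- select_annotation(cand, tau = 0.5)
  expect_identical(sel$status, "annotated")
  sel2 <- select_annotation(cand, tau = 0.99)
  expect_identical(sel2$status, "below_threshold")
  expect_true(is.na(sel2$label))
  expect_identical(select_annotation(cand[0, ], 0.5)$status, "no_hits")
})

test_that("the automatic workflow prioritizes listed taxa over bitscore", {
  ec_coli <- list(organism = "Escherichia coli",
                  lineage = c("Bacteria", "Escherichia", "Escherichia coli"))
  bsub <- list(organism = "Bacillus subtilis",
               lineage = c("Bacteria", "Bacillus", "Bacillus subtilis"))
  hits <- rbind(
    mk_hit("q", "1.1.1.1", ec_coli$lineage, ec_coli$organism, bitscore = 40,
           product = "coli enzyme", subject = "sE"),
    mk_hit("q", "2.2.2.2", bsub$lineage, bsub$organism, bitscore = 90,
           product = "subtilis enzyme", subject = "sB"))
  a <- automatic_workflow(hits, "Escherichia")
  expect_identical(a$product, "coli enzyme")
  expect_identical(a$ec[[1]], "1.1.1.1")
  expect_false(a$fallback)
  b <- automatic_workflow(hits, "Bacillus")
  expect_identical(b$product, "subtilis enzyme")
  # no listed taxon matches: best bitscore adopted, flagged
  c_ <- automatic_workflow(hits, "Saccharomyces")
  expect_identical(c_$product, "subtilis enzyme")
  expect_true(c_$fallback)
  expect_error(automatic_workflow(hits, character(0)), "non-empty")
})

test_that("alpha extremes reduce to pure frequency / pure taxonomy ranking", {
  set.seed(13)
  for (k in 1:10) {
    hits <- do.call(rbind, lapply(1:8, function(i)
      mk_hit("q", sample(sprintf("1.1.1.%d", 1:3), 1),
             lineage = lin8[1:sample(2:8, 1)], bitscore = 70 + i)))
    c1 <- score_candidates(hits, lin8, alpha = 1)
    expect_equal(c1$score, c1$frequency)
    c0 <- score_candidates(hits, lin8, alpha = 0)
    expect_equal(c0$score, c0$taxonomy_score)
  }
})

test_that("grid search recovers parameters that reproduce a labelled sample", {
  w <- get_toy_world()
  hits <- read_alignment_hits(file.path(w$dir, "annotation_hits.tsv"))
  labelled <- data.frame(locus_tag = names(w$manifest$ec_assignments),
                         ec = unlist(w$manifest$ec_assignments),
                         stringsAsFactors = FALSE)
  grid <- tune_annotation(hits, w$manifest$target_lineage, labelled,
                          alphas = c(0, 0.5, 1), taus = c(0.3, 0.6))
  expect_true(all(c("alpha", "tau", "f1") %in% names(grid)))
  # the planted fixture is recoverable: the best configuration is perfect
  expect_equal(grid$f1[1], 1.0)
})
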