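# Independent oracles and small generators shared across the suite.
# These re-derive expected values by routes separate from the package code.

# --- metrics: direct evaluation of the five benchmark formulas ------------
oracle_metrics <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = p, recall = r,
       ratio = if (tp == 0) 0 else if (fp == 0) Inf else tp / fp,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
       jaccard_distance = if (tp + fp + fn > 0) 1 - tp / (fp + tp + fn) else 0)
}

# --- BBH: O(n^2) reciprocal-best search over explicit hit lists -----------
oracle_bbh <- function(fwd, rev, min_bitscore = 50, max_evalue = 1e-5) {
  keep <- function(h) h[h$bitscore >= min_bitscore & h$evalue <= max_evalue, ,
                        drop = FALSE]
  fwd <- keep(fwd); rev <- keep(rev)
  top_hit <- function(h, q) {
    hh <- h[h$query == q, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    best <- hh
    best <- best[best$bitscore == max(best$bitscore), , drop = FALSE]
    best <- best[best$evalue == min(best$evalue), , drop = FALSE]
    sort(best$subject)[1L]
  }
  pairs <- list()
  for (a in unique(fwd$query)) {
    b <- top_hit(fwd, a)
    if (is.na(b)) next
    if (identical(top_hit(rev, b), a))
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (!length(pairs))
    return(data.frame(target_gene = character(0), template_gene = character(0)))
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("target_gene", "template_gene")
  out[order(out$target_gene), , drop = FALSE]
}

# hit frames from a score matrix (integer scores force frequent ties)
hits_from_matrix <- function(scores, qnames, snames, evalue = 1e-10) {
  idx <- which(!is.na(scores), arr.ind = TRUE)
  data.frame(query = qnames[idx[, 1]], subject = snames[idx[, 2]],
             bitscore = scores[idx], evalue = evalue,
             stringsAsFactors = FALSE)
}

random_bbh_case <- function(seed) {
  set.seed(seed)
  n <- sample(2:50, 1)
  m <- sample(2:50, 1)
  qn <- sprintf("a%02d", seq_len(n))
  sn <- sprintf("b%02d", seq_len(m))
  fwd_scores <- matrix(sample(c(NA, 20:70), n * m, replace = TRUE), n, m)
  rev_scores <- matrix(sample(c(NA, 20:70), m * n, replace = TRUE), m, n)
  list(fwd = hits_from_matrix(fwd_scores, qn, sn),
       rev = hits_from_matrix(rev_scores, sn, qn))
}

# --- flux feasibility: LP steady-state oracle -----------------------------
# flux-variability check via scipy's linprog (HiGHS): maximize and minimize
# the flux through one reaction subject to S v = 0 and the model's bounds;
# a reaction is LP-blocked when both optima are ~0. Problems are batched
# into a single python call.
lp_case_for_reaction <- function(model, rid, cap = 1000) {
  rids <- reaction_ids(model)
  mets <- model$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids))
  for (j in seq_along(rids)) {
    r <- model$reactions[[rids[j]]]
    S[names(r$stoichiometry), j] <- r$stoichiometry
    lb[j] <- max(r$lb, -cap)
    ub[j] <- min(r$ub, cap)
  }
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  if (!nrow(S)) S <- matrix(0, 1, length(rids))
  list(S = unname(apply(S, 1, function(x) x, simplify = FALSE)),
       lb = lb, ub = ub, target = match(rid, rids) - 1L)
}

# returns, per case, the maximum attainable |flux| through the target column
oracle_lp_max_flux <- function(cases) {
  stopifnot(length(cases) > 0)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(cases, infile, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for case in cases:",
    "    S = np.array(case['S'], dtype=float)",
    "    n = len(case['lb'])",
    "    bounds = list(zip(case['lb'], case['ub']))",
    "    c = np.zeros(n); c[case['target']] = 1.0",
    "    best = 0.0",
    "    for sign in (1.0, -1.0):",
    "        res = linprog(sign * c, A_eq=S, b_eq=np.zeros(S.shape[0]),",
    "                      bounds=bounds, method='highs')",
    "        if res.status == 0:",
    "            best = max(best, abs(res.fun))",
    "        else:",
    "            best = float('nan')",
    "    out.append(best)",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, infile, outfile))
  stopifnot(status == 0)
  unlist(jsonlite::read_json(outfile))
}

# --- GPR satisfying set over a small gene universe ------------------------
gpr_satisfying_set <- function(gpr, universe) {
  if (is.null(gpr)) return(character(0))
  subsets <- lapply(0:(2^length(universe) - 1), function(mask)
    universe[bitwAnd(mask, 2^(seq_along(universe) - 1)) > 0])
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  keys[vapply(subsets, function(s) gpr_eval(gpr, s), TRUE)]
}

random_template_gpr <- function(template_genes) {
  k <- sample(1:3, 1)
  gs <- sample(template_genes, min(k, length(template_genes)))
  if (length(gs) == 1L) return(gpr_leaf(gs))
  op <- sample(c("and", "or"), 1)
  tree <- gpr_node(op, lapply(gs, gpr_leaf))
  if (runif(1) < 0.4) {
    more <- sample(template_genes, min(2, length(template_genes)))
    sub <- if (length(more) == 1) gpr_leaf(more) else
      gpr_node(sample(c("and", "or"), 1), lapply(more, gpr_leaf))
    tree <- gpr_node(if (op == "and") "or" else "and", list(tree, sub))
  }
  tree
}

random_ortholog_pairs <- function(template_genes, target_genes, p = 0.5) {
  pairs <- expand.grid(target_gene = target_genes,
                       template_gene = template_genes,
                       stringsAsFactors = FALSE)
  pairs[runif(nrow(pairs)) < p * 0.3, , drop = FALSE]
}

# --- balanced-reaction fixture generator ----------------------------------
counts_to_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  paste0(els, counts[els], collapse = "")
}

sum_counts <- function(a, b) {
  els <- union(names(a), names(b))
  vapply(els, function(e)
    (if (e %in% names(a)) a[[e]] else 0L) +
    (if (e %in% names(b)) b[[e]] else 0L), integer(1))
}

make_balanced_model <- function(seed, n_rxns = 50) {
  set.seed(seed)
  mets <- list(); rxns <- list()
  for (i in seq_len(n_rxns)) {
    f1 <- c(C = sample(1:6, 1), H = sample(1:12, 1), O = sample(1:6, 1))
    f2 <- c(C = sample(1:6, 1), H = sample(1:12, 1), N = sample(1:3, 1))
    a <- sprintf("s%03da_c", i); b <- sprintf("s%03db_c", i)
    p <- sprintf("s%03dp_c", i)
    mets[[length(mets) + 1L]] <- data.frame(
      id = c(a, b, p), name = NA_character_, compartment = "c",
      formula = c(counts_to_formula(f1), counts_to_formula(f2),
                  counts_to_formula(sum_counts(f1, f2))),
      charge = 0L, stringsAsFactors = FALSE)
    rxns[[i]] <- reaction(sprintf("B%03d", i),
                          stats::setNames(c(-1, -1, 1), c(a, b, p)))
  }
  metabolic_model(sprintf("balanced_%d", seed), "c",
                  metabolites = do.call(rbind, mets), reactions = rxns)
}
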