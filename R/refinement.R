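#' Parse a subcellular-localization prediction report
#'
#' Best-effort parsers for three common report dialects plus a generic TSV
#' escape hatch (the third-party formats drift between versions; the generic
#' dialect is the stable interface). All scores are rescaled to `[0, 1]` by
#' the dialect's declared maximum:
#'
#' * `psortb_long`: PSORTb-style "Long Format" blocks (`SeqID: <tag>` ...
#'   `Final Prediction:` followed by `<Localization> <score>` lines),
#'   scores on 0-10.
#' * `wolfpsort`: one line per gene, `<tag> <details>? comp1: n1, comp2:
#'   n2, ...` vote counts, normalized by the per-gene total.
#' * `loctree3`: tab-separated `id score localization` rows (comment lines
#'   starting `#` skipped), scores on 0-100.
#' * `generic_tsv`: columns `locus_tag`, `compartment`, `score` already in
#'   `[0, 1]`.
#'
#' @param path report file.
#' @param dialect one of `"psortb_long"`, `"wolfpsort"`, `"loctree3"`,
#'   `"generic_tsv"`.
#' @return a `localization_report`: data.frame `locus_tag, compartment,
#'   score` (normalized), with the dialect in attribute `dialect`. A line
#'   not matching the dialect raises a parse error citing it.
#' @export
parse_localization_report <- function(path,
    dialect = c("generic_tsv", "psortb_long", "wolfpsort", "loctree3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- switch(dialect,
    generic_tsv = {
      df <- read_tsv_strict(path, required = c("locus_tag", "compartment", "score"))
      df$score <- as.numeric(df$score)
      bad <- is.na(df$score) | df$score < 0 | df$score > 1
      if (any(bad))
        stop("generic_tsv scores outside [0,1] at line(s): ",
             paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
      df[, c("locus_tag", "compartment", "score")]
    },
    psortb_long = parse_psortb_long(path),
    wolfpsort = parse_wolfpsort(path),
    loctree3 = parse_loctree3(path))
  out <- out[order(out$locus_tag, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("localization_report", "data.frame"),
            dialect = dialect)
}

parse_psortb_long <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag <- NA_character_
  in_final <- FALSE
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^SeqID:", ln)) {
      tag <- sub("^\\S+\\s*", "", trimws(sub("^SeqID:", "", ln)))
      tag <- trimws(sub("^SeqID:", "", ln))
      tag <- sub("\\s.*$", "", tag)
      in_final <- FALSE
      next
    }
    if (grepl("^\\s*Final Prediction:", ln)) {
      if (is.na(tag))
        stop("psortb_long parse error at line ", i,
             ": Final Prediction before any SeqID", call. = FALSE)
      in_final <- TRUE
      next
    }
    if (in_final) {
      if (!nzchar(trimws(ln)) || grepl("^-", ln)) { in_final <- FALSE; next }
      m <- regmatches(trimws(ln),
                      regexec("^([A-Za-z/ ]+?)\\s+([0-9.]+)$", trimws(ln)))[[1L]]
      if (length(m) != 3L)
        stop("psortb_long parse error at line ", i, ": '", ln, "'",
             call. = FALSE)
      score <- as.numeric(m[3L])
      if (is.na(score) || score < 0 || score > 10)
        stop("psortb_long score out of range 0-10 at line ", i, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_tag = tag, compartment = normalize_compartment(m[2L]),
        score = score / 10, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no predictions found in ", basename(path), call. = FALSE)
  do.call(rbind, rows)
}

parse_wolfpsort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    tag <- sub("\\s.*$", "", ln)
    body <- sub("^\\S+\\s+(details\\s+)?", "", ln)
    parts <- trimws(strsplit(body, ",", fixed = TRUE)[[1L]])
    kv <- regmatches(parts, regexec("^([A-Za-z_./-]+):?\\s+([0-9.]+)$", parts))
    if (any(lengths(kv) != 3L))
      stop("wolfpsort parse error at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    comp <- vapply(kv, `[[`, "", 2L)
    votes <- as.numeric(vapply(kv, `[[`, "", 3L))
    if (any(votes < 0)) stop("wolfpsort negative vote at line ", i, call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = tag, compartment = normalize_compartment(comp),
      score = votes / sum(votes), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no predictions found in ", basename(path), call. = FALSE)
  do.call(rbind, rows)
}

parse_loctree3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no predictions found in ", basename(path), call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("loctree3 parse error at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    score <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(score) || score < 0 || score > 100)
      stop("loctree3 score out of range 0-100 at line ", i, call. = FALSE)
    data.frame(locus_tag = f[1L], compartment = normalize_compartment(f[3L]),
               score = score / 100, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fold predictor vocabulary onto short compartment ids
normalize_compartment <- function(x) {
  lut <- c("cytoplasmic" = "c", "cytoplasm" = "c", "cyto" = "c", "cytosol" = "c",
           "cytoplasmicmembrane" = "p", "plasmamembrane" = "p", "plas" = "p",
           "periplasmic" = "p", "periplasm" = "p",
           "extracellular" = "e", "extr" = "e", "secreted" = "e",
           "outermembrane" = "om", "innermembrane" = "im",
           "mitochondrion" = "m", "mito" = "m", "nucleus" = "n", "nucl" = "n")
  key <- gsub("[^a-z]", "", tolower(x))
  out <- lut[key]
  ifelse(is.na(out), x, out)
}

#' Integrate compartment predictions into a model
#'
#' Assigns each gene its top-scoring predicted compartment when that score
#' reaches the threshold (else the default compartment), re-homes every
#' gene-associated reaction to the majority compartment of its GPR genes
#' (ties go to the default), re-suffixes metabolite ids accordingly, and
#' re-runs reaction classification. Reactions without a GPR are left in
#' place. The operation is idempotent at fixed inputs.
#'
#' @param model a [metabolic_model()].
#' @param report a `localization_report`.
#' @param threshold minimum normalized score in `[0, 1]` to accept a
#'   prediction.
#' @param default_compartment compartment for unpredicted/below-threshold
#'   genes and ties; must exist in the model.
#' @return the re-compartmentalized, re-classified model.
#' @export
integrate_compartments <- function(model, report, threshold = 0.5,
                                   default_compartment) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!default_compartment %in% model$compartments$id)
    stop("default compartment not in model: ", default_compartment,
         call. = FALSE)
  top <- report[!duplicated(report$locus_tag), , drop = FALSE]  # sorted desc
  gene_comp <- ifelse(top$score >= threshold, top$compartment,
                      default_compartment)
  names(gene_comp) <- top$locus_tag

  new_comps <- setdiff(unique(gene_comp), model$compartments$id)
  if (length(new_comps))
    model$compartments <- rbind(model$compartments,
      data.frame(id = new_comps, name = new_comps, stringsAsFactors = FALSE))

  met_comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  met_info <- model$metabolites
  new_mets <- met_info[0, ]
  for (ri in seq_along(model$reactions)) {
    r <- model$reactions[[ri]]
    genes <- gpr_genes(r$gpr)
    if (!length(genes)) next
    comps <- gene_comp[genes]
    comps[is.na(comps)] <- default_compartment
    tab <- sort(table(comps), decreasing = TRUE)
    target <- if (length(tab) > 1L && tab[1L] == tab[2L])
      default_compartment else names(tab)[1L]
    s <- r$stoichiometry
    base <- base_met_id(names(s), met_comp[names(s)])
    new_ids <- paste0(base, "_", target)
    for (j in seq_along(new_ids)) {
      if (!new_ids[j] %in% c(met_info$id, new_mets$id)) {
        src <- met_info[met_info$id == names(s)[j], , drop = FALSE]
        src$id <- new_ids[j]
        src$compartment <- target
        new_mets <- rbind(new_mets, src)
      }
    }
    names(s) <- new_ids
    r$stoichiometry <- s[order(names(s))]
    model$reactions[[ri]] <- r
  }
  model$metabolites <- rbind(met_info, new_mets)
  # prune metabolites no longer referenced
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoichiometry))))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  rownames(model$metabolites) <- NULL
  model <- classify_model(model)
  validate_model(model)
  model
}

#' Parse a Hill-notation chemical formula
#'
#' @param formula e.g. `"C6H12O6"`.
#' @return named integer vector of element counts; stops on an
#'   unparsable token.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula))
    stop("empty formula", call. = FALSE)
  if (!grepl(FORMULA_RE, formula))
    stop("unparsable formula token: ", formula, call. = FALSE)
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  out <- integer(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

#' Audit elemental and charge balance
#'
#' For every reaction whose metabolites all carry formulas, sums
#' `coefficient x element count` across both sides. Pseudo-metabolites
#' (ids matching `pseudo_prefix`) and exchange/sink/demand reactions are
#' skipped; a reaction citing any formula-less metabolite is reported as
#' `"unknown"`.
#'
#' @param model a [metabolic_model()].
#' @param pseudo_prefix regex marking biomass-style pseudo-metabolites
#'   (default `"^e[-_]"`).
#' @return data.frame `reaction, status` (`balanced` / `unbalanced` /
#'   `unknown`) with list column `imbalance` (named per-element net
#'   production; positive = excess on products) and numeric
#'   `charge_imbalance`.
#' @export
check_mass_balance <- function(model, pseudo_prefix = "^e[-_]") {
  model <- classify_model(model)
  met <- model$metabolites
  rows <- lapply(model$reactions, function(r) {
    if (r$kind %in% c("exchange", "sink", "demand"))
      return(NULL)
    s <- r$stoichiometry
    s <- s[!grepl(pseudo_prefix, names(s))]
    if (!length(s)) return(NULL)
    idx <- match(names(s), met$id)
    formulas <- met$formula[idx]
    if (anyNA(formulas)) {
      return(data.frame(reaction = r$id, status = "unknown",
                        imbalance = I(list(NULL)),
                        charge_imbalance = NA_real_, stringsAsFactors = FALSE))
    }
    counts <- tryCatch(lapply(formulas, parse_formula), error = function(e) e)
    if (inherits(counts, "error")) {
      return(data.frame(reaction = r$id, status = "unknown",
                        imbalance = I(list(conditionMessage(counts))),
                        charge_imbalance = NA_real_, stringsAsFactors = FALSE))
    }
    elements <- unique(unlist(lapply(counts, names)))
    bal <- stats::setNames(numeric(length(elements)), elements)
    for (j in seq_along(s))
      bal[names(counts[[j]])] <- bal[names(counts[[j]])] + s[[j]] * counts[[j]]
    bal <- bal[abs(bal) > 1e-9]
    charge <- met$charge[idx]
    chg <- if (anyNA(charge)) NA_real_ else sum(s * charge)
    data.frame(reaction = r$id,
               status = if (length(bal)) "unbalanced" else "balanced",
               imbalance = I(list(bal)), charge_imbalance = chg,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(reaction = character(0), status = character(0),
                      imbalance = I(list()), charge_imbalance = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# producibility/consumability matrices under admissible directions:
# reversible reactions count both ways, exchanges (and sinks) both ways
production_tables <- function(model) {
  rids <- reaction_ids(model)
  produced <- consumed <- stats::setNames(
    rep(list(character(0)), nrow(model$metabolites)), model$metabolites$id)
  for (r in model$reactions) {
    s <- r$stoichiometry
    both <- r$reversible || r$kind %in% c("exchange", "sink")
    for (m in names(s)) {
      if (s[[m]] > 0 || both) produced[[m]] <- c(produced[[m]], r$id)
      if (s[[m]] < 0 || both) consumed[[m]] <- c(consumed[[m]], r$id)
    }
  }
  list(produced = produced, consumed = consumed)
}

#' Find dead-end metabolites
#'
#' A metabolite is *never produced* if no reaction can create it under any
#' admissible direction (reversible reactions count both ways; boundary
#' exchanges count as both producers and consumers), and symmetrically
#' *never consumed*.
#'
#' @param model a [metabolic_model()].
#' @return list with character vectors `never_produced` and
#'   `never_consumed`.
#' @export
find_dead_ends <- function(model) {
  model <- classify_model(model)
  pt <- production_tables(model)
  list(never_produced = names(pt$produced)[lengths(pt$produced) == 0],
       never_consumed = names(pt$consumed)[lengths(pt$consumed) == 0])
}

#' Find topologically blocked reactions
#'
#' Iterates to a fixpoint: any reaction with a substrate that is never
#' produced or a product that is never consumed (direction-aware: a
#' reversible reaction is removed only when both directions are blocked) is
#' removed and dead ends are recomputed. Every returned reaction provably
#' cannot carry steady-state flux; the check is a topological relaxation of
#' flux-variability analysis, so it is sound but not complete.
#'
#' @param model a [metabolic_model()].
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model) {
  model <- classify_model(model)
  active <- reaction_ids(model)
  repeat {
    sub <- model
    sub$reactions <- model$reactions[active]
    pt <- production_tables(sub)
    np <- names(pt$produced)[lengths(pt$produced) == 0]
    nc <- names(pt$consumed)[lengths(pt$consumed) == 0]
    blocked_now <- vapply(sub$reactions, function(r) {
      s <- r$stoichiometry
      if (r$kind %in% c("exchange", "sink"))
        return(any(names(s) %in% np) && any(names(s) %in% nc))
      fwd_dead <- any(names(s)[s < 0] %in% np) || any(names(s)[s > 0] %in% nc)
      if (!r$reversible) return(fwd_dead)
      bwd_dead <- any(names(s)[s > 0] %in% np) || any(names(s)[s < 0] %in% nc)
      fwd_dead && bwd_dead
    }, TRUE)
    if (!any(blocked_now)) break
    active <- active[!blocked_now]
    if (!length(active)) break
  }
  setdiff(reaction_ids(model), active)
}
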