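#' Load a tabular homology-search result
#'
#' Reads alignment hits produced by a protein similarity search (BLAST- or
#' Diamond-style tabular output extended with subject metadata). Two dialects
#' are supported:
#'
#' * `"extended"`: the standard 12-column pairwise format
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`) extended with `subject_organism`, `subject_lineage`
#'   (semicolon-separated, root first), `subject_ec` (semicolon-separated),
#'   `subject_product`, `reviewed`.
#' * `"compact"`: columns `query subject bitscore evalue identity
#'   subject_organism subject_lineage subject_ec subject_product reviewed`
#'   (the fixture dialect).
#'
#' @param path tab-separated file with a header row.
#' @param dialect `"compact"` or `"extended"`.
#' @return a data.frame of hits, grouped by query and sorted by descending
#'   bitscore within each query, with list columns `subject_lineage` and
#'   `subject_ec`. Rows with unparsable or out-of-range numerics are
#'   rejected with their line numbers.
#' @export
read_alignment_hits <- function(path, dialect = c("compact", "extended")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "compact") {
    c(query = "query", subject = "subject", bitscore = "bitscore",
      evalue = "evalue", identity = "identity")
  } else {
    c(query = "qseqid", subject = "sseqid", bitscore = "bitscore",
      evalue = "evalue", identity = "pident")
  }
  extra <- c("subject_organism", "subject_lineage", "subject_ec",
             "subject_product", "reviewed")
  df <- read_tsv_strict(path, required = c(unname(cols), extra))
  if (!nrow(df)) {
    out <- data.frame(query = character(0), subject = character(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      identity = numeric(0), subject_organism = character(0),
                      subject_product = character(0), reviewed = logical(0),
                      stringsAsFactors = FALSE)
    out$subject_lineage <- list(); out$subject_ec <- list()
    return(out)
  }
  hits <- data.frame(query = as.character(df[[cols["query"]]]),
                     subject = as.character(df[[cols["subject"]]]),
                     bitscore = suppressWarnings(as.numeric(df[[cols["bitscore"]]])),
                     evalue = suppressWarnings(as.numeric(df[[cols["evalue"]]])),
                     identity = suppressWarnings(as.numeric(df[[cols["identity"]]])),
                     subject_organism = as.character(df$subject_organism),
                     subject_product = as.character(df$subject_product),
                     reviewed = as.logical(df$reviewed),
                     stringsAsFactors = FALSE)
  hits$subject_lineage <- split_set(df$subject_lineage)
  hits$subject_ec <- split_set(df$subject_ec)

  bad <- is.na(hits$bitscore) | is.na(hits$evalue) | hits$evalue < 0 |
    is.na(hits$identity) | hits$identity < 0 | hits$identity > 100 |
    lengths(hits$subject_lineage) == 0
  if (any(bad)) {
    stop("rejected ", sum(bad), " malformed row(s) in ", basename(path),
         " at line(s): ", paste(which(bad) + 1L, collapse = ", "),
         call. = FALSE)
  }
  hits[order(hits$query, -hits$bitscore, hits$evalue, hits$subject), ,
       drop = FALSE]
}

lineage_similarity <- function(subject_lineage, target_lineage) {
  n <- min(length(subject_lineage), length(target_lineage))
  shared <- 0L
  while (shared < n && subject_lineage[shared + 1L] == target_lineage[shared + 1L])
    shared <- shared + 1L
  shared / max(length(subject_lineage), length(target_lineage))
}

#' Score annotation candidates for one gene
#'
#' Combines, for each candidate label among a gene's homology hits, how often
#' the label occurs (*frequency*) with how taxonomically close its carriers
#' are to the annotated organism (*taxonomy score*: the longest shared
#' lineage prefix, relative to the longer lineage, maximized over carrying
#' hits). The final score is the linear blend
#' `alpha * frequency + (1 - alpha) * taxonomy_score`.
#'
#' @param hits data.frame of [read_alignment_hits()] rows sharing one query.
#' @param target_lineage character vector of the target organism's lineage,
#'   root first.
#' @param alpha blend weight in `[0, 1]`; `1` ranks by pure frequency, `0`
#'   by pure taxonomy.
#' @param type score EC-number labels (`"ec"`) or product-name labels
#'   (`"product"`, normalized by case folding and whitespace collapse).
#' @return a data.frame `label, frequency, taxonomy_score, score,
#'   supporting_hits`, sorted by descending score, ties by descending
#'   frequency then lexicographic label. Empty for an empty hit list.
#' @export
score_candidates <- function(hits, target_lineage, alpha = 0.5,
                             type = c("ec", "product")) {
  type <- match.arg(type)
  stopifnot(alpha >= 0, alpha <= 1)
  empty <- data.frame(label = character(0), frequency = numeric(0),
                      taxonomy_score = numeric(0), score = numeric(0),
                      supporting_hits = integer(0), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  if (length(unique(hits$query)) != 1L)
    stop("score_candidates expects hits for a single query", call. = FALSE)

  labels_per_hit <- if (type == "ec") hits$subject_ec
  else lapply(hits$subject_product, function(p)
    if (is.na(p) || !nzchar(squish(p))) character(0) else tolower(squish(p)))
  tax_per_hit <- vapply(hits$subject_lineage, lineage_similarity,
                        numeric(1), target_lineage = target_lineage)

  all_labels <- sort(unique(unlist(labels_per_hit)))
  if (!length(all_labels)) return(empty)
  n <- nrow(hits)
  rows <- lapply(all_labels, function(lab) {
    carrier <- vapply(labels_per_hit, function(l) lab %in% l, TRUE)
    data.frame(label = lab, frequency = sum(carrier) / n,
               taxonomy_score = max(tax_per_hit[carrier]),
               supporting_hits = sum(carrier), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$score <- alpha * out$frequency + (1 - alpha) * out$taxonomy_score
  out <- out[order(-out$score, -out$frequency, out$label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("label", "frequency", "taxonomy_score", "score", "supporting_hits")]
}

#' Select the annotation from scored candidates
#'
#' @param candidates output of [score_candidates()] (already sorted).
#' @param tau acceptance threshold on the blended score.
#' @return a list `label, score, status` with status `"annotated"`,
#'   `"below_threshold"` or `"no_hits"`.
#' @export
select_annotation <- function(candidates, tau = 0.5) {
  if (!nrow(candidates))
    return(list(label = NA_character_, score = NA_real_, status = "no_hits"))
  top <- candidates[1L, ]
  if (top$score >= tau)
    list(label = top$label, score = top$score, status = "annotated")
  else
    list(label = NA_character_, score = top$score, status = "below_threshold")
}

#' Annotate all genes with the frequency+taxonomy score
#'
#' Applies [score_candidates()] and [select_annotation()] per gene, for both
#' EC numbers and product names.
#'
#' @inheritParams score_candidates
#' @param hits a full hit table ([read_alignment_hits()]).
#' @param tau acceptance threshold.
#' @param genes optional character vector of all locus tags; genes without
#'   hits are reported with status `"no_hits"`.
#' @return an annotation table: data.frame `locus_tag, product, score,
#'   status` with list column `ec`.
#' @export
annotate_genes <- function(hits, target_lineage, alpha = 0.5, tau = 0.5,
                           genes = NULL) {
  by_gene <- split(hits, hits$query)
  tags <- union(names(by_gene), genes %||% character(0))
  rows <- lapply(sort(tags), function(g) {
    h <- by_gene[[g]]
    if (is.null(h) || !nrow(h))
      return(list(locus_tag = g, product = NA_character_,
                  ec = character(0), score = NA_real_, status = "no_hits"))
    ec_sel <- select_annotation(score_candidates(h, target_lineage, alpha, "ec"), tau)
    pr_sel <- select_annotation(score_candidates(h, target_lineage, alpha, "product"), tau)
    status <- if (ec_sel$status == "annotated" || pr_sel$status == "annotated")
      "annotated"
    else if (ec_sel$status == "no_hits" && pr_sel$status == "no_hits") "no_hits"
    else "below_threshold"
    score <- suppressWarnings(max(ec_sel$score, pr_sel$score, na.rm = TRUE))
    if (!is.finite(score)) score <- NA_real_
    list(locus_tag = g,
         product = if (pr_sel$status == "annotated") pr_sel$label else NA_character_,
         ec = if (ec_sel$status == "annotated") ec_sel$label else character(0),
         score = score, status = status)
  })
  annotation_table(rows)
}

annotation_table <- function(rows) {
  out <- data.frame(locus_tag = vapply(rows, `[[`, "", "locus_tag"),
                    product = vapply(rows, `[[`, "", "product"),
                    score = vapply(rows, `[[`, numeric(1), "score"),
                    status = vapply(rows, `[[`, "", "status"),
                    stringsAsFactors = FALSE)
  out$ec <- lapply(rows, `[[`, "ec")
  structure(out[, c("locus_tag", "product", "ec", "score", "status")],
            class = c("annotation_table", "data.frame"))
}

#' Annotate genes by taxonomic priority (automatic workflow)
#'
#' For each gene, hits are ranked by the position of the first priority
#' taxon (genus or species name) occurring in their subject organism or
#' lineage, then by descending bitscore, then by subject accession; the
#' top-ranked hit's product and EC set are adopted. Genes whose hits match
#' no listed taxon fall back to the best-bitscore hit and are flagged.
#'
#' @param hits a hit table ([read_alignment_hits()]).
#' @param priority_taxa non-empty ordered character vector of genus/species
#'   names, most trusted first.
#' @return an annotation table with an extra logical column `fallback`.
#' @export
automatic_workflow <- function(hits, priority_taxa) {
  if (!length(priority_taxa)) stop("priority_taxa must be non-empty", call. = FALSE)
  by_gene <- split(hits, hits$query)
  rows <- lapply(sort(names(by_gene)), function(g) {
    h <- by_gene[[g]]
    prio <- vapply(seq_len(nrow(h)), function(i) {
      names_i <- c(h$subject_organism[i], h$subject_lineage[[i]])
      m <- which(vapply(priority_taxa, function(t)
        any(grepl(t, names_i, fixed = TRUE)), TRUE))
      if (length(m)) min(m) else Inf
    }, numeric(1))
    ord <- order(prio, -h$bitscore, h$subject)
    top <- h[ord[1L], ]
    list(locus_tag = g, product = top$subject_product,
         ec = top$subject_ec[[1L]], score = NA_real_,
         status = "annotated", fallback = is.infinite(prio[ord[1L]]))
  })
  out <- annotation_table(rows)
  out$fallback <- vapply(rows, `[[`, TRUE, "fallback")
  out
}

#' Write / read an annotation table as TSV
#'
#' @param tab an annotation table.
#' @param path file path.
#' @export
write_annotation_table <- function(tab, path) {
  df <- as.data.frame(tab)
  df$ec <- join_set(df$ec)
  write_tsv(df, path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_strict(path, required = c("locus_tag", "product", "ec",
                                           "score", "status"))
  df$ec <- split_set(df$ec)
  df$product <- as.character(df$product)
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Grid-search annotation parameters against a labelled sample
#'
#' Evaluates combinations of the blend weight and acceptance threshold
#' against a user-labelled gene sample and reports the pair with the best
#' EC-annotation F1 score. This is a deliberately simple replacement for
#' semi-automatic parameter calibration: it needs only a small labelled
#' sample and an exhaustive grid.
#'
#' @inheritParams annotate_genes
#' @param labelled data.frame with columns `locus_tag` and `ec` (the trusted
#'   EC for that gene).
#' @param alphas,taus numeric grids to search.
#' @return a data.frame of the full grid with columns `alpha, tau, tp, fp,
#'   fn, f1`, sorted by descending F1; the best row first.
#' @export
tune_annotation <- function(hits, target_lineage, labelled,
                            alphas = seq(0, 1, by = 0.25),
                            taus = seq(0.1, 0.9, by = 0.2)) {
  stopifnot(nrow(labelled) > 0)
  grid <- expand.grid(alpha = alphas, tau = taus)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ann <- annotate_genes(hits, target_lineage, grid$alpha[i], grid$tau[i])
    pred <- stats::setNames(vapply(ann$ec, function(e)
      if (length(e)) e[[1L]] else NA_character_, ""), ann$locus_tag)
    truth <- stats::setNames(labelled$ec, labelled$locus_tag)
    p <- pred[names(truth)]
    tp <- sum(!is.na(p) & p == truth)
    fp <- sum(!is.na(p) & p != truth)
    fn <- sum(is.na(p))
    m <- compute_metrics(set_comparison(tp = tp, fp = fp, fn = fn))
    data.frame(alpha = grid$alpha[i], tau = grid$tau[i], tp = tp, fp = fp,
               fn = fn, f1 = m$f1)
  })
  out <- do.call(rbind, res)
  out[order(-out$f1, out$tau, out$alpha), , drop = FALSE]
}
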