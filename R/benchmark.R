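#' Reaction-identifier alias tables
#'
#' A many-to-many cross-namespace identifier map keyed by a hub namespace
#' (MetaNetX-style `reac_xref`): records `(namespace, external_id, hub_id)`.
#' Namespace comparison is case-insensitive, identifier comparison
#' case-preserving. One `(namespace, id)` may map to several hub ids.
#'
#' @param records data.frame with columns `namespace`, `external_id`,
#'   `hub_id`.
#' @return an object of class `alias_table`.
#' @export
alias_table <- function(records) {
  stopifnot(all(c("namespace", "external_id", "hub_id") %in% names(records)))
  records$namespace <- tolower(records$namespace)
  records <- unique(records[, c("namespace", "external_id", "hub_id")])
  structure(records, class = c("alias_table", "data.frame"))
}

#' @rdname alias_table
#' @param path TSV with columns `namespace`, `external_id`, `hub_id`.
#' @export
read_alias_table <- function(path) {
  alias_table(read_tsv_strict(path, required = c("namespace", "external_id",
                                                 "hub_id")))
}

#' @rdname alias_table
#' @param aliases an `alias_table`.
#' @export
write_alias_table <- function(aliases, path) {
  write_tsv(as.data.frame(aliases), path)
}

#' Identity alias table over a set of ids
#'
#' Maps every id to itself through a hub of the same name, for one or more
#' namespaces; used for self-comparisons.
#'
#' @param ids character vector of reaction ids.
#' @param namespaces namespaces to register the ids under.
#' @export
identity_aliases <- function(ids, namespaces = "self") {
  alias_table(do.call(rbind, lapply(namespaces, function(ns)
    data.frame(namespace = ns, external_id = ids, hub_id = ids,
               stringsAsFactors = FALSE))))
}

# (namespace, ids) -> list of hub-id sets
hubs_of <- function(aliases, namespace, ids) {
  sel <- aliases[aliases$namespace == tolower(namespace), , drop = FALSE]
  split_map <- split(sel$hub_id, sel$external_id)
  lapply(ids, function(i) unique(split_map[[i]] %||% character(0)))
}

# hub ids -> ids in a namespace
ids_in_ns <- function(aliases, namespace, hub_ids) {
  sel <- aliases[aliases$namespace == tolower(namespace), , drop = FALSE]
  unique(sel$external_id[sel$hub_id %in% hub_ids])
}

#' Convert reaction identifiers across namespaces
#'
#' Maps each reaction of a model, through its hub ids, to the union of its
#' identifiers in the target namespace. Reactions with no hub entry map to
#' the empty set.
#'
#' @param model a [metabolic_model()] whose `namespace` field (or
#'   `source_namespace`) names the ids' namespace.
#' @param aliases an [alias_table()].
#' @param target_namespace namespace to convert into.
#' @param source_namespace override for the model's declared namespace.
#' @return list with `map` (named list: reaction id -> character vector of
#'   target ids), `n_converted`, `n_unconverted`.
#' @export
convert_reaction_ids <- function(model, aliases, target_namespace,
                                 source_namespace = model$namespace) {
  if (is.na(source_namespace))
    stop("model declares no identifier namespace", call. = FALSE)
  if (!tolower(source_namespace) %in% unique(aliases$namespace))
    stop("unknown source namespace: ", source_namespace, call. = FALSE)
  rids <- reaction_ids(model)
  hubs <- hubs_of(aliases, source_namespace, rids)
  map <- lapply(hubs, function(h)
    if (!length(h)) character(0) else ids_in_ns(aliases, target_namespace, h))
  names(map) <- rids
  converted <- sum(lengths(map) > 0)
  list(map = map, n_converted = converted,
       n_unconverted = length(map) - converted)
}

#' TP/FP/FN set comparison container
#'
#' @param tp,fp,fn non-negative counts.
#' @param tp_items,fp_items,fn_items the partitioned id sets (optional;
#'   sizes must match the counts when given).
#' @export
set_comparison <- function(tp, fp, fn, tp_items = NULL, fp_items = NULL,
                           fn_items = NULL) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (!is.null(tp_items)) stopifnot(length(tp_items) == tp)
  if (!is.null(fp_items)) stopifnot(length(fp_items) == fp)
  if (!is.null(fn_items)) stopifnot(length(fn_items) == fn)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 tp_items = tp_items, fp_items = fp_items,
                 fn_items = fn_items),
            class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("<set_comparison> TP=", x$tp, " FP=", x$fp, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Compare draft and curated reaction sets through aliases
#'
#' Transport, exchange, sink and demand reactions are removed from both
#' sides before counting. A draft reaction is a true positive when at least
#' one of its aliases (ids converted into the curated namespace) is present
#' in the curated model, a false positive otherwise; curated reactions hit
#' by no draft reaction's alias set are the false negatives. A draft
#' reaction counts once regardless of how many curated ids it matches.
#'
#' @param draft,curated [metabolic_model()]s.
#' @param aliases an [alias_table()] covering both namespaces.
#' @param draft_ns,curated_ns identifier namespaces (default: the models'
#'   declared namespaces).
#' @return a [set_comparison()] with attribute `conversion` carrying the
#'   draft-side conversion statistics.
#' @export
compare_reactions <- function(draft, curated, aliases,
                              draft_ns = draft$namespace,
                              curated_ns = curated$namespace) {
  draft_internal <- reactions_of_kind(draft, "internal")
  curated_internal <- reactions_of_kind(curated, "internal")
  conv <- convert_reaction_ids(draft, aliases, curated_ns,
                               source_namespace = draft_ns)
  map <- conv$map[draft_internal]
  is_tp <- vapply(map, function(ids) any(ids %in% curated_internal), TRUE)
  hit <- unique(unlist(map[is_tp]))
  out <- set_comparison(
    tp = sum(is_tp), fp = sum(!is_tp),
    fn = sum(!curated_internal %in% hit),
    tp_items = draft_internal[is_tp],
    fp_items = draft_internal[!is_tp],
    fn_items = curated_internal[!curated_internal %in% hit])
  attr(out, "conversion") <- data.frame(
    n_converted = sum(lengths(map) > 0),
    n_unconverted = sum(lengths(map) == 0))
  out
}

#' Compare draft and curated gene sets by locus tag
#'
#' Locus tags are compared case-insensitively: true positives are tags
#' present in both models, false positives draft-only, false negatives
#' curated-only.
#'
#' @param draft,curated [metabolic_model()]s.
#' @return a [set_comparison()].
#' @export
compare_genes <- function(draft, curated) {
  d <- draft$genes$locus_tag
  c_ <- curated$genes$locus_tag
  dl <- tolower(d); cl <- tolower(c_)
  set_comparison(tp = sum(dl %in% cl), fp = sum(!dl %in% cl),
                 fn = sum(!cl %in% dl),
                 tp_items = d[dl %in% cl], fp_items = d[!dl %in% cl],
                 fn_items = c_[!cl %in% dl])
}

#' Benchmark metrics from a TP/FP/FN partition
#'
#' Computes the five comparison metrics: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, the TP/FP ratio, `F1 = 2 P R / (P + R)` and the Jaccard
#' distance `1 - TP/(FP+TP+FN)`. Conventions at the degenerate corners:
#' precision 0 when `TP+FP = 0`, recall 0 when `TP+FN = 0`, F1 0 when
#' `P+R = 0`; the ratio is `Inf` when `FP = 0` with `TP > 0` and 0 when
#' `TP = 0`.
#'
#' @param cmp a [set_comparison()].
#' @return a `metric_set`: list `precision, recall, ratio, f1,
#'   jaccard_distance`.
#' @export
compute_metrics <- function(cmp) {
  tp <- cmp$tp; fp <- cmp$fp; fn <- cmp$fn
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  ratio <- if (tp == 0) 0 else if (fp == 0) Inf else tp / fp
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  jd <- if (tp + fp + fn == 0) 0 else 1 - tp / (fp + tp + fn)
  structure(list(precision = precision, recall = recall, ratio = ratio,
                 f1 = f1, jaccard_distance = jd), class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  cat(sprintf("precision %.*f  recall %.*f  ratio %s  F1 %.*f  JD %.*f\n",
              digits, x$precision, digits, x$recall,
              if (is.infinite(x$ratio)) "inf" else sprintf("%.*f", digits, x$ratio),
              digits, x$f1, digits, x$jaccard_distance))
  invisible(x)
}

#' Benchmark one or more drafts against a curated model
#'
#' Produces one row per draft per entity type (reactions, genes) with the
#' TP/FP/FN counts, the five metrics and the draft-side identifier
#' conversion statistics, sorted by descending F1 within entity type.
#'
#' @param drafts named list of draft [metabolic_model()]s (at least one).
#' @param curated the curated reference model.
#' @param aliases an [alias_table()].
#' @param draft_ns optional character vector (recycled) overriding each
#'   draft's declared namespace.
#' @param curated_ns override for the curated model's namespace.
#' @return a data.frame benchmark report.
#' @export
benchmark_report <- function(drafts, curated, aliases, draft_ns = NULL,
                             curated_ns = curated$namespace) {
  if (!length(drafts)) stop("at least one draft model is required", call. = FALSE)
  if (is.null(names(drafts)) || any(!nzchar(names(drafts))))
    names(drafts) <- paste0("draft", seq_along(drafts))
  if (!is.null(draft_ns)) draft_ns <- rep_len(draft_ns, length(drafts))
  rows <- list()
  for (i in seq_along(drafts)) {
    d <- drafts[[i]]
    ns <- if (is.null(draft_ns)) d$namespace else draft_ns[i]
    rc <- compare_reactions(d, curated, aliases, draft_ns = ns,
                            curated_ns = curated_ns)
    gc_ <- compare_genes(d, curated)
    conv <- attr(rc, "conversion")
    for (ent in c("reactions", "genes")) {
      cmp <- if (ent == "reactions") rc else gc_
      m <- compute_metrics(cmp)
      rows[[length(rows) + 1L]] <- data.frame(
        draft = names(drafts)[i], entity = ent,
        tp = cmp$tp, fp = cmp$fp, fn = cmp$fn,
        precision = m$precision, recall = m$recall, ratio = m$ratio,
        f1 = m$f1, jaccard_distance = m$jaccard_distance,
        n_converted = if (ent == "reactions") conv$n_converted else NA_integer_,
        n_unconverted = if (ent == "reactions") conv$n_unconverted else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$entity, -out$f1, out$draft), , drop = FALSE]
  rownames(out) <- NULL
  out
}
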