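#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers: AND nodes encode
#' enzyme complexes (all subunits required), OR nodes encode isozymes (any
#' suffices). Rules are stored as expression trees; [parse_gpr()] and
#' [gpr_string()] convert between trees and the conventional
#' `"(g1 and g2) or g3"` text form.
#'
#' @param gene a gene identifier (leaf constructor).
#' @name gpr
NULL

#' @rdname gpr
#' @export
gpr_leaf <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(gene = gene), class = c("gpr_leaf", "gpr"))
}

gpr_node <- function(op, args) {
  stopifnot(op %in% c("and", "or"))
  if (!length(args)) stop("empty ", op, " node in GPR rule", call. = FALSE)
  args <- lapply(args, function(a) if (is.character(a)) gpr_leaf(a) else a)
  if (length(args) == 1L) return(args[[1L]])
  # flatten nested nodes of the same operator
  flat <- list()
  for (a in args) {
    if (inherits(a, "gpr_node") && a$op == op) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  structure(list(op = op, args = flat), class = c("gpr_node", "gpr"))
}

#' @rdname gpr
#' @param ... child rules or gene id strings.
#' @export
gpr_and <- function(...) gpr_node("and", list(...))

#' @rdname gpr
#' @export
gpr_or <- function(...) gpr_node("or", list(...))

#' Parse a GPR string into an expression tree
#'
#' Accepts the usual infix syntax with `and`/`or` (case-insensitive; `&`/`|`
#' also accepted) and parentheses.
#'
#' @param x a single string such as `"(g1 and g2) or g3"`.
#' @return a `gpr` tree, or `NULL` for an empty/whitespace string.
#' @export
parse_gpr <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) return(NULL)
  toks <- gpr_tokens(x)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  out <- gpr_parse_or(st)
  if (st$i <= length(st$toks)) {
    stop("trailing input in GPR rule near '", st$toks[[st$i]]$value, "'",
         call. = FALSE)
  }
  out
}

gpr_tokens <- function(x) {
  toks <- list()
  i <- 1L
  n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "open", value = "("); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "close", value = ")"); i <- i + 1L; next }
    if (ch == "&") { toks[[length(toks) + 1L]] <- list(type = "and", value = "&"); i <- i + 1L; next }
    if (ch == "|") { toks[[length(toks) + 1L]] <- list(type = "or", value = "|"); i <- i + 1L; next }
    m <- regmatches(substr(x, i, n), regexpr("^[^()&|[:space:]]+", substr(x, i, n)))
    if (!length(m)) stop("cannot tokenize GPR rule at position ", i, call. = FALSE)
    word <- m[[1L]]
    type <- switch(tolower(word), "and" = "and", "or" = "or", "word")
    toks[[length(toks) + 1L]] <- list(type = type, value = word)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]]$type else "eof"

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  gpr_node("and", args)
}

gpr_parse_atom <- function(st) {
  t <- gpr_peek(st)
  if (t == "open") {
    st$i <- st$i + 1L
    out <- gpr_parse_or(st)
    if (gpr_peek(st) != "close") stop("unbalanced parentheses in GPR rule", call. = FALSE)
    st$i <- st$i + 1L
    return(out)
  }
  if (t == "word") {
    tok <- st$toks[[st$i]]
    st$i <- st$i + 1L
    return(gpr_leaf(tok$value))
  }
  stop("malformed GPR rule: expected gene or '(' , got ",
       if (t == "eof") "end of input" else st$toks[[st$i]]$value, call. = FALSE)
}

#' Render a GPR tree as a string
#'
#' @param gpr a `gpr` tree or `NULL`.
#' @return a string; `""` for `NULL`.
#' @export
gpr_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (inherits(gpr, "gpr_leaf")) return(gpr$gene)
  parts <- vapply(gpr$args, function(a) {
    s <- gpr_string(a)
    if (inherits(a, "gpr_node") && a$op != gpr$op) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_string(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR tree
#' @param gpr a `gpr` tree or `NULL`.
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (inherits(gpr, "gpr_leaf")) return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR tree against a set of present genes
#' @param gpr a `gpr` tree or `NULL` (NULL evaluates FALSE).
#' @param present character vector of gene ids considered present/active.
#' @export
gpr_eval <- function(gpr, present) {
  if (is.null(gpr)) return(FALSE)
  if (inherits(gpr, "gpr_leaf")) return(gpr$gene %in% present)
  vals <- vapply(gpr$args, gpr_eval, logical(1), present = present)
  if (gpr$op == "and") all(vals) else any(vals)
}

# canonical form: argument lists sorted by their rendered string, recursively;
# used for structural equality where argument order is immaterial
gpr_canonical <- function(gpr) {
  if (is.null(gpr) || inherits(gpr, "gpr_leaf")) return(gpr)
  args <- lapply(gpr$args, gpr_canonical)
  keys <- vapply(args, gpr_string, "")
  structure(list(op = gpr$op, args = args[order(keys)]),
            class = c("gpr_node", "gpr"))
}

#' Structural equality of GPR trees (argument order ignored)
#' @param a,b `gpr` trees or `NULL`.
#' @export
gpr_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  identical(gpr_string(gpr_canonical(a)), gpr_string(gpr_canonical(b)))
}
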