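#' Reaction catalogues
#'
#' A reaction catalogue is a universal EC-to-reaction lookup (a desk-scale
#' stand-in for a KEGG/BiGG dump): compartment-free reaction records with
#' equation, reversibility, EC numbers and pathway. Stored as TSV with
#' columns `id, name, equation, reversible, ec, pathway, spontaneous`;
#' `equation` uses the textual form `"2 A + B <=> C"` (`=>` when
#' irreversible), `ec` is semicolon-separated.
#'
#' @name reaction_catalogue
NULL

#' Build a reaction catalogue from a data.frame
#'
#' @param entries data.frame with columns `id`, `name`, `equation`,
#'   `reversible` (logical), `ec` (list of character vectors or
#'   semicolon-joined strings), `pathway`, and optionally `spontaneous`
#'   (logical, default `FALSE`).
#' @return an object of class `reaction_catalogue`. Entry ids must be
#'   unique and every entry must carry at least one EC number or be flagged
#'   spontaneous.
#' @export
reaction_catalogue <- function(entries) {
  stopifnot(is.data.frame(entries))
  if (anyDuplicated(entries$id))
    stop("duplicated catalogue entry ids", call. = FALSE)
  if (!is.list(entries$ec)) entries$ec <- split_set(entries$ec)
  if (is.null(entries$spontaneous)) entries$spontaneous <- FALSE
  no_ec <- lengths(entries$ec) == 0 & !entries$spontaneous
  if (any(no_ec))
    stop("catalogue entries without EC and not spontaneous: ",
         paste(entries$id[no_ec], collapse = ", "), call. = FALSE)
  entries$stoichiometry <- lapply(entries$equation, parse_equation)
  structure(entries, class = c("reaction_catalogue", "data.frame"))
}

# "2 A + B <=> C" -> named coefficient vector (substrates negative)
parse_equation <- function(eq) {
  sides <- strsplit(eq, "<=>|=>", perl = TRUE)[[1L]]
  if (length(sides) != 2L)
    stop("cannot parse equation: ", eq, call. = FALSE)
  term <- function(side, sgn) {
    parts <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    out <- numeric(0)
    for (p in parts) {
      m <- regmatches(p, regexec("^([0-9.]+\\s+)?(\\S+)$", p))[[1L]]
      if (length(m) != 3L) stop("cannot parse equation term: ", p, call. = FALSE)
      coef <- if (nzchar(trimws(m[2L]))) as.numeric(trimws(m[2L])) else 1
      out[m[3L]] <- (if (m[3L] %in% names(out)) out[[m[3L]]] else 0) + sgn * coef
    }
    out
  }
  lhs <- term(sides[1L], -1)
  rhs <- term(sides[2L], +1)
  both <- intersect(names(lhs), names(rhs))
  s <- c(lhs[setdiff(names(lhs), both)], rhs[setdiff(names(rhs), both)])
  for (b in both) s[b] <- lhs[[b]] + rhs[[b]]
  s[s != 0]
}

format_equation <- function(stoich, reversible) {
  fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste(abs(v), names(v))), collapse = " + ")
  paste(fmt(stoich[stoich < 0]), if (reversible) "<=>" else "=>",
        fmt(stoich[stoich > 0]))
}

#' Read / write a reaction catalogue TSV
#' @param path TSV file in the documented schema.
#' @export
read_catalogue <- function(path) {
  df <- read_tsv_strict(path, required = c("id", "name", "equation",
                                           "reversible", "ec", "pathway"))
  df$reversible <- as.logical(df$reversible)
  if (!is.null(df$spontaneous)) df$spontaneous <- as.logical(df$spontaneous)
  reaction_catalogue(df)
}

#' @rdname read_catalogue
#' @param catalogue a [reaction_catalogue()].
#' @export
write_catalogue <- function(catalogue, path) {
  df <- as.data.frame(catalogue)
  df$ec <- join_set(df$ec)
  df$stoichiometry <- NULL
  write_tsv(df, path)
}
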