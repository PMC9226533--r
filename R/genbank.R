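#' Read CDS features from a GenBank flat file
#'
#' Parses the FEATURES table and ORIGIN sequence of a GenBank flat file and
#' returns one record per CDS feature carrying a `locus_tag`. The protein
#' translation is taken from the `/translation` qualifier when present and
#' otherwise computed with the standard genetic code (terminal stop dropped).
#' CDS whose length is not a multiple of three (or whose location is marked
#' partial with `<`/`>`) are flagged.
#'
#' Locations of the forms `start..end`, `complement(start..end)` and
#' `join(...)` over such spans are supported.
#'
#' @param path a GenBank flat file.
#' @return a data.frame with columns `locus_tag`, `cds` (nucleotide
#'   sequence), `protein`, `partial` (logical), `product`. A file without
#'   CDS features yields zero rows with a warning.
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  empty <- data.frame(locus_tag = character(0), cds = character(0),
                      protein = character(0), partial = logical(0),
                      product = character(0), stringsAsFactors = FALSE)

  origin_at <- grep("^ORIGIN", lines)
  genome <- ""
  if (length(origin_at)) {
    end_at <- grep("^//", lines)
    end_at <- end_at[end_at > origin_at[1L]][1L]
    if (is.na(end_at)) end_at <- length(lines) + 1L
    seq_lines <- lines[seq(origin_at[1L] + 1L, end_at - 1L)]
    genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  feat_at <- grep("^FEATURES", lines)
  if (!length(feat_at)) {
    warning("no FEATURES table in ", basename(path), call. = FALSE)
    return(empty)
  }
  stop_at <- if (length(origin_at)) origin_at[1L] else length(lines) + 1L
  flines <- lines[seq(feat_at[1L] + 1L, stop_at - 1L)]

  # split the feature table into (key, location+qualifier) blocks:
  # a new feature starts with a key in columns 6-20
  starts <- grep("^ {5}\\S", flines)
  if (!length(starts)) {
    warning("no CDS features in ", basename(path), call. = FALSE)
    return(empty)
  }
  blocks <- Map(function(s, e) flines[s:e], starts,
                c(starts[-1L] - 1L, length(flines)))
  keys <- sub("^ {5}(\\S+).*$", "\\1", flines[starts])
  cds_blocks <- blocks[keys == "CDS"]
  if (!length(cds_blocks)) {
    warning("no CDS features in ", basename(path), call. = FALSE)
    return(empty)
  }

  recs <- lapply(cds_blocks, parse_cds_block, genome = genome)
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) {
    warning("no CDS feature carries a locus_tag in ", basename(path), call. = FALSE)
    return(empty)
  }
  do.call(rbind, recs)
}

parse_cds_block <- function(block, genome) {
  # location: continuation lines before the first qualifier
  qual_at <- grep("^ {21}/", block)
  loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
  loc <- paste(trimws(sub("^ {5}CDS", "", block[1L])),
               paste(trimws(block[seq_len(loc_end)[-1L]]), collapse = ""),
               sep = "")
  loc <- gsub("\\s", "", loc)

  quals <- parse_qualifiers(block[seq.int(loc_end + 1L, length.out = length(block) - loc_end)])
  tag <- quals[["locus_tag"]]
  if (is.null(tag)) return(NULL)

  partial_loc <- grepl("[<>]", loc)
  loc_clean <- gsub("[<>]", "", loc)
  spans <- parse_location(loc_clean)

  cds <- ""
  if (nzchar(genome) && !is.null(spans)) {
    pieces <- vapply(spans$spans, function(sp)
      substr(genome, sp[1L], sp[2L]), "")
    cds <- paste(pieces, collapse = "")
    if (spans$complement) cds <- revcomp(cds)
  }
  partial <- partial_loc || (nchar(cds) %% 3L != 0L)

  protein <- quals[["translation"]]
  if (is.null(protein)) protein <- translate_cds(cds)
  data.frame(locus_tag = tag, cds = cds, protein = protein,
             partial = partial,
             product = quals[["product"]] %||% NA_character_,
             stringsAsFactors = FALSE)
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  # join continuation lines onto their qualifier
  idx <- cumsum(grepl("^ {21}/", lines))
  lines <- lines[idx > 0]
  idx <- idx[idx > 0]
  quals <- list()
  for (q in split(lines, idx)) {
    txt <- paste(trimws(q), collapse = " ")
    m <- regmatches(txt, regexec("^/([A-Za-z_]+)(=(.*))?$", txt))[[1L]]
    if (length(m) < 2L) next
    val <- if (length(m) >= 4L && nzchar(m[4L])) gsub('^"|"$', "", m[4L]) else TRUE
    if (identical(m[2L], "translation") && is.character(val))
      val <- gsub(" ", "", val)
    quals[[m[2L]]] <- val
  }
  quals
}

parse_location <- function(loc) {
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1L]]
    if (length(m) != 3L) return(NULL)
    as.integer(m[2:3])
  })
  if (any(vapply(spans, is.null, TRUE))) return(NULL)
  list(spans = spans, complement = complement)
}

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  if (n < 3L) return("")
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                          if.fuzzy.codon = "X")))
  sub("\\*$", "", aa)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (nucleotide or protein).
#' @return named character vector of sequences; names are the first word of
#'   each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  out <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    for (j in seq(1L, nchar(s), by = width))
      cat(substr(s, j, min(j + width - 1L, nchar(s))), "\n", sep = "", file = con)
  }
  invisible(path)
}
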