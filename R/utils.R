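#' @keywords internal
"_PACKAGE"

# number formatting that survives a write/read round trip bit-exactly
num_chr <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

squish <- function(x) gsub("\\s+", " ", trimws(x))

# semicolon-joined set columns used across the TSV interfaces
join_set <- function(x) vapply(x, function(v) paste(v, collapse = ";"), "")
split_set <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

is_ec <- function(x) grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9a-zA-Z-]+$", x)

read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop("missing mandatory column(s) in ", basename(path), ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
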