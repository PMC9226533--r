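#' Reconstruction workspaces
#'
#' A workspace bundles a model, its annotation table and the run
#' configuration into a plain directory: SBML + TSV + a YAML manifest
#' recording the tool version and random seed. Directories are diffable,
#' cloneable by copying, and survive semantic round trips through
#' [save_workspace()] / [load_workspace()].
#'
#' @param model a [metabolic_model()].
#' @param annotations an annotation table or `NULL`.
#' @param config named list of configuration values.
#' @param seed the integer seed the workspace's artifacts were generated
#'   with, or `NA`.
#' @return an object of class `workspace`.
#' @export
workspace <- function(model, annotations = NULL, config = list(),
                      seed = NA_integer_) {
  structure(list(model = model, annotations = annotations, config = config,
                 seed = seed), class = "workspace")
}

#' @export
print.workspace <- function(x, ...) {
  cat("<workspace> model:", x$model$id,
      " annotations:", if (is.null(x$annotations)) 0 else nrow(x$annotations),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Save a workspace to a directory
#'
#' @param ws a [workspace()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_workspace <- function(ws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(model = "model.xml")
  write_sbml(ws$model, file.path(dir, "model.xml"))
  if (!is.null(ws$annotations)) {
    files$annotations <- "annotations.tsv"
    write_annotation_table(ws$annotations, file.path(dir, "annotations.tsv"))
  }
  if (length(ws$config)) {
    files$config <- "config.yaml"
    yaml::write_yaml(ws$config, file.path(dir, "config.yaml"))
  }
  manifest <- list(tool = "gemdraft",
                   version = as.character(utils::packageVersion("gemdraft")),
                   seed = if (is.na(ws$seed)) NULL else as.integer(ws$seed),
                   files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a workspace from a directory
#'
#' @param dir a directory written by [save_workspace()]. A directory
#'   without a manifest is refused; a manifest written by a different tool
#'   version is loaded best-effort with a warning.
#' @return a [workspace()].
#' @export
load_workspace <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath))
    stop("missing manifest: ", dir,
         " is not a workspace (no manifest.yaml)", call. = FALSE)
  manifest <- yaml::read_yaml(mpath)
  here <- as.character(utils::packageVersion("gemdraft"))
  if (!identical(manifest$version, here))
    warning("workspace written by version ", manifest$version %||% "<unknown>",
            ", loading best-effort with version ", here, call. = FALSE)
  model <- read_sbml(file.path(dir, manifest$files$model %||% "model.xml"))
  ann <- NULL
  if (!is.null(manifest$files$annotations))
    ann <- read_annotation_table(file.path(dir, manifest$files$annotations))
  config <- list()
  if (!is.null(manifest$files$config))
    config <- yaml::read_yaml(file.path(dir, manifest$files$config))
  workspace(model, ann, config, seed = manifest$seed %||% NA_integer_)
}

#' Clone a workspace directory
#'
#' @param src,dst source and destination directories; the clone is an
#'   independent copy.
#' @export
clone_workspace <- function(src, dst) {
  if (!file.exists(file.path(src, "manifest.yaml")))
    stop("missing manifest: ", src, " is not a workspace", call. = FALSE)
  dir.create(dst, showWarnings = FALSE, recursive = TRUE)
  ok <- file.copy(list.files(src, full.names = TRUE), dst, recursive = TRUE)
  if (!all(ok)) stop("failed to copy workspace files", call. = FALSE)
  invisible(dst)
}
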