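# one shared toy world per test run, generated lazily
.toy_cache <- new.env(parent = emptyenv())

get_toy_world <- function(seed = 1L) {
  key <- paste0("w", seed)
  if (is.null(.toy_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("toyworld_", seed))
    manifest <- make_toy_world(dir, seed = seed)
    .toy_cache[[key]] <- list(dir = dir, manifest = manifest)
  }
  .toy_cache[[key]]
}

# tiny deterministic hand-built model used by several tests
chain_model <- function() {
  metabolic_model("chain", "c",
    metabolites = data.frame(id = c("A_c", "B_c", "C_c"),
                             name = c("A", "B", "C"), compartment = "c",
                             stringsAsFactors = FALSE),
    reactions = list(reaction("r1", c(A_c = -1, B_c = 1)),
                     reaction("r2", c(B_c = -1, C_c = 1))))
}
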