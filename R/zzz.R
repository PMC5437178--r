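# package-local cache for the JSON parameter defaults
.csfq_env <- new.env(parent = emptyenv())

.csfq_defaults <- function(which = c("reibergram", "molecules")) {
  which <- match.arg(which)
  key <- paste0("defaults_", which)
  if (!exists(key, envir = .csfq_env)) {
    file <- switch(which,
                   reibergram = "reibergram_params.json",
                   molecules = "molecules.json")
    path <- system.file("extdata", file, package = "csfquotient")
    if (!nzchar(path)) stop("packaged defaults not found: ", file)
    assign(key, jsonlite::fromJSON(path, simplifyVector = FALSE),
           envir = .csfq_env)
  }
  get(key, envir = .csfq_env)
}
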