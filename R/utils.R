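`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible 31-bit substream seed from a master seed and an index.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 2654435761 + as.double(index) * 40503) %% 2147483647
}

#' Read a pipeline configuration file
#'
#' Configuration is a single YAML or JSON document with optional sections
#' `observer`, `acuity`, `ranked_filter`, `leia`, `pipeline`, `cohort` and
#' `stats`. Any key left out falls back to the package default documented on
#' the function that consumes it.
#'
#' @param path path to a `.yaml`, `.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '.", ext, "' (use YAML or JSON)")
  }
}
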