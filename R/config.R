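## Run metadata: every runner's resolved parameters (including parse and
## sign-convention choices) can be serialized next to its outputs so a
## run is re-creatable from the output directory alone.

#' Assemble run metadata
#'
#' @param ... Named resolved parameters to record.
#' @param seed Seed used for any randomness (or NA).
#' @param dt Integration step (ms) where applicable.
#' @return A list with package version, timestamp-free provenance fields,
#'   and the supplied parameters.
#' @export
run_metadata <- function(..., seed = NA_integer_, dt = NA_real_) {
  list(package = "kv3net",
       version = as.character(utils::packageVersion("kv3net")),
       seed = seed, dt = dt,
       shift_convention = "delta_shift = change in half-activation voltage (negative = hyperpolarizing); internal vshift = -delta_shift",
       mtau_parse_default = "gaussian",
       params = list(...))
}

#' Write run metadata as JSON
#'
#' @param meta A list from [run_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
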