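# Polynomial rolling hash mod 2^31-1 over the JSON serialization; cheap
# content hash for provenance records (no cryptographic requirement).
.contentHash <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Content hash of a simulation configuration
#'
#' A stable hash of the JSON serialization of a [SimConfig], used in
#' provenance records so a run can be matched to the exact configuration
#' that produced it.
#'
#' @param config a [SimConfig].
#' @return an 8-hex-digit character scalar.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeSimConfig(config, tmp)
  .contentHash(paste(readLines(tmp, warn = FALSE), collapse = "\n"))
}
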