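# Rolling polynomial hash of a serialized R object (provenance stamp, not
# cryptographic).
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  b <- as.integer(raw)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
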