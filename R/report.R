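#' Write a results table with run metadata
#'
#' Writes a CSV preceded by comment lines carrying the package version
#' and a hash of the run configuration, so every output table is
#' traceable to the exact parameters that produced it.
#'
#' @param tab data.frame.
#' @param path output CSV path.
#' @param config list of run parameters (serialized to JSON for the
#'   hash and stored alongside as `<path>.config.json`).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path, config = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# periplaque version: ",
           as.character(utils::packageVersion("periplaque"))),
    paste0("# config sha: ", config_hash(config))), con)
  write.csv(tab, con, row.names = FALSE)
  writeLines(cfg_json, paste0(path, ".config.json"))
  invisible(path)
}

#' Read a table written by [write_result_table()]
#'
#' @param path CSV path.
#' @return data.frame (metadata comment lines skipped).
#' @export
read_result_table <- function(path) {
  read.csv(path, comment.char = "#")
}

# Stable content hash of a configuration list (order-normalized JSON,
# summed byte rolling hash; no external digest dependency).
config_hash <- function(config) {
  if (length(config) > 0 && !is.null(names(config)))
    config <- config[order(names(config))]
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
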