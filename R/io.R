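#' Write a population to CSV with a provenance header
#'
#' One row per neuron, columns in model channel order, full double precision
#' (round-trip exact). Provenance is serialized into commented header lines
#' (`# key: json`).
#'
#' @param pop a `neuron_population`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_population <- function(pop, path) {
  pv <- attr(pop, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# model: ", attr(pop, "model")), con)
  if (length(pv))
    writeLines(paste0("# provenance: ",
                      jsonlite::toJSON(pv, auto_unbox = TRUE, digits = NA,
                                       null = "null")), con)
  df <- as.data.frame(unclass(pop))
  # full repr precision
  for (j in seq_along(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population written by [write_population()]
#'
#' @param path CSV file with provenance header
#' @param model optional `cb_model`; default: rebuilt from the header
#' @return a `neuron_population`
#' @export
read_population <- function(path, model = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- val
  }
  if (is.null(model)) {
    if (is.null(meta$model)) stop("population file lacks a '# model:' header")
    model <- build_model(meta$model)
  }
  df <- utils::read.csv(textConnection(lines[-hdr]))
  missing_cols <- setdiff(model$analysis_channels, colnames(df))
  if (length(missing_cols))
    stop("population file lacks conductance column(s): ",
         paste(missing_cols, collapse = ", "))
  pv <- if (!is.null(meta$provenance))
    jsonlite::fromJSON(meta$provenance, simplifyVector = TRUE) else list()
  new_population(model, as.matrix(df[, model$analysis_channels]), pv)
}

#' Write a voltage trace as delimited text
#' @param trace a `voltage_trace`
#' @param path output file
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
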