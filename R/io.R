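#' Write a spike raster to TSV
#'
#' Tab-separated columns `trial`, `neuron_id`, `time_ms` preceded by
#' `#`-prefixed metadata header lines (experiment id, seed, dt,
#' duration). Round-trips losslessly through [read_raster()].
#'
#' @param records data.frame `(trial, neuron, time)`.
#' @param path output file.
#' @param meta named list of metadata scalars written into the header.
#' @return `path`, invisibly.
#' @export
write_raster <- function(records, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  writeLines("trial\tneuron_id\ttime_ms", con)
  if (nrow(records))
    utils::write.table(
      data.frame(records$trial, records$neuron,
                 formatC(records$time, format = "g", digits = 17)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path raster file.
#' @return data.frame `(trial, neuron, time)` with attribute `meta`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  data_lines <- if (length(hdr)) lines[-hdr] else lines
  data_lines <- data_lines[-1]  # column header row
  body <- if (length(data_lines))
    utils::read.table(text = data_lines, header = FALSE, sep = "\t",
                      col.names = c("trial", "neuron", "time"))
  else data.frame(trial = integer(), neuron = integer(), time = numeric())
  attr(body, "meta") <- meta
  body
}

#' Read a flat key-value experiment config
#'
#' Plain-text `key = value` pairs with dotted section keys
#' (`architecture.*`, `plasticity.*`, `stimulus.*`, `schedule.*`,
#' `integration.dt_ms`, `seed`); `#` comments and blank lines ignored.
#' Values are parsed as numeric when possible, `true`/`false` as
#' logical, and comma-separated values as vectors.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln)) stop("bad config line (no '='): ", ln)
    k <- trimws(sub("=.*$", "", ln))
    v <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[k]] <- if (!any(is.na(num))) num
                else if (all(tolower(parts) %in% c("true", "false")))
                  tolower(parts) == "true"
                else if (length(parts) > 1) parts else v
  }
  out
}

#' Write a config snapshot
#'
#' @param config named list of scalars/vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(format(config[[k]], digits = 17),
                                collapse = ", ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
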