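# One configuration dialect (key = value lines, '#' comments) shared by
# the extract / analyse / simulate entry points.

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored;
#' values are kept as strings and coerced by the consumers.
#'
#' @param path file path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0))
    stop(sprintf("config line without '=': '%s'", lines[eq < 0][1]))
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substr(lines, eq + 1, nchar(lines)))
  if (any(!nzchar(keys))) stop("config line with empty key")
  if (anyDuplicated(keys))
    stop("duplicate config key: ", keys[duplicated(keys)][1])
  stats::setNames(as.list(vals), keys)
}

#' @rdname read_config
#' @param config named list to serialise.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) paste(v, collapse = ","),
                            character(1))),
             path)
  invisible(path)
}

# typed accessors --------------------------------------------------------

cfg_chr <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) {
    if (is.null(default)) stop("missing required config key: ", key)
    default
  } else cfg[[key]]
}

cfg_num <- function(cfg, key, default = NULL) {
  v <- cfg_chr(cfg, key, if (is.null(default)) NULL else as.character(default))
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) stop(sprintf("config key '%s' is not numeric: '%s'",
                               key, v))
  out
}

cfg_flag <- function(cfg, key, default = FALSE) {
  v <- tolower(cfg_chr(cfg, key, as.character(default)))
  if (!v %in% c("true", "false", "1", "0", "yes", "no"))
    stop(sprintf("config key '%s' is not a flag: '%s'", key, v))
  v %in% c("true", "1", "yes")
}

cfg_list <- function(cfg, key, default = character()) {
  v <- cfg_chr(cfg, key, paste(default, collapse = ","))
  v <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
  v[nzchar(v)]
}
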