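# Internal helpers: issue construction, classed conditions, IO plumbing.

fvcfError <- function(class, message, ...) {
  stop(structure(class = c(class, "fvcf_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

# One issue row; severity resolved from the rule catalogue.
newIssue <- function(rule_id, message, line = NA_integer_,
                     observed = NA_character_) {
  sev <- .ruleSeverity(rule_id)
  data.frame(rule_id = rule_id, severity = sev,
             line = as.integer(line), message = message,
             observed = as.character(observed), stringsAsFactors = FALSE)
}

bindIssues <- function(...) {
  xs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(xs)) return(emptyIssues())
  do.call(rbind, xs)
}

setIssueLine <- function(issues, line) {
  if (nrow(issues)) issues$line <- as.integer(line)
  issues
}

orderIssues <- function(issues) {
  if (!nrow(issues)) return(issues)
  o <- order(is.na(issues$line), issues$line, issues$rule_id,
             issues$message)
  out <- issues[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Open a text connection to a possibly gzip-compressed file.
# Gzip is recognized by its leading magic bytes 0x1f 0x8b (bgzf included).
openTextSource <- function(path) {
  if (!file.exists(path))
    fvcfError("fvcf_io", sprintf("cannot open '%s': no such file", path))
  magic <- readBin(path, what = "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) &&
      magic[2] == as.raw(0x8b)) gzfile(path, open = "rt")
  else file(path, open = "rt")
}

# Accept either a path or literal text (single string with newlines or a
# character vector of lines); return a read-mode connection.
asLineSource <- function(x, what = "input") {
  if (!is.character(x) || !length(x))
    fvcfError("fvcf_io", sprintf("%s must be a path or text", what))
  looksLikeText <- length(x) > 1L || grepl("\n", x, fixed = TRUE) ||
    startsWith(x, ">") || startsWith(x, "#")
  if (!looksLikeText) return(openTextSource(x))
  textConnection(splitLines(x))
}

splitLines <- function(x) {
  txt <- paste(x, collapse = "\n")
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

# Strip one pair of surrounding double quotes, if present.
unquoteValue <- function(x) {
  ifelse(nchar(x) >= 2 & startsWith(x, "\"") & endsWith(x, "\""),
         substr(x, 2, nchar(x) - 1L), x)
}

escapeQuoted <- function(x) {
  gsub("\"", "\\\"", gsub("\\", "\\\\", x, fixed = TRUE), fixed = TRUE)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

# MD5 digest of a normalized sequence accumulated in chunks: residues are
# uppercased and whitespace removed before they reach the writer, so the
# digest never sees line structure. Backed by a scratch file so the full
# sequence is never held in memory.
sequenceDigester <- function() {
  tmp <- tempfile("fvcf-md5-")
  con <- NULL
  list(
    reset = function() {
      if (!is.null(con)) close(con)
      con <<- file(tmp, open = "wb")
    },
    add = function(chunk) {
      writeBin(charToRaw(chunk), con)
    },
    digest = function() {
      close(con)
      con <<- NULL
      unname(as.character(tools::md5sum(tmp)))
    },
    cleanup = function() {
      if (!is.null(con)) close(con)
      unlink(tmp)
    }
  )
}

normalizeResidues <- function(x) toupper(gsub("[[:space:]]", "", x))

writeTextFile <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
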