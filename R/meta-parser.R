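# Tokenizer / serializer for VCF meta-information with byte-identical
# round-trips: attribute order, the verbatim key text and the quoting of
# each value are preserved, and the only escapes honoured inside quotes
# are \" and \\ (the VCF 4.3 convention).

.CANONICAL_KEYS <- c("fileformat", "fileDate", "bioinformatics_source",
                     "reference_ac", "reference_url", "contig", "SAMPLE",
                     "reference")

# Split the inner text of a "<...>" value into (key, value, quoted) rows.
# Returns list(attributes=<data.frame>, issues=<data.frame>); attributes
# is NULL when tokenization failed and the line must fall back to an
# unstructured representation.
tokenizeAttributes <- function(inner, line = NA_integer_) {
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  n <- length(chars)
  keys <- character(); vals <- character(); quoted <- logical()
  issues <- emptyIssues()
  i <- 1L
  repeat {
    if (i > n) break
    # -- key: verbatim up to '='
    j <- i
    while (j <= n && chars[j] != "=" && chars[j] != ",") j <- j + 1L
    if (j > n || chars[j] == ",") {
      issues <- bindIssues(issues, newIssue("FVCF-PARSE-006",
        "attribute lacks '='", line = line,
        observed = paste(chars[i:min(j, n)], collapse = "")))
      return(list(attributes = NULL, issues = issues))
    }
    key <- if (j > i) paste(chars[i:(j - 1L)], collapse = "") else ""
    if (key == "")
      issues <- bindIssues(issues, newIssue("FVCF-PARSE-003",
        "empty attribute key", line = line))
    i <- j + 1L
    # -- value: quoted or bare
    if (i <= n && chars[i] == "\"") {
      buf <- character(); i <- i + 1L; closed <- FALSE
      while (i <= n) {
        ch <- chars[i]
        if (ch == "\\" && i < n && chars[i + 1L] %in% c("\"", "\\")) {
          buf <- c(buf, chars[i + 1L]); i <- i + 2L
        } else if (ch == "\"") {
          closed <- TRUE; i <- i + 1L; break
        } else {
          buf <- c(buf, ch); i <- i + 1L
        }
      }
      if (!closed) {
        issues <- bindIssues(issues, newIssue("FVCF-PARSE-001",
          "unterminated quote in structured value", line = line,
          observed = key))
        return(list(attributes = NULL, issues = issues))
      }
      if (i <= n && chars[i] != ",") {
        issues <- bindIssues(issues, newIssue("FVCF-PARSE-007",
          "text after closing quote", line = line, observed = key))
        return(list(attributes = NULL, issues = issues))
      }
      keys <- c(keys, key); vals <- c(vals, paste(buf, collapse = ""))
      quoted <- c(quoted, TRUE)
      i <- i + 1L                      # skip ',' (or move past end)
      if (i == n + 2L) break
    } else {
      j <- i
      while (j <= n && chars[j] != ",") j <- j + 1L
      keys <- c(keys, key)
      vals <- c(vals, if (j > i) paste(chars[i:(j - 1L)], collapse = "") else "")
      quoted <- c(quoted, FALSE)
      i <- j + 1L
    }
  }
  dups <- unique(keys[duplicated(keys)])
  for (d in dups)
    issues <- bindIssues(issues, newIssue("FVCF-STRUCT-002",
      sprintf("attribute key '%s' appears %d times", d, sum(keys == d)),
      line = line, observed = d))
  list(attributes = data.frame(key = keys, value = vals, quoted = quoted,
                               stringsAsFactors = FALSE),
       issues = issues)
}

#' Parse one meta-information line
#'
#' Parses a `##`-prefixed line into either a [MetaLine-class]
#' (unstructured `##key=value`) or a [StructuredMeta-class]
#' (`##TYPE=<k=v,...>`). The structured form is chosen exactly when the
#' value opens with `<` and closes with `>`. Attribute splitting is
#' quote-aware: commas and `=` inside double-quoted values do not split,
#' quotes are stripped into the value with the quoting recorded, and the
#' escapes `\"` and `\\` are honoured. Malformations (unterminated quote
#' or angle bracket, empty key, missing `=`) are reported as parse issues
#' on the returned object, never as R errors.
#'
#' @param raw The line text, starting with `##`.
#' @param lineNumber Its 1-based line number in the source.
#' @return A [MetaLine-class] or [StructuredMeta-class]; inspect
#'   [parseIssues()] for problems.
#' @examples
#' m <- parseMetaLine("##fileformat=VCFv4.3", 1L)
#' s <- parseMetaLine(
#'   "##contig=<ID=chr1H,length=522466905,assembly=GCA_902498975.1,md5=8d21a35cc68340ecf40e2a8dec9428fa,species=NCBITaxon:4513>",
#'   2L)
#' s@attributes
#' @export
parseMetaLine <- function(raw, lineNumber = NA_integer_) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!startsWith(raw, "##"))
    fvcfError("fvcf_not_meta", "meta-information lines start with '##'")
  lineNumber <- as.integer(lineNumber)
  body <- substring(raw, 3L)
  eq <- regexpr("=", body, fixed = TRUE)
  if (eq < 0L) {
    return(new("MetaLine", lineNumber = lineNumber, raw = raw,
               key = body, value = NA_character_,
               issues = newIssue("FVCF-PARSE-006",
                                 "meta-information line lacks '='",
                                 line = lineNumber, observed = raw)))
  }
  key <- substr(body, 1L, eq - 1L)
  val <- substring(body, eq + 1L)
  issues <- emptyIssues()
  if (key == "")
    issues <- newIssue("FVCF-PARSE-003", "empty meta-information key",
                       line = lineNumber, observed = raw)
  if (startsWith(val, "<")) {
    if (!endsWith(val, ">")) {
      issues <- bindIssues(issues, newIssue("FVCF-PARSE-002",
        "structured value does not close with '>'", line = lineNumber,
        observed = key))
      return(new("MetaLine", lineNumber = lineNumber, raw = raw,
                 key = key, value = val, issues = issues))
    }
    inner <- substr(val, 2L, nchar(val) - 1L)
    tok <- tokenizeAttributes(inner, line = lineNumber)
    issues <- bindIssues(issues, tok$issues)
    if (is.null(tok$attributes))
      return(new("MetaLine", lineNumber = lineNumber, raw = raw,
                 key = key, value = val, issues = issues))
    if (!"ID" %in% tok$attributes$key)
      issues <- bindIssues(issues, newIssue("FVCF-STRUCT-001",
        sprintf("structured line '%s' has no ID attribute", key),
        line = lineNumber, observed = key))
    return(new("StructuredMeta", lineNumber = lineNumber, raw = raw,
               recordType = key, attributes = tok$attributes,
               issues = issues))
  }
  new("MetaLine", lineNumber = lineNumber, raw = raw, key = key,
      value = val, issues = issues)
}

#' Serialize a meta-information entry
#'
#' Inverse of [parseMetaLine()]: entries that came from the parser
#' re-serialize byte-for-byte (attribute order, verbatim keys, and the
#' original quoting are all preserved; `\"`/`\\` are re-escaped). Newly
#' constructed structured entries are emitted with no spaces around `=`,
#' comma separators, and quoting applied to any value containing a comma,
#' `=`, `<`, `>`, a space, or a quote.
#'
#' @param entry A [MetaLine-class] or [StructuredMeta-class].
#' @return The single-line text.
#' @examples
#' serializeMeta(parseMetaLine("##fileDate=20120921", 1L))
#' @export
setGeneric("serializeMeta", function(entry) standardGeneric("serializeMeta"))

#' @rdname serializeMeta
setMethod("serializeMeta", "MetaLine", function(entry) {
  if (is.na(entry@value)) return(entry@raw)
  paste0("##", entry@key, "=", entry@value)
})

#' @rdname serializeMeta
setMethod("serializeMeta", "StructuredMeta", function(entry) {
  a <- entry@attributes
  parts <- vapply(seq_len(nrow(a)), function(i) {
    v <- if (a$quoted[i]) paste0("\"", escapeQuoted(a$value[i]), "\"")
         else a$value[i]
    paste0(a$key[i], "=", v)
  }, character(1))
  paste0("##", entry@recordType, "=<", paste(parts, collapse = ","), ">")
})

# Decide quoting for constructed attributes.
needsQuoting <- function(value) {
  grepl("[,=<> \"]", value)
}

#' Construct a structured meta entry
#'
#' Convenience constructor for new `##TYPE=<...>` lines. Quoting is
#' decided per value unless `quoted` is supplied.
#'
#' @param recordType Record type text (e.g. `"contig"`, `"SAMPLE"`).
#' @param keys,values Parallel character vectors of attributes.
#' @param quoted Optional logical vector; default quotes any value
#'   containing a comma, `=`, `<`, `>`, space or quote.
#' @param lineNumber Optional source line number.
#' @return A [StructuredMeta-class].
#' @export
structuredMeta <- function(recordType, keys, values, quoted = NULL,
                           lineNumber = NA_integer_) {
  stopifnot(length(keys) == length(values))
  if (is.null(quoted)) quoted <- vapply(values, needsQuoting, logical(1))
  new("StructuredMeta", lineNumber = as.integer(lineNumber),
      raw = character(), recordType = recordType,
      attributes = data.frame(key = as.character(keys),
                              value = as.character(values),
                              quoted = as.logical(quoted),
                              stringsAsFactors = FALSE))
}

#' Parse the column header line
#'
#' Splits the single-`#` header line on tabs: the first nine tokens are
#' the fixed columns (`#CHROM`, `POS`, `ID`, `REF`, `ALT`, `QUAL`,
#' `FILTER`, `INFO`, `FORMAT`; fewer when truncated), the remainder the
#' sample columns. Deviations from the mandatory headings are left to the
#' rule engine; nothing is silently fixed.
#'
#' @param raw The header line text, starting with a single `#`.
#' @param lineNumber Its 1-based line number.
#' @return A [HeaderLine-class].
#' @export
parseHeaderLine <- function(raw, lineNumber = NA_integer_) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (startsWith(raw, "##"))
    fvcfError("fvcf_not_header_line",
              "'##' lines are meta-information, not the header line")
  if (!startsWith(raw, "#"))
    fvcfError("fvcf_not_header_line", "header line must start with '#'")
  toks <- strsplit(raw, "\t", fixed = TRUE)[[1]]
  nfix <- min(length(toks), 9L)
  new("HeaderLine", lineNumber = as.integer(lineNumber),
      fixed = toks[seq_len(nfix)],
      samples = if (length(toks) > 9L) toks[10:length(toks)] else character())
}

.MANDATORY_COLUMNS <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT")

#' Stream the (CHROM, POS) core of every data line
#'
#' Reads a VCF (plain or gzip, detected by magic bytes), skips the header
#' section, and extracts per data line only the chromosome, the position
#' and the field count. Reading is chunked: with a `callback` the file is
#' never materialized and memory use is independent of its length.
#'
#' @param source Path to a VCF, or its text.
#' @param callback Optional `function(cores)` invoked per chunk with a
#'   data frame (`line`, `chrom`, `pos`, `n_fields`). When supplied, cores
#'   are not accumulated.
#' @param maxLines Bound on the number of data lines examined
#'   (default unlimited).
#' @param chunkSize Lines per read (tuning only).
#' @return With no callback, `list(cores=<data.frame>, issues=<data.frame>,
#'   nLines=<int>)`; with a callback the `cores` element is empty.
#'   Malformed lines (fewer than two fields, non-integer POS) yield
#'   issues, never cores, and never stop the stream.
#' @export
streamDataCores <- function(source, callback = NULL, maxLines = Inf,
                            chunkSize = 5000L) {
  con <- asLineSource(source, "VCF source")
  on.exit(close(con))
  issues <- emptyIssues()
  coresList <- list()
  nData <- 0L
  inHeader <- TRUE
  lineNo <- 0L
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (!length(lines)) break
    lns <- lineNo + seq_along(lines)
    lineNo <- lineNo + length(lines)
    if (inHeader) {
      isHead <- startsWith(lines, "#")
      firstData <- which(!isHead)
      if (!length(firstData)) next
      keep <- seq(firstData[1], length(lines))
      # header lines cannot reappear after the first data line
      lines <- lines[keep]; lns <- lns[keep]
      inHeader <- FALSE
    }
    if (nData + length(lines) > maxLines) {
      take <- max(0L, as.integer(maxLines) - nData)
      lines <- lines[seq_len(take)]; lns <- lns[seq_len(take)]
      if (!length(lines)) break
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    short <- nf < 2L
    if (any(short))
      issues <- bindIssues(issues, do.call(rbind, lapply(which(short),
        function(i) newIssue("FVCF-PARSE-004",
          "data line has fewer than 2 tab-separated fields",
          line = lns[i], observed = lines[i]))))
    ok <- !short
    chrom <- vapply(fields[ok], `[`, character(1), 1L)
    posTxt <- vapply(fields[ok], `[`, character(1), 2L)
    posOk <- grepl("^[0-9]+$", posTxt)
    if (any(!posOk))
      issues <- bindIssues(issues, do.call(rbind, lapply(which(!posOk),
        function(i) newIssue("FVCF-PARSE-005",
          "POS is not a base-10 integer", line = lns[ok][i],
          observed = posTxt[i]))))
    cores <- data.frame(line = lns[ok][posOk], chrom = chrom[posOk],
                        pos = as.numeric(posTxt[posOk]),
                        n_fields = nf[ok][posOk],
                        stringsAsFactors = FALSE)
    nData <- nData + length(lines)
    if (is.null(callback)) coresList[[length(coresList) + 1L]] <- cores
    else if (nrow(cores)) callback(cores)
    if (nData >= maxLines) break
  }
  cores <- if (length(coresList)) do.call(rbind, coresList)
           else data.frame(line = integer(), chrom = character(),
                           pos = numeric(), n_fields = integer(),
                           stringsAsFactors = FALSE)
  list(cores = cores, issues = issues, nLines = nData)
}

# ---- FairHeader assembly -------------------------------------------------

extIdRecord <- function(value) {
  tryCatch(parseExtId(value),
           fvcf_extid_arity = function(e)
             list(dialect = "invalid", parts = character(), raw = value,
                  issues = newIssue("FVCF-EXTID-001", conditionMessage(e),
                                    observed = value)))
}

contigFromMeta <- function(sm) {
  a <- sm@attributes
  get1 <- function(k) {
    v <- a$value[a$key == k]
    if (length(v)) v[1] else NA_character_
  }
  len <- get1("length")
  lenNum <- if (is.na(len)) NA_real_
            else if (grepl("^[0-9]+$", len)) as.numeric(len) else -1
  new("ContigRecord", id = get1("ID"), length = lenNum,
      assembly = get1("assembly"), md5 = get1("md5"),
      species = get1("species"), lineNumber = sm@lineNumber)
}

sampleFromMeta <- function(sm) {
  a <- sm@attributes
  ids <- a$value[a$key == "ID"]
  dois <- a$value[a$key == "DOI"]
  extVals <- a$value[a$key == "ext_ID"]
  # one quoted value may itself carry comma-separated external IDs
  extVals <- unlist(lapply(extVals, function(v)
    strsplit(v, ",", fixed = TRUE)[[1]]), use.names = FALSE)
  extVals <- extVals[nzchar(extVals)]
  rec <- new("SampleRecord",
             id = if (length(ids)) ids[1] else NA_character_,
             doi = if (length(dois)) dois[1] else NA_character_,
             extIds = lapply(extVals, extIdRecord),
             lineNumber = sm@lineNumber)
  extra <- emptyIssues()
  if (length(dois) > 1L)
    extra <- newIssue("FVCF-SMP-001",
                      sprintf("%d DOI attributes; cardinality is 0-1",
                              length(dois)),
                      line = sm@lineNumber, observed = rec@id)
  attr(rec, "extraIssues") <- extra
  rec
}

#' Read and assemble the FAIR header of a VCF
#'
#' Parses every meta-information line and the column header line of a VCF
#' (path, plain or gzip-compressed, or literal text) into a
#' [FairHeader-class]: recognized scalar profile fields with their source
#' lines (surrounding quotes stripped from values), contig and SAMPLE
#' records, all other meta lines verbatim, and the parse-level issues
#' encountered. Keys that are case variants of a canonical profile key
#' (e.g. `##filedate`) are recognized as that field and flagged.
#'
#' @param source Path to a VCF, or VCF text.
#' @return A [FairHeader-class].
#' @examples
#' hdr <- readFairHeader(c(
#'   "##fileformat=VCFv4.3",
#'   "##fileDate=20120921",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
#' fieldValues(hdr, "fileDate")
#' @export
readFairHeader <- function(source) {
  con <- asLineSource(source, "VCF source")
  on.exit(close(con))
  path <- if (is.character(source) && length(source) == 1L &&
              file.exists(source) && !grepl("\n", source, fixed = TRUE))
    source else NA_character_
  meta <- list()
  contigs <- list(); smpls <- list()
  fieldRows <- list()
  hline <- NULL
  issues <- emptyIssues()
  lineNo <- 0L
  scalarCanon <- setdiff(.CANONICAL_KEYS, c("contig", "SAMPLE"))
  repeat {
    lines <- readLines(con, n = 512L)
    if (!length(lines)) break
    stopScan <- FALSE
    for (k in seq_along(lines)) {
      lineNo <- lineNo + 1L
      ln <- lines[k]
      if (startsWith(ln, "##")) {
        entry <- parseMetaLine(ln, lineNo)
        meta[[length(meta) + 1L]] <- entry
        issues <- bindIssues(issues, parseIssues(entry))
        key <- if (is(entry, "StructuredMeta")) entry@recordType
               else entry@key
        canon <- .canonicalKey(key)
        if (!is.na(canon) && key != canon)
          issues <- bindIssues(issues, newIssue("FVCF-CASE-001",
            sprintf("key '%s' is a case variant of canonical '%s'",
                    key, canon),
            line = lineNo, observed = key))
        if (!is.na(canon) && canon %in% scalarCanon &&
            is(entry, "MetaLine") && !is.na(entry@value)) {
          fieldRows[[length(fieldRows) + 1L]] <-
            data.frame(canonical = canon, key = key,
                       value = unquoteValue(entry@value), line = lineNo,
                       stringsAsFactors = FALSE)
        } else if (!is.na(canon) && canon == "contig" &&
                   is(entry, "StructuredMeta")) {
          contigs[[length(contigs) + 1L]] <- contigFromMeta(entry)
        } else if (!is.na(canon) && canon == "SAMPLE" &&
                   is(entry, "StructuredMeta")) {
          rec <- sampleFromMeta(entry)
          issues <- bindIssues(issues, attr(rec, "extraIssues"))
          attr(rec, "extraIssues") <- NULL
          smpls[[length(smpls) + 1L]] <- rec
        }
      } else if (startsWith(ln, "#")) {
        hline <- parseHeaderLine(ln, lineNo)
        stopScan <- TRUE
        break
      } else {
        stopScan <- TRUE
        break
      }
    }
    if (stopScan) break
  }
  fieldLines <- if (length(fieldRows)) do.call(rbind, fieldRows)
                else data.frame(canonical = character(), key = character(),
                                value = character(), line = integer(),
                                stringsAsFactors = FALSE)
  new("FairHeader", path = path, meta = meta, fieldLines = fieldLines,
      contigs = contigs, samples = smpls, headerLine = hline,
      parseIssues = issues)
}

.canonicalKey <- function(key) {
  i <- match(tolower(key), tolower(.CANONICAL_KEYS))
  if (is.na(i)) NA_character_ else .CANONICAL_KEYS[i]
}
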