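#' Accessors for fairVCF objects
#'
#' Small accessor generics for the S4 containers: source line numbers,
#' raw line text, parse issues, header components, reference-index
#' columns, and report fields.
#'
#' @param x,object An object of the documented class.
#' @return `lineNumber`: integer. `rawText`: character. `parseIssues`,
#'   `issues`: a data frame of issues. `contigs`, `samples`: lists of
#'   records. `headerLine`: a [HeaderLine-class] or `NULL`. `fieldValues`:
#'   character vector of unquoted values for one canonical field.
#'   `refNames`/`refLengths`/`refMd5`: vectors over index sequences.
#'   `passed`: logical. `issueCounts`: named integer vector
#'   (errors, warnings, infos).
#' @name fairVCF-accessors
#' @aliases lineNumber rawText parseIssues issues contigs samples
#'   headerLine fieldValues refNames refLengths refMd5 passed issueCounts
NULL

#' @rdname fairVCF-accessors
#' @export
setGeneric("lineNumber", function(x) standardGeneric("lineNumber"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("rawText", function(x) standardGeneric("rawText"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("parseIssues", function(x) standardGeneric("parseIssues"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("headerLine", function(x) standardGeneric("headerLine"))
#' @rdname fairVCF-accessors
#' @param canonical Canonical field name, e.g. `"fileDate"`.
#' @export
setGeneric("fieldValues", function(x, canonical) standardGeneric("fieldValues"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("refNames", function(x) standardGeneric("refNames"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("refLengths", function(x) standardGeneric("refLengths"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("refMd5", function(x) standardGeneric("refMd5"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))
#' @rdname fairVCF-accessors
#' @export
setGeneric("issueCounts", function(x) standardGeneric("issueCounts"))

#' @rdname fairVCF-accessors
setMethod("lineNumber", "MetaLine", function(x) x@lineNumber)
#' @rdname fairVCF-accessors
setMethod("lineNumber", "StructuredMeta", function(x) x@lineNumber)
#' @rdname fairVCF-accessors
setMethod("lineNumber", "HeaderLine", function(x) x@lineNumber)
#' @rdname fairVCF-accessors
setMethod("lineNumber", "ContigRecord", function(x) x@lineNumber)
#' @rdname fairVCF-accessors
setMethod("lineNumber", "SampleRecord", function(x) x@lineNumber)

#' @rdname fairVCF-accessors
setMethod("rawText", "MetaLine", function(x) x@raw)
#' @rdname fairVCF-accessors
setMethod("rawText", "StructuredMeta", function(x) x@raw)

#' @rdname fairVCF-accessors
setMethod("parseIssues", "MetaLine", function(x) x@issues)
#' @rdname fairVCF-accessors
setMethod("parseIssues", "StructuredMeta", function(x) x@issues)
#' @rdname fairVCF-accessors
setMethod("parseIssues", "FairHeader", function(x) x@parseIssues)

#' @rdname fairVCF-accessors
setMethod("contigs", "FairHeader", function(x) x@contigs)
#' @rdname fairVCF-accessors
setMethod("samples", "FairHeader", function(x) x@samples)
#' @rdname fairVCF-accessors
setMethod("headerLine", "FairHeader", function(x) x@headerLine)
#' @rdname fairVCF-accessors
setMethod("fieldValues", "FairHeader", function(x, canonical) {
  f <- x@fieldLines
  f$value[f$canonical == canonical]
})

#' @rdname fairVCF-accessors
setMethod("refNames", "ReferenceIndex", function(x) x@table$name)
#' @rdname fairVCF-accessors
setMethod("refLengths", "ReferenceIndex", function(x) {
  stats::setNames(x@table$length, x@table$name)
})
#' @rdname fairVCF-accessors
setMethod("refMd5", "ReferenceIndex", function(x) {
  stats::setNames(x@table$md5, x@table$name)
})

#' @rdname fairVCF-accessors
setMethod("issues", "ValidationReport", function(x) x@issues)
#' @rdname fairVCF-accessors
setMethod("issueCounts", "ValidationReport", function(x) {
  sev <- x@issues$severity
  c(errors = sum(sev == "error"), warnings = sum(sev == "warning"),
    infos = sum(sev == "info"))
})
#' @rdname fairVCF-accessors
setMethod("passed", "ValidationReport", function(x) {
  n <- issueCounts(x)
  if (x@strict) n[["errors"]] == 0L && n[["warnings"]] == 0L
  else n[["errors"]] == 0L
})

setMethod("show", "StructuredMeta", function(object) {
  cat(sprintf("StructuredMeta '%s' (line %s) with %d attribute(s)\n",
              object@recordType, format(object@lineNumber),
              nrow(object@attributes)))
  if (nrow(object@attributes))
    cat(" ", paste(object@attributes$key, collapse = ", "), "\n")
})

setMethod("show", "MetaLine", function(object) {
  cat(sprintf("MetaLine '%s' (line %s): %s\n", object@key,
              format(object@lineNumber), object@value))
})

setMethod("show", "FairHeader", function(object) {
  cat("FairHeader\n")
  cat(sprintf("  meta lines: %d | contigs: %d | SAMPLE records: %d\n",
              length(object@meta), length(object@contigs),
              length(object@samples)))
  ff <- fieldValues(object, "fileformat")
  cat(sprintf("  fileformat: %s\n",
              if (length(ff)) ff[1] else "<absent>"))
  hl <- object@headerLine
  cat(sprintf("  header line: %s\n",
              if (is.null(hl)) "<absent>"
              else sprintf("%d fixed + %d sample column(s)",
                           length(hl@fixed), length(hl@samples))))
  if (nrow(object@parseIssues))
    cat(sprintf("  parse issues: %d\n", nrow(object@parseIssues)))
})

setMethod("show", "ReferenceIndex", function(object) {
  cat(sprintf("ReferenceIndex with %d sequence(s)\n", nrow(object@table)))
  if (nrow(object@table)) {
    head6 <- utils::head(object@table, 6)
    print(head6, row.names = FALSE)
    if (nrow(object@table) > 6) cat("  ...\n")
  }
})

setMethod("show", "ValidationReport", function(object) {
  n <- issueCounts(object)
  cat(sprintf("ValidationReport for %s\n", object@filePath))
  cat(sprintf("  profile %s | %s mode | %s\n", object@profileVersion,
              if (object@strict) "strict" else "default",
              if (passed(object)) "PASSED" else "FAILED"))
  cat(sprintf("  %d error(s), %d warning(s), %d info note(s)\n",
              n[["errors"]], n[["warnings"]], n[["infos"]]))
})

setMethod("show", "ContigRecord", function(object) {
  cat(sprintf("ContigRecord %s (length=%s, assembly=%s)\n", object@id,
              format(object@length), object@assembly))
})

setMethod("show", "SampleRecord", function(object) {
  cat(sprintf("SampleRecord %s (DOI=%s, %d ext_ID(s))\n", object@id,
              object@doi, length(object@extIds)))
})
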