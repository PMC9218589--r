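#' @import methods
NULL

emptyIssues <- function() {
  data.frame(rule_id = character(), severity = character(),
             line = integer(), message = character(),
             observed = character(), stringsAsFactors = FALSE)
}

#' Unstructured meta-information line
#'
#' A `##key=value` line whose value is not an angle-bracketed attribute
#' list. The raw text is retained so that serialization reproduces the
#' input byte-for-byte.
#'
#' @slot lineNumber Line number in the source file (1-based).
#' @slot raw The original line text.
#' @slot key Text between `##` and the first `=`.
#' @slot value Text after the first `=` (possibly empty).
#' @slot issues A data frame of parse-level issues found on this line.
#' @exportClass MetaLine
setClass("MetaLine",
  representation(lineNumber = "integer", raw = "character",
                 key = "character", value = "character",
                 issues = "data.frame"),
  prototype(lineNumber = NA_integer_, raw = character(),
            key = NA_character_, value = NA_character_,
            issues = emptyIssues()))

#' Structured meta-information line
#'
#' A `##TYPE=<k1=v1,k2=v2,...>` line. Attribute order, the exact key text,
#' and which values were double-quoted are preserved so the line can be
#' re-serialized byte-identically.
#'
#' @slot lineNumber Line number in the source file (1-based).
#' @slot raw The original line text (empty for constructed lines).
#' @slot recordType The text between `##` and `=` (e.g. "contig", "SAMPLE").
#' @slot attributes Data frame with columns `key`, `value`, `quoted`.
#' @slot issues A data frame of parse-level issues found on this line.
#' @exportClass StructuredMeta
setClass("StructuredMeta",
  representation(lineNumber = "integer", raw = "character",
                 recordType = "character", attributes = "data.frame",
                 issues = "data.frame"),
  prototype(lineNumber = NA_integer_, raw = character(),
            recordType = NA_character_,
            attributes = data.frame(key = character(), value = character(),
                                    quoted = logical(),
                                    stringsAsFactors = FALSE),
            issues = emptyIssues()),
  validity = function(object) {
    a <- object@attributes
    if (!all(c("key", "value", "quoted") %in% names(a)))
      return("attributes must have columns key, value, quoted")
    TRUE
  })

#' VCF column header line
#'
#' The single-`#` line naming the fixed columns and the per-sample
#' genotype columns.
#'
#' @slot lineNumber Line number in the source file (1-based).
#' @slot fixed The first (up to) nine tab-delimited tokens.
#' @slot samples Tokens after the ninth: the sample columns.
#' @exportClass HeaderLine
setClass("HeaderLine",
  representation(lineNumber = "integer", fixed = "character",
                 samples = "character"),
  prototype(lineNumber = NA_integer_, fixed = character(),
            samples = character()))

#' Contig metadata record
#'
#' One reference sequence as declared by a `##contig` line: identifier,
#' length in base pairs, the assembly accession it belongs to, the MD5
#' digest of its (uppercased, whitespace-free) sequence, and the taxon of
#' the organism. Absent attributes are `NA`.
#'
#' @slot id Sequence identifier (the ID attribute).
#' @slot length Declared length in bp, or `NA`.
#' @slot assembly INSDC assembly accession (GCA_/GCF_), or `NA`.
#' @slot md5 32-character hexadecimal digest, or `NA`.
#' @slot species Prefixed taxon identifier (`NCBITaxon:<digits>`), or `NA`.
#' @slot lineNumber Source line number, `NA` for constructed records.
#' @exportClass ContigRecord
setClass("ContigRecord",
  representation(id = "character", length = "numeric",
                 assembly = "character", md5 = "character",
                 species = "character", lineNumber = "integer"),
  prototype(id = NA_character_, length = NA_real_,
            assembly = NA_character_, md5 = NA_character_,
            species = NA_character_, lineNumber = NA_integer_))

#' Sample metadata record
#'
#' One genotyped sample as declared by a `##SAMPLE` line: its BioSample
#' accession, an optional DOI, and zero or more external identifiers in
#' either the genebank (instcode:genus:accession) or the
#' DNS (dns:database:scheme:identifier) encoding.
#'
#' @slot id Primary identifier (BioSample accession when compliant).
#' @slot doi DOI locator, or `NA`.
#' @slot extIds List of parsed external identifiers (see [parseExtId()]).
#' @slot lineNumber Source line number, `NA` for constructed records.
#' @exportClass SampleRecord
setClass("SampleRecord",
  representation(id = "character", doi = "character", extIds = "list",
                 lineNumber = "integer"),
  prototype(id = NA_character_, doi = NA_character_, extIds = list(),
            lineNumber = NA_integer_))

#' Parsed VCF header under the FAIR profile
#'
#' The full meta-information section of one VCF file: every meta line in
#' file order, the recognized scalar profile fields with their source line
#' numbers, the contig and SAMPLE records, the column header line, and any
#' parse-level issues encountered.
#'
#' @slot path Source path, or `NA` when parsed from text.
#' @slot meta List of [MetaLine-class] / [StructuredMeta-class] objects in
#'   file order.
#' @slot fieldLines Data frame (`canonical`, `key`, `value`, `line`) with
#'   one row per occurrence of a recognized scalar field (fileformat,
#'   fileDate, bioinformatics_source, reference_ac, reference_url,
#'   reference). Values are unquoted.
#' @slot contigs List of [ContigRecord-class] objects in file order.
#' @slot samples List of [SampleRecord-class] objects in file order.
#' @slot headerLine A [HeaderLine-class], or `NULL` if absent.
#' @slot parseIssues Data frame of issues raised while parsing the header.
#' @exportClass FairHeader
setClass("FairHeader",
  representation(path = "character", meta = "list",
                 fieldLines = "data.frame", contigs = "list",
                 samples = "list", headerLine = "ANY",
                 parseIssues = "data.frame"),
  prototype(path = NA_character_, meta = list(),
            fieldLines = data.frame(canonical = character(),
                                    key = character(), value = character(),
                                    line = integer(),
                                    stringsAsFactors = FALSE),
            contigs = list(), samples = list(), headerLine = NULL,
            parseIssues = emptyIssues()),
  validity = function(object) {
    if (!is.null(object@headerLine) && !is(object@headerLine, "HeaderLine"))
      return("headerLine must be NULL or a HeaderLine")
    if (!all(vapply(object@contigs, is, logical(1), "ContigRecord")))
      return("contigs must be ContigRecord objects")
    if (!all(vapply(object@samples, is, logical(1), "SampleRecord")))
      return("samples must be SampleRecord objects")
    TRUE
  })

#' Per-sequence index of a reference FASTA
#'
#' Name, length and MD5 digest for every sequence of a reference genome
#' FASTA. Digests are computed over the normalized sequence: residues
#' uppercased, all whitespace and line breaks removed.
#'
#' @slot table Data frame with columns `name`, `length`, `md5`.
#' @slot source Source path, or `NA` when built from text.
#' @exportClass ReferenceIndex
setClass("ReferenceIndex",
  representation(table = "data.frame", source = "character"),
  prototype(table = data.frame(name = character(), length = numeric(),
                               md5 = character(), stringsAsFactors = FALSE),
            source = NA_character_),
  validity = function(object) {
    t <- object@table
    if (!all(c("name", "length", "md5") %in% names(t)))
      return("table must have columns name, length, md5")
    if (anyDuplicated(t$name)) return("duplicate sequence names")
    if (nrow(t) && !all(grepl("^[0-9a-f]{32}$", t$md5)))
      return("md5 must be 32 lowercase hex characters")
    TRUE
  })

#' Validation report
#'
#' The aggregated outcome of validating one VCF: the ordered issue table
#' (columns `rule_id`, `severity`, `line`, `message`, `observed`), the
#' strictness flag, and the derived pass/fail verdict. In default mode a
#' file passes when it has no errors; in strict mode warnings also fail it.
#'
#' @slot filePath Path of the validated file.
#' @slot profileVersion Version string of the metadata profile.
#' @slot strict Whether strict mode was requested.
#' @slot issues Data frame of issues, ordered by line then rule id.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(filePath = "character", profileVersion = "character",
                 strict = "logical", issues = "data.frame"),
  prototype(filePath = NA_character_, profileVersion = "1.0",
            strict = FALSE, issues = emptyIssues()),
  validity = function(object) {
    req <- c("rule_id", "severity", "line", "message", "observed")
    if (!all(req %in% names(object@issues)))
      return("issues must have columns rule_id, severity, line, message, observed")
    bad <- setdiff(unique(object@issues$severity),
                   c("error", "warning", "info"))
    if (length(bad)) return(paste("unknown severity:", bad[1]))
    TRUE
  })
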