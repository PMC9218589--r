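# Aggregate validation and report rendering.

headerLineIssues <- function(header) {
  hl <- headerLine(header)
  if (is.null(hl))
    return(newIssue("FVCF-HDR-002", "no column header line found"))
  fixedOk <- identical(hl@fixed, .MANDATORY_COLUMNS) ||
    (length(hl@samples) == 0L &&
       identical(hl@fixed, .MANDATORY_COLUMNS[1:8]))
  if (!fixedOk)
    return(newIssue("FVCF-HDR-001",
      "fixed columns deviate from the 9 mandatory headings",
      line = hl@lineNumber,
      observed = paste(hl@fixed, collapse = ",")))
  emptyIssues()
}

#' Validate a VCF against the FAIR metadata profile
#'
#' Runs the full pipeline on one file: header parsing, the field-grammar
#' rules for every recognized field occurrence, cardinality and
#' ID-uniqueness checks, header-line compliance, sample-column
#' reconciliation, data-line position checks against declared contig
#' bounds, and — when a reference FASTA is supplied — name/length/MD5
#' agreement between contig declarations and the indexed sequences.
#' Issues are ordered deterministically (line number, then rule id).
#'
#' @param vcf Path to the VCF (plain or gzip), or VCF text.
#' @param fasta Optional reference FASTA (path or text).
#' @param strict Strict mode: warnings also fail the file.
#' @param maxDataLines Bound on data lines examined (default unlimited).
#' @return A [ValidationReport-class].
#' @examples
#' fx <- makeVcf(makeReference(1, 120, seed = 7), nSamples = 2,
#'               nVariants = 5, seed = 7, profile = "fair")
#' rep <- runValidation(fx$vcf)
#' issueCounts(rep)
#' @export
runValidation <- function(vcf, fasta = NULL, strict = FALSE,
                          maxDataLines = Inf) {
  header <- readFairHeader(vcf)
  out <- bindIssues(
    parseIssues(header),
    fieldGrammarIssues(header),
    checkCardinalities(header),
    checkUniqueness(header),
    headerLineIssues(header),
    if (!is.null(headerLine(header))) checkSampleColumns(header),
    checkContigAssemblyAgreement(header))
  if (!is.null(fasta)) {
    index <- buildReferenceIndex(fasta)
    out <- bindIssues(out, checkContigsVsReference(header, index))
  }
  stream <- streamDataCores(vcf, maxLines = maxDataLines)
  out <- bindIssues(out, stream$issues,
                    checkPositions(stream$cores, header))
  new("ValidationReport",
      filePath = if (!is.na(header@path)) header@path else "<text>",
      profileVersion = .FVCF_PROFILE_VERSION, strict = strict,
      issues = orderIssues(out))
}

#' Render a validation report
#'
#' `json` renders a stable-keyed machine-readable document (see the
#' schema shipped under `inst/schema/`); `text` lists issues grouped by
#' severity with line anchors. Rendering is deterministic: the same
#' report always yields the same text.
#'
#' @param report A [ValidationReport-class].
#' @param format `"json"` or `"text"`.
#' @return A single string.
#' @export
renderReport <- function(report, format = c("json", "text")) {
  stopifnot(is(report, "ValidationReport"))
  format <- match.arg(format)
  n <- issueCounts(report)
  if (format == "json") {
    iss <- report@issues
    issueList <- lapply(seq_len(nrow(iss)), function(i) list(
      rule_id = iss$rule_id[i],
      severity = iss$severity[i],
      line_number = if (is.na(iss$line[i])) NULL else iss$line[i],
      message = iss$message[i],
      observed = if (is.na(iss$observed[i])) NULL else iss$observed[i]))
    doc <- list(file_path = report@filePath,
                profile_version = report@profileVersion,
                strict = report@strict,
                passed = passed(report),
                counts = list(errors = unname(n[["errors"]]),
                              warnings = unname(n[["warnings"]]),
                              infos = unname(n[["infos"]])),
                issues = issueList)
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                         null = "null", digits = NA,
                                         pretty = TRUE)))
  }
  lines <- c(sprintf("Validation of %s (profile %s, %s mode): %s",
                     report@filePath, report@profileVersion,
                     if (report@strict) "strict" else "default",
                     if (passed(report)) "PASSED" else "FAILED"),
             sprintf("  %d error(s), %d warning(s), %d info note(s)",
                     n[["errors"]], n[["warnings"]], n[["infos"]]))
  for (sev in c("error", "warning", "info")) {
    sub <- report@issues[report@issues$severity == sev, , drop = FALSE]
    if (!nrow(sub)) next
    lines <- c(lines, paste0(toupper(sev), "S:"))
    lines <- c(lines, vapply(seq_len(nrow(sub)), function(i)
      sprintf("  [%s] %s%s", sub$rule_id[i],
              if (is.na(sub$line[i])) "" else sprintf("line %d: ",
                                                      sub$line[i]),
              sub$message[i]), character(1)))
  }
  paste(lines, collapse = "\n")
}

#' Parse a rendered JSON report back into its content
#'
#' Inverse of the JSON rendering, for machine consumers and round-trip
#' checks.
#'
#' @param json JSON text produced by [renderReport()].
#' @return A list mirroring the report content.
#' @export
parseReportJson <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE,
                     simplifyDataFrame = TRUE)
}
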