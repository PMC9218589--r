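# Field-grammar and cardinality rules of the FAIR VCF metadata profile.
# Every emitted rule id is drawn from the catalogue below; validators are
# pure (same input, same issue list) and return zero-row data frames when
# the value is compliant.

.FVCF_PROFILE_VERSION <- "1.0"

.ruleCatalogue <- local({
  r <- function(id, severity, field, description)
    data.frame(rule_id = id, severity = severity, field = field,
               description = description, stringsAsFactors = FALSE)
  rbind(
    r("FVCF-PARSE-001", "error", "meta line", "Unterminated double quote inside a structured value."),
    r("FVCF-PARSE-002", "error", "meta line", "Structured value opens with '<' but does not close with '>'."),
    r("FVCF-PARSE-003", "error", "meta line", "Meta-information key is empty."),
    r("FVCF-PARSE-004", "error", "data line", "Data line has fewer than two tab-separated fields."),
    r("FVCF-PARSE-005", "error", "data line", "POS is not a base-10 integer."),
    r("FVCF-PARSE-006", "error", "meta line", "Meta-information line lacks an '=' after the key."),
    r("FVCF-PARSE-007", "error", "meta line", "Text follows a closing quote before the next separator."),
    r("FVCF-STRUCT-001", "error", "structured line", "Structured meta line has no ID attribute."),
    r("FVCF-STRUCT-002", "warning", "structured line", "Duplicate attribute key within one structured line."),
    r("FVCF-CASE-001", "warning", "meta line", "Meta key is a case variant of a canonical profile key."),
    r("FVCF-DATE-001", "error", "##fileDate", "File date is not 8 digits in basic YYYYMMDD form (no separators)."),
    r("FVCF-DATE-002", "error", "##fileDate", "File date digits do not form a valid Gregorian calendar date."),
    r("FVCF-ACC-001", "error", "##reference_ac", "Assembly accession does not match GCA_/GCF_ + 9 digits + '.' + version."),
    r("FVCF-URL-001", "error", "##bioinformatics_source / ##reference_url", "Locator is not a usable URL/URI/DOI."),
    r("FVCF-BIOS-001", "error", "##SAMPLE ID", "Identifier does not match the BioSample accession grammar SAM(E|N|D)(A|G)?digits."),
    r("FVCF-TAX-001", "error", "species", "Taxon is not of the form NCBITaxon:<digits>."),
    r("FVCF-TAX-002", "warning", "species", "Taxon given as bare digits; prefix with 'NCBITaxon:' (auto-fixable)."),
    r("FVCF-TAX-003", "warning", "species", "Taxon prefix is a case/alias variant of 'NCBITaxon:' (auto-fixable)."),
    r("FVCF-EXTID-001", "error", "##SAMPLE ext_ID", "External ID has neither 3 (instcode:genus:accession) nor 4 (dns:database:scheme:identifier) colon-separated parts."),
    r("FVCF-EXTID-002", "warning", "##SAMPLE ext_ID", "Institute code does not match the expected AAA999 pattern."),
    r("FVCF-SMP-001", "error", "##SAMPLE DOI", "More than one DOI attribute on a single SAMPLE record."),
    r("FVCF-CTG-001", "error", "##contig length", "Contig length is not a positive integer."),
    r("FVCF-CTG-002", "error", "##contig md5", "Contig md5 is not a 32-character hexadecimal digest."),
    r("FVCF-CTG-003", "info", "##contig", "Recommended contig attribute (length/md5/species) absent."),
    r("FVCF-CARD-001", "warning", "header", "Recommended scalar field absent (expected exactly once)."),
    r("FVCF-CARD-002", "error", "header", "Scalar field declared more than once (cardinality 1)."),
    r("FVCF-CARD-003", "error", "##fileformat", "##fileformat line absent (obligatory in VCF)."),
    r("FVCF-CARD-004", "warning", "##contig", "No contig lines declared (expected 1 or more)."),
    r("FVCF-CARD-005", "warning", "##SAMPLE", "No SAMPLE lines declared (expected 1 or more)."),
    r("FVCF-UNIQ-001", "error", "##contig", "Contig ID duplicated within its type."),
    r("FVCF-UNIQ-002", "error", "##SAMPLE", "SAMPLE ID duplicated within its type."),
    r("FVCF-HDR-001", "error", "header line", "Fixed columns deviate from the 9 mandatory headings."),
    r("FVCF-HDR-002", "error", "header line", "Column header line absent."),
    r("FVCF-REF-001", "error", "##contig", "Contig ID not present in the reference FASTA."),
    r("FVCF-REF-002", "warning", "##contig", "Reference FASTA sequence has no contig declaration."),
    r("FVCF-REF-003", "error", "##contig length", "Declared contig length differs from the reference sequence length."),
    r("FVCF-REF-004", "error", "##contig md5", "Declared contig md5 differs from the reference sequence digest."),
    r("FVCF-REF-005", "error", "##contig assembly", "Contig assembly accession differs from ##reference_ac."),
    r("FVCF-REF-006", "warning", "##contig assembly", "Contig has no assembly attribute."),
    r("FVCF-COL-001", "warning", "sample columns", "Sample column has no matching ##SAMPLE record."),
    r("FVCF-COL-002", "warning", "sample columns", "##SAMPLE record has no matching sample column."),
    r("FVCF-COL-003", "warning", "sample columns", "Sample column name fails the BioSample accession grammar."),
    r("FVCF-COL-004", "error", "sample columns", "Duplicate sample column name."),
    r("FVCF-POS-001", "error", "data lines", "Data lines reference a chromosome with no contig declaration."),
    r("FVCF-POS-002", "error", "data lines", "POS outside the declared contig bounds [1, length]."),
    r("FVCF-POS-003", "warning", "data lines", "POS 0 (telomeric convention) encountered."),
    r("FVCF-POS-004", "info", "data lines", "Contig without declared length; position bound check skipped."),
    r("FVCF-META-001", "info", "##reference", "Legacy ##reference key present alongside the profile fields.")
  )
})

.ruleSeverity <- function(rule_id) {
  i <- match(rule_id, .ruleCatalogue$rule_id)
  if (anyNA(i)) stop("unknown rule id: ", rule_id[is.na(i)][1])
  .ruleCatalogue$severity[i]
}

#' The rule catalogue
#'
#' Machine-readable registry of every validation rule the package can
#' emit: stable identifier, severity, the metadata field it concerns, and
#' a description. Every `rule_id` appearing in a [ValidationReport-class]
#' is drawn from this table.
#'
#' @return A data frame with columns `rule_id`, `severity`, `field`,
#'   `description`.
#' @examples
#' head(ruleCatalogue())
#' @export
ruleCatalogue <- function() .ruleCatalogue

#' Validate the VCF creation date
#'
#' The profile requires the creation date in ISO 8601 basic form:
#' exactly eight digits, `YYYYMMDD`, no separators, forming a valid
#' Gregorian calendar date (leap years honoured).
#'
#' @param value The fileDate value text.
#' @return A data frame of issues; zero rows when compliant.
#' @examples
#' validateFileDate("20120921")   # compliant
#' validateFileDate("2012-09-21") # extended form is rejected
#' @export
validateFileDate <- function(value) {
  stopifnot(is.character(value), length(value) == 1L)
  if (!grepl("^[0-9]{8}$", value)) {
    msg <- if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value))
      "date uses separators; the basic form YYYYMMDD is required"
    else "date must be exactly 8 digits (YYYYMMDD)"
    return(newIssue("FVCF-DATE-001", msg, observed = value))
  }
  d <- as.Date(value, format = "%Y%m%d")
  if (is.na(d) || format(d, "%Y%m%d") != value)
    return(newIssue("FVCF-DATE-002",
                    "digits do not form a valid calendar date",
                    observed = value))
  emptyIssues()
}

#' Validate an INSDC genome assembly accession
#'
#' Accepts `GCA_` (GenBank) or `GCF_` (RefSeq) followed by exactly nine
#' digits, a dot, and a version of at least one digit, e.g.
#' `GCA_902498975.1`.
#'
#' @param value The accession text.
#' @return A data frame of issues; zero rows when compliant.
#' @examples
#' validateAssemblyAccession("GCA_902498975.1")
#' validateAssemblyAccession("GCA_1234.1") # digit block too short
#' @export
validateAssemblyAccession <- function(value) {
  stopifnot(is.character(value), length(value) == 1L)
  if (grepl("^GC[AF]_[0-9]{9}\\.[0-9]+$", value)) return(emptyIssues())
  newIssue("FVCF-ACC-001",
           "expected GCA_ or GCF_, 9 digits, '.', then a version",
           observed = value)
}

.isDoi <- function(value) {
  grepl("doi\\.org/10\\.", value) || grepl("^doi:", value) ||
    grepl("^10\\.[0-9]+/", value)
}

#' Validate a URL/URI/DOI locator
#'
#' Locators for the bioinformatics-source and reference-URL fields: a
#' non-empty string without whitespace that either carries a scheme
#' (`http://`, `https://`, `ftp://`, `doi:`) or is scheme-less with a
#' dotted host followed by a path (`doi.org/...`, `github.com/...`).
#'
#' @param value The locator text (without surrounding quotes).
#' @return A data frame of issues; zero rows when compliant. The returned
#'   frame carries an attribute `kind` (`"doi"` or `"url"`) when clean.
#' @examples
#' validateUrlOrDoi("doi.org/10.1038/s41588-018-0266-x")
#' validateUrlOrDoi("github.com/gramarga/tassel4-poly")
#' @export
validateUrlOrDoi <- function(value) {
  stopifnot(is.character(value), length(value) == 1L)
  if (!nchar(value))
    return(newIssue("FVCF-URL-001", "locator is empty", observed = value))
  if (grepl("[[:space:]]", value))
    return(newIssue("FVCF-URL-001", "locator contains whitespace",
                    observed = value))
  schemed <- grepl("^(https?|ftp)://", value) || grepl("^doi:", value)
  schemeless <- grepl("^[A-Za-z0-9._-]+\\.[A-Za-z]{2,}/", value)
  if (!schemed && !schemeless)
    return(newIssue("FVCF-URL-001",
                    "locator needs a scheme or a dotted host followed by '/'",
                    observed = value))
  out <- emptyIssues()
  attr(out, "kind") <- if (.isDoi(value)) "doi" else "url"
  out
}

#' Validate a BioSample accession
#'
#' BioSample accessions begin with `SAM`, then `E`, `N` or `D` for the
#' archive of first submission, optionally `A` or `G` (assay sample or
#' group), and a numeric component that may be zero-padded:
#' `^SAM[END][AG]?[0-9]+$`.
#'
#' @param value The identifier text.
#' @return A data frame of issues; zero rows when compliant.
#' @examples
#' validateBiosampleId("SAMEA104646767")
#' validateBiosampleId("SAMN0000123")
#' @export
validateBiosampleId <- function(value) {
  stopifnot(is.character(value), length(value) == 1L)
  if (grepl("^SAM[END][AG]?[0-9]+$", value)) return(emptyIssues())
  newIssue("FVCF-BIOS-001",
           "expected SAM, then E/N/D, optional A/G, then digits",
           observed = value)
}

#' Validate a prefixed NCBI taxon identifier
#'
#' The species attribute of contig records must read
#' `NCBITaxon:<digits>` (e.g. `NCBITaxon:4513` for barley). Bare digits
#' and case/alias variants of the prefix are reported as distinct,
#' auto-fixable issues.
#'
#' @param value The taxon text.
#' @return A data frame of issues; zero rows when compliant.
#' @examples
#' validateTaxon("NCBITaxon:4513")
#' validateTaxon("4513") # fixable: missing prefix
#' @export
validateTaxon <- function(value) {
  stopifnot(is.character(value), length(value) == 1L)
  if (grepl("^NCBITaxon:[0-9]+$", value)) return(emptyIssues())
  if (grepl("^[0-9]+$", value))
    return(newIssue("FVCF-TAX-002",
                    "bare taxon number; expected NCBITaxon:<digits>",
                    observed = value))
  if (grepl("^(ncbitaxon|taxon|NCBITaxon|Taxon):[0-9]+$", value,
            ignore.case = TRUE))
    return(newIssue("FVCF-TAX-003",
                    "prefix variant; canonical form is NCBITaxon:<digits>",
                    observed = value))
  newIssue("FVCF-TAX-001", "expected NCBITaxon:<digits>", observed = value)
}

#' Parse an external sample identifier
#'
#' External IDs tie a genotyped sample to a genebank or institutional
#' database and come in two encodings distinguished by arity:
#' three colon-separated parts `instcode:genus:accession_number`
#' (FAO-WIEWS-registered holders) or four parts
#' `dns:database:scheme:identifier`. The accession number and the
#' identifier may contain spaces.
#'
#' @param value The external identifier text (without surrounding quotes).
#' @return A list with elements `dialect` (`"faowiews"` or `"dns"`),
#'   `parts` (named character), `raw`, and `issues` (a data frame;
#'   non-fatal pattern warnings such as an unusual institute code).
#'   Any other component count raises a classed error
#'   (`fvcf_extid_arity`).
#' @examples
#' parseExtId("DEU146:Hordeum:HOR 1361 BRG")
#' parseExtId("ipk-gatersleben.de:GBIS:akzessionId:7811152")
#' @export
parseExtId <- function(value) {
  stopifnot(is.character(value), length(value) == 1L, nchar(value) > 0)
  parts <- strsplit(value, ":", fixed = TRUE)[[1]]
  if (length(parts) == 3L) {
    issues <- emptyIssues()
    if (!grepl("^[A-Z]{3}[0-9]{3}$", parts[1]))
      issues <- newIssue("FVCF-EXTID-002",
                         "institute code does not look like AAA999",
                         observed = parts[1])
    return(list(dialect = "faowiews",
                parts = c(instcode = parts[1], genus = parts[2],
                          accession_number = parts[3]),
                raw = value, issues = issues))
  }
  if (length(parts) == 4L) {
    return(list(dialect = "dns",
                parts = c(dns_name = parts[1], database = parts[2],
                          scheme = parts[3], identifier = parts[4]),
                raw = value, issues = emptyIssues()))
  }
  fvcfError("fvcf_extid_arity",
            sprintf("external ID '%s' has %d colon-separated parts; expected 3 or 4",
                    value, length(parts)))
}

# ext_ID issue frame for one value (non-throwing wrapper around parseExtId).
extIdIssues <- function(value) {
  tryCatch(parseExtId(value)$issues,
           fvcf_extid_arity = function(e)
             newIssue("FVCF-EXTID-001", conditionMessage(e),
                      observed = value))
}

#' Check field cardinalities of a parsed header
#'
#' The profile expects `##fileformat` (obligatory in VCF) plus exactly one
#' each of `##fileDate`, `##bioinformatics_source`, `##reference_ac` and
#' `##reference_url`, and at least one `##contig` and `##SAMPLE` line.
#' Absence of a recommended field is a warning (an error under strict-mode
#' pass semantics); multiplicity beyond one is an error.
#'
#' @param header A [FairHeader-class].
#' @return A data frame of issues.
#' @export
checkCardinalities <- function(header) {
  stopifnot(is(header, "FairHeader"))
  out <- emptyIssues()
  if (!length(fieldValues(header, "fileformat")))
    out <- bindIssues(out, newIssue("FVCF-CARD-003",
                                    "##fileformat is obligatory but absent"))
  for (f in c("fileDate", "bioinformatics_source", "reference_ac",
              "reference_url")) {
    rows <- header@fieldLines[header@fieldLines$canonical == f, , drop = FALSE]
    if (nrow(rows) == 0L)
      out <- bindIssues(out, newIssue("FVCF-CARD-001",
        sprintf("missing recommended field ##%s", f)))
    else if (nrow(rows) > 1L)
      out <- bindIssues(out, newIssue("FVCF-CARD-002",
        sprintf("##%s declared %d times; cardinality is 1", f, nrow(rows)),
        line = rows$line[2], observed = rows$value[2]))
  }
  if (!length(contigs(header)))
    out <- bindIssues(out, newIssue("FVCF-CARD-004",
                                    "no ##contig lines declared"))
  if (!length(samples(header)))
    out <- bindIssues(out, newIssue("FVCF-CARD-005",
                                    "no ##SAMPLE lines declared"))
  out
}

#' Check ID uniqueness within structured line types
#'
#' Structured meta lines require an ID unique within their type: one error
#' per duplicated contig ID and per duplicated SAMPLE ID. The same ID on a
#' contig and a SAMPLE is permitted.
#'
#' @param header A [FairHeader-class].
#' @return A data frame of issues.
#' @export
checkUniqueness <- function(header) {
  stopifnot(is(header, "FairHeader"))
  out <- emptyIssues()
  dupIssues <- function(records, rule, what) {
    ids <- vapply(records, function(r) r@id, character(1))
    lns <- vapply(records, function(r) r@lineNumber, integer(1))
    ids2 <- ids[!is.na(ids)]
    for (d in unique(ids2[duplicated(ids2)])) {
      at <- lns[which(ids == d)]
      out <<- bindIssues(out, newIssue(rule,
        sprintf("%s ID '%s' declared %d times", what, d, sum(ids == d, na.rm = TRUE)),
        line = at[length(at)], observed = d))
    }
  }
  dupIssues(contigs(header), "FVCF-UNIQ-001", "contig")
  dupIssues(samples(header), "FVCF-UNIQ-002", "SAMPLE")
  out
}

# Apply the per-field grammars to every recognized occurrence in a header,
# anchoring each issue to its source line.
fieldGrammarIssues <- function(header) {
  stopifnot(is(header, "FairHeader"))
  out <- emptyIssues()
  fl <- header@fieldLines
  for (i in seq_len(nrow(fl))) {
    v <- fl$value[i]; ln <- fl$line[i]
    iss <- switch(fl$canonical[i],
      fileDate = validateFileDate(v),
      bioinformatics_source = validateUrlOrDoi(v),
      reference_url = validateUrlOrDoi(v),
      reference_ac = validateAssemblyAccession(v),
      reference = newIssue("FVCF-META-001",
        "legacy ##reference key present; profile uses ##reference_ac/##reference_url",
        observed = v),
      NULL)
    if (!is.null(iss)) out <- bindIssues(out, setIssueLine(iss, ln))
  }
  for (ct in contigs(header)) {
    ln <- ct@lineNumber
    if (is.na(ct@id))
      out <- bindIssues(out, newIssue("FVCF-STRUCT-001",
        "contig line has no ID attribute", line = ln))
    if (is.na(ct@length)) {
      out <- bindIssues(out, newIssue("FVCF-CTG-003",
        "contig has no length attribute", line = ln, observed = ct@id))
    } else if (!(ct@length >= 1 && ct@length == floor(ct@length))) {
      out <- bindIssues(out, newIssue("FVCF-CTG-001",
        "length must be a positive integer (bp)", line = ln,
        observed = format(ct@length, scientific = FALSE)))
    }
    if (is.na(ct@md5)) {
      out <- bindIssues(out, newIssue("FVCF-CTG-003",
        "contig has no md5 attribute", line = ln, observed = ct@id))
    } else if (!grepl("^[0-9a-fA-F]{32}$", ct@md5)) {
      out <- bindIssues(out, newIssue("FVCF-CTG-002",
        "md5 must be 32 hexadecimal characters", line = ln,
        observed = ct@md5))
    }
    if (is.na(ct@species)) {
      out <- bindIssues(out, newIssue("FVCF-CTG-003",
        "contig has no species attribute", line = ln, observed = ct@id))
    } else {
      out <- bindIssues(out, setIssueLine(validateTaxon(ct@species), ln))
    }
    if (!is.na(ct@assembly))
      out <- bindIssues(out,
                        setIssueLine(validateAssemblyAccession(ct@assembly), ln))
  }
  for (sm in samples(header)) {
    ln <- sm@lineNumber
    if (is.na(sm@id))
      out <- bindIssues(out, newIssue("FVCF-STRUCT-001",
        "SAMPLE line has no ID attribute", line = ln))
    else
      out <- bindIssues(out, setIssueLine(validateBiosampleId(sm@id), ln))
    if (!is.na(sm@doi))
      out <- bindIssues(out, setIssueLine(validateUrlOrDoi(sm@doi), ln))
    for (e in sm@extIds)
      if (nrow(e$issues)) out <- bindIssues(out, setIssueLine(e$issues, ln))
  }
  out
}
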