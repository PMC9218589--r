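# Cross-checks tying declared metadata to the data lines and to the
# actual reference sequences.

#' Index a reference FASTA
#'
#' Streams a FASTA (path, plain or gzip-compressed, or literal text) and
#' records, per sequence, its name (first whitespace-delimited token after
#' `>`), its length in bp, and the MD5 digest of the normalized sequence:
#' residues uppercased, all whitespace and line breaks removed, no
#' terminal newline. This is the per-sequence checksum convention of the
#' alignment-format ecosystem, so digests are comparable with `##contig`
#' `md5` attributes. The digest is accumulated chunk-wise; memory use is
#' independent of sequence length.
#'
#' @param fasta Path to a FASTA, or FASTA text.
#' @return A [ReferenceIndex-class].
#' @examples
#' idx <- buildReferenceIndex(c(">chrT", "ACGTACGTAC"))
#' refLengths(idx)
#' @export
buildReferenceIndex <- function(fasta) {
  con <- asLineSource(fasta, "FASTA source")
  on.exit(close(con), add = TRUE)
  src <- if (is.character(fasta) && length(fasta) == 1L &&
             file.exists(fasta) && !grepl("\n", fasta, fixed = TRUE))
    fasta else NA_character_
  dig <- sequenceDigester()
  on.exit(dig$cleanup(), add = TRUE)
  names <- character(); lens <- numeric(); md5s <- character()
  cur <- NA_character_; curLen <- 0
  finishRecord <- function() {
    if (is.na(cur)) return()
    names <<- c(names, cur)
    lens <<- c(lens, curLen)
    md5s <<- c(md5s, dig$digest())
  }
  repeat {
    lines <- readLines(con, n = 2000L)
    if (!length(lines)) break
    for (ln in lines) {
      if (startsWith(ln, ">")) {
        finishRecord()
        cur <- strsplit(substring(ln, 2L), "[[:space:]]+")[[1]][1]
        if (is.na(cur) || !nzchar(cur))
          fvcfError("fvcf_bad_fasta", "FASTA record with empty name")
        if (cur %in% names)
          fvcfError("fvcf_duplicate_sequence",
                    sprintf("duplicate sequence name '%s'", cur))
        curLen <- 0
        dig$reset()
      } else {
        if (is.na(cur)) {
          if (!nzchar(trimws(ln))) next
          fvcfError("fvcf_bad_fasta",
                    "sequence data before the first '>' header")
        }
        chunk <- normalizeResidues(ln)
        curLen <- curLen + nchar(chunk)
        if (nchar(chunk)) dig$add(chunk)
      }
    }
  }
  finishRecord()
  if (!length(names))
    fvcfError("fvcf_empty_fasta", "FASTA contains no sequence records")
  new("ReferenceIndex",
      table = data.frame(name = names, length = lens, md5 = md5s,
                         stringsAsFactors = FALSE),
      source = src)
}

#' Check contig declarations against a reference index
#'
#' Contig IDs must use the same nomenclature as the reference FASTA, and
#' declared lengths and MD5 digests must agree with the indexed
#' sequences. Emits: an error per contig ID absent from the index; a
#' warning per index sequence with no contig declaration; an error per
#' length mismatch; an error per digest mismatch (hex comparison is
#' case-insensitive).
#'
#' @param header A [FairHeader-class].
#' @param index A [ReferenceIndex-class].
#' @return A data frame of issues; zero rows when everything agrees.
#' @export
checkContigsVsReference <- function(header, index) {
  stopifnot(is(header, "FairHeader"), is(index, "ReferenceIndex"))
  out <- emptyIssues()
  idx <- index@table
  seen <- character()
  for (ct in contigs(header)) {
    if (is.na(ct@id)) next
    seen <- c(seen, ct@id)
    i <- match(ct@id, idx$name)
    if (is.na(i)) {
      out <- bindIssues(out, newIssue("FVCF-REF-001",
        sprintf("contig '%s' is not a sequence of the reference FASTA",
                ct@id),
        line = ct@lineNumber, observed = ct@id))
      next
    }
    if (!is.na(ct@length) && ct@length != idx$length[i])
      out <- bindIssues(out, newIssue("FVCF-REF-003",
        sprintf("contig '%s' declares length %s but the reference sequence has %s bp",
                ct@id, format(ct@length, scientific = FALSE),
                format(idx$length[i], scientific = FALSE)),
        line = ct@lineNumber,
        observed = format(ct@length, scientific = FALSE)))
    if (!is.na(ct@md5) && tolower(ct@md5) != idx$md5[i])
      out <- bindIssues(out, newIssue("FVCF-REF-004",
        sprintf("contig '%s' md5 does not match the reference sequence digest %s",
                ct@id, idx$md5[i]),
        line = ct@lineNumber, observed = ct@md5))
  }
  for (nm in setdiff(idx$name, seen))
    out <- bindIssues(out, newIssue("FVCF-REF-002",
      sprintf("reference sequence '%s' has no contig declaration", nm),
      observed = nm))
  out
}

#' Check contig/assembly agreement with ##reference_ac
#'
#' Every contig carrying an `assembly` attribute must name the same
#' accession as the `##reference_ac` line (error on mismatch); contigs
#' without an `assembly` attribute draw a warning. When no
#' `##reference_ac` line exists the agreement check is skipped (the
#' cardinality rule reports the absence separately).
#'
#' @param header A [FairHeader-class].
#' @return A data frame of issues.
#' @export
checkContigAssemblyAgreement <- function(header) {
  stopifnot(is(header, "FairHeader"))
  out <- emptyIssues()
  ac <- fieldValues(header, "reference_ac")
  for (ct in contigs(header)) {
    if (is.na(ct@assembly)) {
      out <- bindIssues(out, newIssue("FVCF-REF-006",
        sprintf("contig '%s' has no assembly attribute", ct@id),
        line = ct@lineNumber, observed = ct@id))
    } else if (length(ac) && ct@assembly != ac[1]) {
      out <- bindIssues(out, newIssue("FVCF-REF-005",
        sprintf("contig '%s' assembly %s differs from ##reference_ac %s",
                ct@id, ct@assembly, ac[1]),
        line = ct@lineNumber, observed = ct@assembly))
    }
  }
  out
}

#' Reconcile sample columns with SAMPLE records
#'
#' The column headers after the nine mandatory headings should be
#' BioSample accessions, each matched by a `##SAMPLE` record. Emits: a
#' warning per sample column with no matching record; a warning per
#' record with no matching column; a warning per column failing the
#' BioSample grammar; an error per duplicated column name.
#'
#' @param header A [FairHeader-class] with a header line.
#' @return A data frame of issues.
#' @export
checkSampleColumns <- function(header) {
  stopifnot(is(header, "FairHeader"))
  hl <- headerLine(header)
  if (is.null(hl))
    fvcfError("fvcf_no_header_line",
              "header has no column header line to reconcile")
  out <- emptyIssues()
  cols <- hl@samples
  ids <- vapply(samples(header), function(s) s@id, character(1))
  ids <- ids[!is.na(ids)]
  for (d in unique(cols[duplicated(cols)]))
    out <- bindIssues(out, newIssue("FVCF-COL-004",
      sprintf("sample column '%s' appears %d times", d, sum(cols == d)),
      line = hl@lineNumber, observed = d))
  for (cn in unique(cols)) {
    if (!cn %in% ids)
      out <- bindIssues(out, newIssue("FVCF-COL-001",
        sprintf("sample column '%s' has no ##SAMPLE record", cn),
        line = hl@lineNumber, observed = cn))
    if (nrow(validateBiosampleId(cn)))
      out <- bindIssues(out, newIssue("FVCF-COL-003",
        sprintf("sample column '%s' is not a BioSample accession", cn),
        line = hl@lineNumber, observed = cn))
  }
  for (id in setdiff(ids, cols))
    out <- bindIssues(out, newIssue("FVCF-COL-002",
      sprintf("##SAMPLE '%s' has no matching sample column", id),
      observed = id))
  out
}

#' Check data-line positions against declared contig bounds
#'
#' Positions are 1-based and valid within `[1, length]` inclusive
#' (`POS == length` is valid; `POS == length + 1` is not). `POS 0`, the
#' telomeric convention, draws a warning. Lines on a chromosome with no
#' contig declaration are aggregated into one error per unknown name with
#' a count; lines on contigs lacking a declared length are skipped for
#' the bound check with a single info notice per contig.
#'
#' @param cores Data frame of data-line cores (`line`, `chrom`, `pos`),
#'   as produced by [streamDataCores()].
#' @param header A [FairHeader-class].
#' @return A data frame of issues.
#' @export
checkPositions <- function(cores, header) {
  stopifnot(is.data.frame(cores), is(header, "FairHeader"))
  out <- emptyIssues()
  cts <- contigs(header)
  ids <- vapply(cts, function(c) c@id, character(1))
  lens <- vapply(cts, function(c) c@length, numeric(1))
  known <- !is.na(ids)
  ids <- ids[known]; lens <- lens[known]
  if (!nrow(cores)) return(out)
  m <- match(cores$chrom, ids)
  unknown <- is.na(m)
  if (any(unknown)) {
    tab <- table(cores$chrom[unknown])
    for (nm in names(tab))
      out <- bindIssues(out, newIssue("FVCF-POS-001",
        sprintf("chromosome '%s' has no contig declaration (%d data line(s))",
                nm, tab[[nm]]),
        line = cores$line[unknown & cores$chrom == nm][1], observed = nm))
  }
  kc <- cores[!unknown, , drop = FALSE]
  km <- m[!unknown]
  if (!nrow(kc)) return(out)
  zero <- kc$pos == 0
  for (i in which(zero))
    out <- bindIssues(out, newIssue("FVCF-POS-003",
      sprintf("POS 0 on '%s' (telomeric convention)", kc$chrom[i]),
      line = kc$line[i], observed = "0"))
  noLen <- is.na(lens[km])
  for (nm in unique(kc$chrom[noLen & !zero]))
    out <- bindIssues(out, newIssue("FVCF-POS-004",
      sprintf("contig '%s' has no declared length; bound check skipped", nm),
      observed = nm))
  checkable <- !noLen & !zero
  oob <- checkable & (kc$pos < 1 | kc$pos > lens[km])
  for (i in which(oob))
    out <- bindIssues(out, newIssue("FVCF-POS-002",
      sprintf("POS %s on '%s' outside [1, %s]",
              format(kc$pos[i], scientific = FALSE), kc$chrom[i],
              format(lens[km][i], scientific = FALSE)),
      line = kc$line[i], observed = format(kc$pos[i], scientific = FALSE)))
  out
}
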