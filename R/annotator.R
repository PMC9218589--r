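# Construct or repair FAIR metadata in an existing VCF.

contigToMeta <- function(ct) {
  keys <- c("ID", "length", "assembly", "md5", "species")
  vals <- c(ct@id, if (is.na(ct@length)) NA
            else format(ct@length, scientific = FALSE),
            ct@assembly, ct@md5, ct@species)
  keep <- !is.na(vals)
  structuredMeta("contig", keys[keep], vals[keep],
                 quoted = rep(FALSE, sum(keep)))
}

# DOI and ext_ID values are always emitted quoted, matching the profile's
# worked examples; multiple external IDs use repeated ext_ID keys.
sampleToMeta <- function(sm) {
  keys <- "ID"; vals <- sm@id; quo <- FALSE
  if (!is.na(sm@doi)) {
    keys <- c(keys, "DOI"); vals <- c(vals, sm@doi); quo <- c(quo, TRUE)
  }
  for (e in sm@extIds) {
    keys <- c(keys, "ext_ID"); vals <- c(vals, e$raw); quo <- c(quo, TRUE)
  }
  structuredMeta("SAMPLE", keys, vals, quoted = quo)
}

#' Derive contig records from a reference index
#'
#' Builds one fully populated [ContigRecord-class] per indexed sequence,
#' in index order, attaching the supplied assembly accession and taxon to
#' each. The accession and taxon must pass their grammars; records
#' derived this way re-validate cleanly against the same FASTA.
#'
#' @param index A [ReferenceIndex-class].
#' @param assembly INSDC assembly accession (`GCA_`/`GCF_` form).
#' @param species Prefixed taxon, e.g. `"NCBITaxon:4513"`.
#' @return A list of [ContigRecord-class] objects.
#' @examples
#' idx <- buildReferenceIndex(c(">chrT", "ACGTACGTAC"))
#' deriveContigs(idx, "GCA_000000001.1", "NCBITaxon:4513")
#' @export
deriveContigs <- function(index, assembly, species) {
  stopifnot(is(index, "ReferenceIndex"))
  if (!nrow(index@table))
    fvcfError("fvcf_empty_index", "reference index has no sequences")
  iss <- bindIssues(validateAssemblyAccession(assembly),
                    validateTaxon(species))
  if (any(iss$severity == "error"))
    fvcfError("fvcf_invalid_fragment",
              paste("invalid contig attributes:",
                    paste(iss$message, collapse = "; ")))
  lapply(seq_len(nrow(index@table)), function(i)
    new("ContigRecord", id = index@table$name[i],
        length = index@table$length[i], assembly = assembly,
        md5 = index@table$md5[i], species = species,
        lineNumber = NA_integer_))
}

#' Assemble a metadata fragment for injection
#'
#' Bundles the scalar profile fields and contig/SAMPLE records to be
#' injected into a VCF header. Every supplied element is validated
#' against its field grammar; an element with an error-level violation
#' makes the constructor fail (classed error `fvcf_invalid_fragment`), so
#' only compliant fragments can reach [injectMetadata()].
#'
#' @param fileDate Creation date, `YYYYMMDD`.
#' @param bioinformaticsSource URL/DOI of the pipeline description.
#' @param referenceAc Assembly accession of the reference.
#' @param referenceUrl Download locator of the reference FASTA.
#' @param contigs List of [ContigRecord-class] objects.
#' @param samples List of [SampleRecord-class] objects.
#' @return An object of class `FairFragment` (a validated list).
#' @export
fairFragment <- function(fileDate = NULL, bioinformaticsSource = NULL,
                         referenceAc = NULL, referenceUrl = NULL,
                         contigs = NULL, samples = NULL) {
  iss <- emptyIssues()
  if (!is.null(fileDate)) iss <- bindIssues(iss, validateFileDate(fileDate))
  if (!is.null(bioinformaticsSource))
    iss <- bindIssues(iss, validateUrlOrDoi(bioinformaticsSource))
  if (!is.null(referenceAc))
    iss <- bindIssues(iss, validateAssemblyAccession(referenceAc))
  if (!is.null(referenceUrl))
    iss <- bindIssues(iss, validateUrlOrDoi(referenceUrl))
  if (!is.null(contigs)) {
    stopifnot(all(vapply(contigs, is, logical(1), "ContigRecord")))
    for (ct in contigs) {
      if (is.na(ct@id)) iss <- bindIssues(iss, newIssue("FVCF-STRUCT-001",
        "fragment contig without ID"))
      if (!is.na(ct@species))
        iss <- bindIssues(iss, validateTaxon(ct@species))
      if (!is.na(ct@assembly))
        iss <- bindIssues(iss, validateAssemblyAccession(ct@assembly))
    }
  }
  if (!is.null(samples)) {
    stopifnot(all(vapply(samples, is, logical(1), "SampleRecord")))
    for (sm in samples) {
      if (is.na(sm@id)) iss <- bindIssues(iss, newIssue("FVCF-STRUCT-001",
        "fragment SAMPLE without ID"))
      else iss <- bindIssues(iss, validateBiosampleId(sm@id))
      if (!is.na(sm@doi)) iss <- bindIssues(iss, validateUrlOrDoi(sm@doi))
      for (e in sm@extIds) iss <- bindIssues(iss, e$issues)
    }
  }
  if (any(iss$severity == "error"))
    fvcfError("fvcf_invalid_fragment",
              paste("fragment fails validation:",
                    paste(unique(iss$message), collapse = "; ")))
  structure(list(fileDate = fileDate,
                 bioinformaticsSource = bioinformaticsSource,
                 referenceAc = referenceAc, referenceUrl = referenceUrl,
                 contigs = contigs, samples = samples),
            class = "FairFragment")
}

scalarFragmentLine <- function(canonical, value) {
  quotedFields <- c("bioinformatics_source", "reference_url")
  v <- if (canonical %in% quotedFields) paste0("\"", value, "\"") else value
  paste0("##", canonical, "=", v)
}

#' Inject FAIR metadata into a VCF
#'
#' Rewrites the header of a VCF so that the profile fields appear in a
#' deterministic order — `##fileformat` first, then `##fileDate`,
#' `##bioinformatics_source`, `##reference_ac`, `##reference_url`, the
#' contig lines, the SAMPLE lines, then every remaining pre-existing meta
#' line in original order, the column header line, and the data lines
#' byte-for-byte unchanged. An existing line with the same key is
#' replaced only when `replace = TRUE`; otherwise it is kept and the
#' conflict counted. A missing `##fileformat` is synthesized as
#' `VCFv4.3`.
#'
#' @param vcfIn Path to the input VCF (plain or gzip).
#' @param fragment A `FairFragment` from [fairFragment()].
#' @param vcfOut Path of the output VCF (written plain).
#' @param replace Replace conflicting existing lines instead of keeping
#'   them.
#' @return Invisibly, a list with counts `added`, `replaced`, `kept`
#'   (conflicting lines only).
#' @export
injectMetadata <- function(vcfIn, fragment, vcfOut, replace = FALSE) {
  if (!inherits(fragment, "FairFragment"))
    fvcfError("fvcf_invalid_fragment",
              "fragment must come from fairFragment()")
  con <- asLineSource(vcfIn, "VCF source")
  on.exit(close(con), add = TRUE)
  # -- pull in the header section
  metaRaw <- character(); metaKey <- character()
  headerRaw <- NULL; pending <- character()
  repeat {
    lines <- readLines(con, n = 512L)
    if (!length(lines)) break
    stop <- FALSE
    for (k in seq_along(lines)) {
      ln <- lines[k]
      if (startsWith(ln, "##")) {
        metaRaw <- c(metaRaw, ln)
        key <- sub("^##([^=]*)=?.*$", "\\1", ln)
        canon <- .canonicalKey(key)
        metaKey <- c(metaKey, if (is.na(canon)) "" else canon)
      } else if (startsWith(ln, "#")) {
        headerRaw <- ln
        if (k < length(lines)) pending <- lines[(k + 1L):length(lines)]
        stop <- TRUE; break
      } else {
        pending <- lines[k:length(lines)]
        stop <- TRUE; break
      }
    }
    if (stop) break
  }
  added <- 0L; replaced <- 0L; kept <- 0L
  consumed <- logical(length(metaRaw))
  out <- character()
  takeExisting <- function(canon) {
    i <- which(metaKey == canon & !consumed)
    consumed[i] <<- TRUE
    metaRaw[i]
  }
  # fileformat first
  ff <- takeExisting("fileformat")
  if (length(ff)) out <- c(out, ff)
  else { out <- c(out, "##fileformat=VCFv4.3"); added <- added + 1L }
  scalars <- c(fileDate = "fileDate",
               bioinformaticsSource = "bioinformatics_source",
               referenceAc = "reference_ac",
               referenceUrl = "reference_url")
  for (el in names(scalars)) {
    canon <- scalars[[el]]
    ex <- takeExisting(canon)
    fr <- fragment[[el]]
    if (!is.null(fr)) {
      if (length(ex)) {
        if (replace) {
          out <- c(out, scalarFragmentLine(canon, fr))
          replaced <- replaced + length(ex)
        } else {
          out <- c(out, ex); kept <- kept + length(ex)
        }
      } else {
        out <- c(out, scalarFragmentLine(canon, fr)); added <- added + 1L
      }
    } else out <- c(out, ex)
  }
  for (blk in list(list(canon = "contig", recs = fragment$contigs,
                        ser = contigToMeta),
                   list(canon = "SAMPLE", recs = fragment$samples,
                        ser = sampleToMeta))) {
    ex <- takeExisting(blk$canon)
    if (!is.null(blk$recs)) {
      newLines <- vapply(blk$recs,
                         function(r) serializeMeta(blk$ser(r)), character(1))
      if (length(ex)) {
        if (replace) {
          out <- c(out, newLines); replaced <- replaced + length(ex)
        } else {
          out <- c(out, ex); kept <- kept + length(ex)
        }
      } else {
        out <- c(out, newLines); added <- added + length(newLines)
      }
    } else out <- c(out, ex)
  }
  out <- c(out, metaRaw[!consumed])
  if (!is.null(headerRaw)) out <- c(out, headerRaw)
  # -- data region, copied unchanged
  ocon <- file(vcfOut, open = "wb")
  on.exit(close(ocon), add = TRUE)
  writeLines(out, ocon, sep = "\n")
  if (length(pending)) writeLines(pending, ocon, sep = "\n")
  repeat {
    lines <- readLines(con, n = 5000L)
    if (!length(lines)) break
    writeLines(lines, ocon, sep = "\n")
  }
  invisible(list(added = added, replaced = replaced, kept = kept))
}

#' Rename sample columns to BioSample accessions
#'
#' Rewrites the sample columns of the header line according to `mapping`
#' (old name to BioSample accession), adds a `##SAMPLE` record for every
#' renamed column that lacks one, and leaves the data lines untouched.
#' All mapping keys must be current columns (`fvcf_unknown_column`
#' otherwise), all values must pass the BioSample grammar, and the
#' resulting column set must be free of duplicates
#' (`fvcf_duplicate_target`).
#'
#' @param vcfIn Path to the input VCF.
#' @param mapping Named character vector: `names` are current column
#'   names, values the replacement accessions.
#' @param vcfOut Path of the output VCF.
#' @return Invisibly, the number of renamed columns.
#' @export
renameSampleColumns <- function(vcfIn, mapping, vcfOut) {
  stopifnot(is.character(mapping))
  if (length(mapping) && is.null(names(mapping)))
    fvcfError("fvcf_unknown_column", "mapping must be named (old -> new)")
  for (v in mapping)
    if (nrow(validateBiosampleId(v)))
      fvcfError("fvcf_invalid_fragment",
                sprintf("'%s' is not a valid BioSample accession", v))
  if (anyDuplicated(unname(mapping)))
    fvcfError("fvcf_duplicate_target",
              "two columns mapped to the same accession")
  con <- asLineSource(vcfIn, "VCF source")
  on.exit(close(con), add = TRUE)
  ocon <- file(vcfOut, open = "wb")
  on.exit(close(ocon), add = TRUE)
  headerMeta <- character()
  headerRaw <- NULL; pending <- character()
  repeat {
    lines <- readLines(con, n = 512L)
    if (!length(lines)) break
    stop <- FALSE
    for (k in seq_along(lines)) {
      ln <- lines[k]
      if (startsWith(ln, "##")) headerMeta <- c(headerMeta, ln)
      else if (startsWith(ln, "#")) {
        headerRaw <- ln
        if (k < length(lines)) pending <- lines[(k + 1L):length(lines)]
        stop <- TRUE; break
      } else {
        pending <- lines[k:length(lines)]
        stop <- TRUE; break
      }
    }
    if (stop) break
  }
  nRenamed <- 0L
  if (length(mapping)) {
    if (is.null(headerRaw))
      fvcfError("fvcf_unknown_column", "VCF has no column header line")
    hl <- parseHeaderLine(headerRaw)
    unknown <- setdiff(names(mapping), hl@samples)
    if (length(unknown))
      fvcfError("fvcf_unknown_column",
                sprintf("column(s) not present: %s",
                        paste(unknown, collapse = ", ")))
    newCols <- hl@samples
    hit <- newCols %in% names(mapping)
    newCols[hit] <- unname(mapping[newCols[hit]])
    nRenamed <- sum(hit)
    if (anyDuplicated(newCols))
      fvcfError("fvcf_duplicate_target",
                "renaming would duplicate a sample column")
    headerRaw <- paste(c(hl@fixed, newCols), collapse = "\t")
    existing <- vapply(headerMeta, function(x) {
      m <- parseMetaLine(x)
      if (is(m, "StructuredMeta") &&
          identical(.canonicalKey(m@recordType), "SAMPLE")) {
        id <- m@attributes$value[m@attributes$key == "ID"]
        if (length(id)) id[1] else NA_character_
      } else NA_character_
    }, character(1), USE.NAMES = FALSE)
    toAdd <- setdiff(unname(mapping), existing[!is.na(existing)])
    for (id in toAdd)
      headerMeta <- c(headerMeta,
                      serializeMeta(sampleToMeta(new("SampleRecord",
                                                     id = id))))
  }
  writeLines(headerMeta, ocon, sep = "\n")
  if (!is.null(headerRaw)) writeLines(headerRaw, ocon, sep = "\n")
  if (length(pending)) writeLines(pending, ocon, sep = "\n")
  repeat {
    lines <- readLines(con, n = 5000L)
    if (!length(lines)) break
    writeLines(lines, ocon, sep = "\n")
  }
  invisible(nRenamed)
}

#' One-call annotation of a VCF against its reference
#'
#' Convenience wrapper: indexes the FASTA, derives fully populated contig
#' records, builds SAMPLE records for every sample column that lacks one,
#' assembles the scalar fields into a fragment, and injects everything
#' with `replace = TRUE`. The output validates cleanly (strict mode)
#' against the same FASTA when the sample columns are BioSample
#' accessions.
#'
#' @param vcfIn,vcfOut Input and output VCF paths.
#' @param fasta Reference FASTA (path or text).
#' @param assembly,species Passed to [deriveContigs()].
#' @param fileDate Creation date (`YYYYMMDD`); defaults to today.
#' @param bioinformaticsSource,referenceUrl Scalar locator fields.
#' @return Invisibly, the injection summary.
#' @export
annotateVcf <- function(vcfIn, vcfOut, fasta, assembly, species,
                        fileDate = format(Sys.Date(), "%Y%m%d"),
                        bioinformaticsSource, referenceUrl) {
  idx <- buildReferenceIndex(fasta)
  cts <- deriveContigs(idx, assembly, species)
  hdr <- readFairHeader(vcfIn)
  hl <- headerLine(hdr)
  haveIds <- vapply(samples(hdr), function(s) s@id, character(1))
  smpls <- samples(hdr)
  if (!is.null(hl))
    for (cn in setdiff(hl@samples, haveIds))
      smpls <- c(smpls, new("SampleRecord", id = cn))
  frag <- fairFragment(fileDate = fileDate,
                       bioinformaticsSource = bioinformaticsSource,
                       referenceAc = assembly,
                       referenceUrl = referenceUrl,
                       contigs = cts,
                       samples = if (length(smpls)) smpls else NULL)
  injectMetadata(vcfIn, frag, vcfOut, replace = TRUE)
}
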