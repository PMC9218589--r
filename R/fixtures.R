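# Deterministic toy references and VCFs at three compliance profiles.
# Synthetic BioSample accessions use the high-numbered SAMEA9xxxxxxx
# range: grammatical, but not registered samples.

.FIXTURE_ASSEMBLY <- "GCA_000000001.1"
.FIXTURE_SPECIES <- "NCBITaxon:4513"

#' Generate a toy reference FASTA
#'
#' Seeded uniform-random A/C/G/T sequences named `chr1..chrN`, wrapped at
#' 60 columns. Identical arguments and seed give byte-identical output.
#'
#' @param nSeqs Number of sequences; must equal `length(lengths)`.
#' @param lengths Sequence lengths in bp (each at least 1).
#' @param seed RNG seed.
#' @return Character vector of FASTA lines.
#' @examples
#' makeReference(2, c(100, 50), seed = 42)
#' @export
makeReference <- function(nSeqs, lengths, seed) {
  if (length(lengths) != nSeqs)
    fvcfError("fvcf_argument_mismatch",
              "nSeqs must equal length(lengths)")
  if (any(lengths < 1))
    fvcfError("fvcf_argument_mismatch", "lengths must be >= 1")
  withLocalSeed(seed, {
    out <- character()
    for (i in seq_len(nSeqs)) {
      s <- paste(sample(c("A", "C", "G", "T"), lengths[i],
                        replace = TRUE), collapse = "")
      starts <- seq(1L, nchar(s), by = 60L)
      body <- substring(s, starts, pmin(starts + 59L, nchar(s)))
      out <- c(out, paste0(">chr", i), body)
    }
    out
  })
}

fixtureSampleRecords <- function(ids) {
  lapply(seq_along(ids), function(i) {
    ext <- if (i %% 2L == 1L)
      sprintf("DEU146:Hordeum:HOR %d BRG", 1000L + i)
    else
      sprintf("genebank.example.org:GBIS:accessionId:%d", 7000000L + i)
    new("SampleRecord", id = ids[i],
        doi = sprintf("doi.org/10.5072/synthetic/%s", ids[i]),
        extIds = list(extIdRecord(ext)))
  })
}

#' Generate a toy VCF at a compliance profile
#'
#' Builds a VCF against `reference` at one of three profiles. `"fair"`
#' carries all six recommended fields, contig lines with real lengths and
#' digests derived from the reference, SAMPLE records with synthetic
#' (grammatical, unregistered) BioSample accessions, and sorted in-bounds
#' positions — it validates with zero errors and zero warnings.
#' `"missing_fields"` drops a seeded subset of the recommended scalar
#' fields (warnings only). `"malformed"` plants four known defects — a
#' separator-bearing date, a short assembly-accession digit block, an
#' out-of-bounds position, and a duplicated contig ID — and lists them in
#' the returned manifest.
#'
#' @param reference FASTA text (e.g. from [makeReference()]) or a path.
#' @param nSamples Number of genotype columns (0 for a frequency-only
#'   file without FORMAT).
#' @param nVariants Number of data lines (0 for a header-only file).
#' @param seed RNG seed; identical arguments and seed give identical
#'   bytes.
#' @param profile One of `"fair"`, `"missing_fields"`, `"malformed"`.
#' @return A list of class `fvcfFixture`: `vcf` (character lines),
#'   `manifest` (data frame `rule_id`, `field`, `detail`; planted defects,
#'   empty for `"fair"`), `profile`, `seed`.
#' @examples
#' fx <- makeVcf(makeReference(2, c(200, 100), 1), 2, 10, 1, "fair")
#' fx$manifest
#' @export
makeVcf <- function(reference, nSamples, nVariants, seed,
                    profile = c("fair", "missing_fields", "malformed")) {
  profile <- match.arg(profile)
  stopifnot(nVariants >= 0, nSamples >= 0)
  idx <- buildReferenceIndex(reference)
  cts <- deriveContigs(idx, .FIXTURE_ASSEMBLY, .FIXTURE_SPECIES)
  lens <- refLengths(idx)
  withLocalSeed(seed, {
    ids <- if (nSamples > 0)
      sprintf("SAMEA9%07d", sample.int(9999999L, nSamples)) else character()
    scalarLines <- c(
      fileDate = "##fileDate=20240101",
      bioinformatics_source =
        "##bioinformatics_source=\"doi.org/10.5072/fvcf.synthetic.pipeline\"",
      reference_ac = paste0("##reference_ac=", .FIXTURE_ASSEMBLY),
      reference_url = paste0("##reference_url=\"example.org/synthetic/",
                             .FIXTURE_ASSEMBLY, "_genomic.fna.gz\""))
    contigLines <- vapply(cts, function(ct) serializeMeta(contigToMeta(ct)),
                          character(1))
    sampleLines <- vapply(fixtureSampleRecords(ids),
                          function(s) serializeMeta(sampleToMeta(s)),
                          character(1))
    fixed <- if (nSamples > 0) .MANDATORY_COLUMNS
             else .MANDATORY_COLUMNS[1:8]
    headerLine <- paste(c(fixed, ids), collapse = "\t")
    # in-bounds sorted variant positions, allocated across contigs
    dataLines <- character()
    if (nVariants > 0) {
      alloc <- table(factor(sample.int(length(lens), nVariants,
                                       replace = TRUE, prob = lens),
                            levels = seq_along(lens)))
      for (ci in seq_along(lens)) {
        k <- min(alloc[[ci]], lens[[ci]])
        if (!k) next
        pos <- sort(sample.int(lens[[ci]], k))
        ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
        alt <- vapply(ref, function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
        gt <- if (nSamples > 0)
          vapply(seq_len(k), function(z)
            paste(sample(c("0/0", "0/1", "1/1"), nSamples,
                         replace = TRUE), collapse = "\t"), character(1))
        info <- if (nSamples > 0) "."
                else sprintf("AF=%.2f", round(stats::runif(k), 2))
        core <- paste(names(lens)[ci], pos, ".", ref, alt, ".", ".",
                      info, sep = "\t")
        dataLines <- c(dataLines,
                       if (nSamples > 0) paste(core, "GT", gt, sep = "\t")
                       else core)
      }
    }
    manifest <- data.frame(rule_id = character(), field = character(),
                           detail = character(), stringsAsFactors = FALSE)
    if (profile == "missing_fields") {
      dropN <- sample(1:3, 1L)
      dropped <- sample(names(scalarLines), dropN)
      scalarLines <- scalarLines[!names(scalarLines) %in% dropped]
      manifest <- data.frame(rule_id = "FVCF-CARD-001",
                             field = paste0("##", dropped),
                             detail = "recommended field removed",
                             stringsAsFactors = FALSE)
    } else if (profile == "malformed") {
      scalarLines[["fileDate"]] <- "##fileDate=2012-09-21"
      scalarLines[["reference_ac"]] <- "##reference_ac=GCA_1234.1"
      contigLines <- c(contigLines, contigLines[1])
      badPos <- lens[[1]] + 1
      badCore <- paste(names(lens)[1],
                       format(badPos, scientific = FALSE), ".", "A", "T",
                       ".", ".",
                       if (nSamples > 0) "." else "AF=0.50", sep = "\t")
      if (nSamples > 0)
        badCore <- paste(badCore, "GT",
                         paste(rep("0/1", nSamples), collapse = "\t"),
                         sep = "\t")
      dataLines <- c(dataLines, badCore)
      manifest <- data.frame(
        rule_id = c("FVCF-DATE-001", "FVCF-ACC-001", "FVCF-UNIQ-001",
                    "FVCF-POS-002"),
        field = c("##fileDate", "##reference_ac", "##contig",
                  "data lines"),
        detail = c("separator-bearing date planted",
                   "accession with short digit block planted",
                   sprintf("contig '%s' duplicated", names(lens)[1]),
                   sprintf("POS %s beyond contig '%s' length %s",
                           format(badPos, scientific = FALSE),
                           names(lens)[1],
                           format(lens[[1]], scientific = FALSE))),
        stringsAsFactors = FALSE)
    }
    vcf <- c("##fileformat=VCFv4.3", unname(scalarLines), contigLines,
             sampleLines, headerLine, dataLines)
    structure(list(vcf = vcf, manifest = manifest, profile = profile,
                   seed = seed),
              class = "fvcfFixture")
  })
}

#' Write a fixture set to a directory
#'
#' Materializes a seeded reference FASTA, a VCF at the requested
#' compliance profile, and the planted-defect manifest (JSON) beside it.
#'
#' @param outDir Output directory (created if needed).
#' @param seed RNG seed.
#' @param profile Compliance profile, see [makeVcf()].
#' @param nSeqs,lengths,nSamples,nVariants Fixture dimensions.
#' @return Invisibly, a named list of the written paths.
#' @export
writeFixtures <- function(outDir, seed,
                          profile = c("fair", "missing_fields",
                                      "malformed"),
                          nSeqs = 2L, lengths = c(500L, 300L),
                          nSamples = 3L, nVariants = 20L) {
  profile <- match.arg(profile)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ref <- makeReference(nSeqs, lengths, seed)
  fx <- makeVcf(ref, nSamples, nVariants, seed, profile)
  refPath <- file.path(outDir, "reference.fa")
  vcfPath <- file.path(outDir, paste0(profile, ".vcf"))
  manifestPath <- file.path(outDir, paste0(profile, ".manifest.json"))
  writeTextFile(ref, refPath)
  writeTextFile(fx$vcf, vcfPath)
  jsonlite::write_json(fx$manifest, manifestPath, dataframe = "rows",
                       pretty = TRUE)
  invisible(list(reference = refPath, vcf = vcfPath,
                 manifest = manifestPath))
}
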