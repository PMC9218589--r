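test_that("file dates accept basic YYYYMMDD and reject variants", {
  expect_identical(nrow(validateFileDate("20120921")), 0L)
  expect_identical(nrow(validateFileDate("20200229")), 0L) # leap day
  expect_identical(validateFileDate("2012-09-21")$rule_id, "FVCF-DATE-001")
  expect_match(validateFileDate("2012-09-21")$message, "separator")
  expect_identical(validateFileDate("20121341")$rule_id, "FVCF-DATE-002")
  expect_identical(validateFileDate("20210229")$rule_id, "FVCF-DATE-002")
  expect_identical(validateFileDate("923")$rule_id, "FVCF-DATE-001")
})

test_that("assembly accessions require GCA/GCF, 9 digits and a version", {
  for (ok in c("GCA_902498975.1", "GCA_000001405.26", "GCF_000001405.26",
               "GCA_000005005.5"))
    expect_identical(nrow(validateAssemblyAccession(ok)), 0L)
  for (bad in c("GCA_1234.1", "GCB_000000001.1", "GCA_000000001",
                "GCA_000000001.", "gca_000000001.1", "GCA-000000001.1"))
    expect_identical(validateAssemblyAccession(bad)$rule_id, "FVCF-ACC-001")
})

test_that("URL/DOI locators accept schemed and scheme-less forms", {
  doi <- validateUrlOrDoi("doi.org/10.1038/s41588-018-0266-x")
  expect_identical(nrow(doi), 0L)
  expect_identical(attr(doi, "kind"), "doi")
  url <- validateUrlOrDoi("github.com/gramarga/tassel4-poly")
  expect_identical(nrow(url), 0L)
  expect_identical(attr(url, "kind"), "url")
  expect_identical(nrow(validateUrlOrDoi("https://example.org/x")), 0L)
  expect_identical(nrow(validateUrlOrDoi("ftp://example.org/x")), 0L)
  expect_identical(nrow(validateUrlOrDoi("doi:10.1000/xyz")), 0L)
  expect_identical(validateUrlOrDoi("not a url")$rule_id, "FVCF-URL-001")
  expect_identical(validateUrlOrDoi("")$rule_id, "FVCF-URL-001")
  expect_identical(validateUrlOrDoi("nodothost")$rule_id, "FVCF-URL-001")
})

test_that("BioSample accessions follow SAM + E/N/D + optional A/G + digits", {
  for (ok in c("SAMEA104646767", "SAMN0000123", "SAMD1", "SAMEG123"))
    expect_identical(nrow(validateBiosampleId(ok)), 0L)
  for (bad in c("SAM104646767", "SAMX123", "SAMEA", "samea123",
                "SAMEAB123", "SAMEA12x"))
    expect_identical(validateBiosampleId(bad)$rule_id, "FVCF-BIOS-001")
})

test_that("taxon identifiers distinguish fixable from hard violations", {
  expect_identical(nrow(validateTaxon("NCBITaxon:4513")), 0L)
  expect_identical(nrow(validateTaxon("NCBITaxon:4577")), 0L)
  expect_identical(validateTaxon("4513")$rule_id, "FVCF-TAX-002")
  expect_identical(validateTaxon("taxon:4513")$rule_id, "FVCF-TAX-003")
  expect_identical(validateTaxon("ncbitaxon:4513")$rule_id, "FVCF-TAX-003")
  expect_identical(validateTaxon("Hordeum vulgare")$rule_id, "FVCF-TAX-001")
  expect_identical(unique(validateTaxon("4513")$severity), "warning")
})

test_that("external IDs parse into the two dialects by arity", {
  f <- parseExtId("DEU146:Hordeum:HOR 1361 BRG")
  expect_identical(f$dialect, "faowiews")
  expect_identical(unname(f$parts["instcode"]), "DEU146")
  expect_identical(unname(f$parts["accession_number"]), "HOR 1361 BRG")
  expect_identical(nrow(f$issues), 0L)

  d <- parseExtId("ipk-gatersleben.de:GBIS:akzessionId:7811152")
  expect_identical(d$dialect, "dns")
  expect_identical(unname(d$parts["dns_name"]), "ipk-gatersleben.de")
  expect_identical(unname(d$parts["identifier"]), "7811152")

  expect_error(parseExtId("a:b"), class = "fvcf_extid_arity")
  expect_error(parseExtId("a:b:c:d:e"), class = "fvcf_extid_arity")

  odd <- parseExtId("notacode:Hordeum:X 1")
  expect_identical(odd$issues$rule_id, "FVCF-EXTID-002")
  expect_identical(unique(odd$issues$severity), "warning")
})

test_that("SAMPLE lines accept both repeated ext_ID keys and comma-joined values", {
  hdr <- readFairHeader(c(
    "##fileformat=VCFv4.3",
    "##SAMPLE=<ID=SAMEA1,ext_ID=\"DEU146:Hordeum:A 1\",ext_ID=\"ipk.de:GBIS:acc:1\">",
    "##SAMPLE=<ID=SAMEA2,ext_ID=\"DEU146:Hordeum:B 2,ipk.de:GBIS:acc:2\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  expect_length(samples(hdr)[[1]]@extIds, 2L)
  expect_length(samples(hdr)[[2]]@extIds, 2L)
  expect_identical(samples(hdr)[[2]]@extIds[[2]]$dialect, "dns")
})

test_that("cardinalities: exactly-once scalars, at-least-once records", {
  full <- c("##fileformat=VCFv4.3", "##fileDate=20240101",
            "##bioinformatics_source=\"doi.org/10.5072/x\"",
            "##reference_ac=GCA_000000001.1",
            "##reference_url=\"example.org/r/f.fa.gz\"",
            "##contig=<ID=c1,length=10>",
            "##SAMPLE=<ID=SAMEA1>",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  expect_identical(nrow(checkCardinalities(readFairHeader(full))), 0L)

  dup <- append(full, "##reference_ac=GCA_000000002.1", after = 4)
  iss <- checkCardinalities(readFairHeader(dup))
  expect_identical(iss$rule_id, "FVCF-CARD-002")
  expect_identical(iss$severity, "error")

  noff <- readFairHeader(full[-1])
  expect_true("FVCF-CARD-003" %in% checkCardinalities(noff)$rule_id)

  bare <- readFairHeader(c("##fileformat=VCFv4.3",
                           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  iss2 <- checkCardinalities(bare)
  expect_identical(sum(iss2$rule_id == "FVCF-CARD-001"), 4L)
  expect_true(all(c("FVCF-CARD-004", "FVCF-CARD-005") %in% iss2$rule_id))
  expect_true(all(iss2$severity == "warning"))
})

test_that("ID uniqueness is enforced within, not across, line types", {
  h <- readFairHeader(c("##fileformat=VCFv4.3",
                        "##contig=<ID=chr1H,length=10>",
                        "##contig=<ID=chr1H,length=10>",
                        "##SAMPLE=<ID=chr1H>",
                        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  iss <- checkUniqueness(h)
  expect_identical(iss$rule_id, "FVCF-UNIQ-001")
  expect_match(iss$message, "chr1H")

  distinct <- readFairHeader(c("##fileformat=VCFv4.3",
    sprintf("##contig=<ID=c%d,length=10>", 1:7),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  expect_identical(nrow(checkUniqueness(distinct)), 0L)
})

test_that("validators are pure: repeated calls give identical issue lists", {
  inputs <- list(validateFileDate, validateAssemblyAccession,
                 validateUrlOrDoi, validateBiosampleId, validateTaxon)
  values <- c("20121341", "GCA_1234.1", "not a url", "SAM1", "x:1")
  for (i in seq_along(inputs)) {
    a <- inputs[[i]](values[i]); b <- inputs[[i]](values[i])
    attr(a, "kind") <- NULL; attr(b, "kind") <- NULL
    expect_identical(a, b)
  }
})

test_that("every emitted rule id is in the catalogue, and the catalogue is well-formed", {
  cat <- ruleCatalogue()
  expect_true(all(nchar(cat$rule_id) > 0 & nchar(cat$description) > 0))
  expect_true(all(cat$severity %in% c("error", "warning", "info")))
  expect_false(anyDuplicated(cat$rule_id) > 0)

  ref <- makeReference(2, c(300, 200), 77)
  emitted <- character()
  for (p in c("fair", "missing_fields", "malformed")) {
    fx <- makeVcf(ref, 2, 15, 77, p)
    rep <- runValidation(fx$vcf, fasta = ref)
    emitted <- c(emitted, issues(rep)$rule_id)
  }
  # plus some adversarial content
  bad <- c("##fileformat=VCFv4.3", "##filedate=2012-09-21",
           "##reference=GCA_000000001.1",
           "##contig=<length=abc,md5=xyz,species=4513>",
           "##SAMPLE=<ID=bad id,DOI=\"x\",DOI=\"y\",ext_ID=\"a:b\">",
           "#CHROM\tPOS", "chrZ\t0\t.", "chrZ\tNaN\t.")
  emitted <- c(emitted, issues(runValidation(bad))$rule_id)
  expect_true(all(emitted %in% cat$rule_id))
})
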