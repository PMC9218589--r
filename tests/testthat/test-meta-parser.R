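test_that("structured and unstructured meta lines parse into the right shapes", {
  s <- parseMetaLine(
    "##contig=<ID=chr1H,length=522466905,assembly=GCA_902498975.1,md5=8d21a35cc68340ecf40e2a8dec9428fa,species=NCBITaxon:4513>",
    3L)
  expect_s4_class(s, "StructuredMeta")
  expect_identical(s@recordType, "contig")
  expect_identical(nrow(s@attributes), 5L)
  expect_identical(s@attributes$value[s@attributes$key == "length"],
                   "522466905")
  expect_identical(lineNumber(s), 3L)

  m <- parseMetaLine("##fileformat=VCFv4.3", 1L)
  expect_s4_class(m, "MetaLine")
  expect_identical(m@key, "fileformat")
  expect_identical(m@value, "VCFv4.3")
})

test_that("commas and '=' inside double quotes do not split attributes", {
  s <- parseMetaLine("##SAMPLE=<ID=S1,DOI=\"doi.org/10.1000/a,b\">", 1L)
  expect_s4_class(s, "StructuredMeta")
  expect_identical(nrow(s@attributes), 2L)
  expect_identical(s@attributes$value[2], "doi.org/10.1000/a,b")
  expect_true(s@attributes$quoted[2])
  expect_false(s@attributes$quoted[1])

  # cross-check against the independent reference splitter
  ref <- referenceSplit("ID=S1,DOI=\"doi.org/10.1000/a,b\"")
  expect_identical(s@attributes$key, ref$key)
  expect_identical(s@attributes$value, ref$value)
})

test_that("backslash escapes for quote and backslash are honoured and round-trip", {
  raw <- "##SAMPLE=<ID=S1,note=\"a \\\"quoted\\\" word and a \\\\ slash\">"
  s <- parseMetaLine(raw, 1L)
  expect_identical(s@attributes$value[2],
                   "a \"quoted\" word and a \\ slash")
  expect_identical(serializeMeta(s), raw)
})

test_that("malformed meta lines yield parse issues, not crashes", {
  u <- parseMetaLine("##SAMPLE=<ID=S1,DOI=\"unterminated>", 4L)
  expect_s4_class(u, "MetaLine")
  expect_true("FVCF-PARSE-001" %in% parseIssues(u)$rule_id)

  a <- parseMetaLine("##contig=<ID=chr1", 5L)
  expect_true("FVCF-PARSE-002" %in% parseIssues(a)$rule_id)

  e <- parseMetaLine("##=value", 6L)
  expect_true("FVCF-PARSE-003" %in% parseIssues(e)$rule_id)

  n <- parseMetaLine("##justtext", 7L)
  expect_true("FVCF-PARSE-006" %in% parseIssues(n)$rule_id)
  expect_identical(serializeMeta(n), "##justtext")

  noId <- parseMetaLine("##contig=<length=5>", 8L)
  expect_true("FVCF-STRUCT-001" %in% parseIssues(noId)$rule_id)

  dup <- parseMetaLine("##SAMPLE=<ID=a,ID=b>", 9L)
  expect_true("FVCF-STRUCT-002" %in% parseIssues(dup)$rule_id)
  expect_identical(nrow(dup@attributes), 2L) # nothing dropped
})

test_that("serialize(parse(x)) is byte-identical for every worked example line", {
  for (ln in exampleLines())
    expect_identical(serializeMeta(parseMetaLine(ln, 1L)), ln)
})

test_that("parse/serialize recovers random attribute lists exactly", {
  set.seed(404)
  for (rep in 1:40) {
    attrs <- randomAttributes(sample(1:6, 1))
    entry <- structuredMeta("SAMPLE", attrs$key, attrs$value)
    txt <- serializeMeta(entry)
    back <- parseMetaLine(txt, 1L)
    expect_s4_class(back, "StructuredMeta")
    expect_identical(back@attributes$key, attrs$key)
    expect_identical(back@attributes$value, attrs$value)
    expect_identical(serializeMeta(back), txt)
    # agreement with the independent splitter on the same text
    inner <- sub("^##SAMPLE=<(.*)>$", "\\1", txt)
    ref <- referenceSplit(inner)
    expect_identical(ref$key, attrs$key)
    expect_identical(ref$value, attrs$value)
  }
})

test_that("constructed entries quote exactly the values that need it", {
  e <- structuredMeta("SAMPLE",
                      c("ID", "ext_ID"),
                      c("SAMEA104646767", "DEU146:Hordeum:HOR 1361 BRG"))
  expect_identical(serializeMeta(e),
    "##SAMPLE=<ID=SAMEA104646767,ext_ID=\"DEU146:Hordeum:HOR 1361 BRG\">")
})

test_that("the header line splits into fixed and sample columns", {
  h <- parseHeaderLine(paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                               "QUAL", "FILTER", "INFO", "FORMAT",
                               "SAMEA104646767"), collapse = "\t"), 12L)
  expect_length(h@fixed, 9L)
  expect_identical(h@samples, "SAMEA104646767")

  h8 <- parseHeaderLine(paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                                "QUAL", "FILTER", "INFO"),
                              collapse = "\t"))
  expect_length(h8@fixed, 8L)
  expect_length(h8@samples, 0L)

  h2 <- parseHeaderLine("#CHROM\tPOS")
  expect_length(h2@fixed, 2L)

  expect_error(parseHeaderLine("##meta=1"), class = "fvcf_not_header_line")
})

test_that("data-line cores stream with chrom/pos only and survive bad lines", {
  lines <- c(minimalVcfLines(dataLines = character()),
             "chr1\t42\t.\tA\tT\t.\t.\t.",
             "chr1\tNaN\t.",
             "onlyonefield",
             "chr2\t7\t.\tG\tC\t.\t.\t.\tGT\t0/0")
  res <- streamDataCores(writeTemp(lines))
  expect_identical(nrow(res$cores), 2L)
  expect_identical(res$cores$chrom, c("chr1", "chr2"))
  expect_identical(res$cores$pos, c(42, 7))
  expect_identical(res$cores$n_fields[1], 8L)
  expect_setequal(res$issues$rule_id, c("FVCF-PARSE-005", "FVCF-PARSE-004"))
})

test_that("gzip input is detected by magic bytes", {
  lines <- minimalVcfLines()
  gz <- writeTempGz(lines)
  res <- streamDataCores(gz)
  expect_identical(nrow(res$cores), 1L)
  hdr <- readFairHeader(gz)
  expect_identical(fieldValues(hdr, "fileformat"), "VCFv4.3")
})

test_that("a generated fixture yields exactly one core per data line", {
  ref <- makeReference(2, c(800, 400), 21)
  fx <- makeVcf(ref, 2, 100, 21, "fair")
  res <- streamDataCores(writeTemp(fx$vcf))
  expect_identical(nrow(res$cores), 100L)
})

test_that("callback streaming never accumulates cores", {
  ref <- makeReference(1, 600, 3)
  fx <- makeVcf(ref, 1, 200, 3, "fair")
  seen <- 0L; maxChunk <- 0L
  res <- streamDataCores(writeTemp(fx$vcf), chunkSize = 32L,
                         callback = function(cores) {
                           seen <<- seen + nrow(cores)
                           maxChunk <<- max(maxChunk, nrow(cores))
                         })
  expect_identical(nrow(res$cores), 0L)
  expect_identical(seen, 200L)
  expect_lte(maxChunk, 32L)
  expect_identical(res$nLines, 200L)
})

test_that("maxLines bounds the number of data lines examined", {
  ref <- makeReference(1, 600, 3)
  fx <- makeVcf(ref, 1, 50, 3, "fair")
  res <- streamDataCores(writeTemp(fx$vcf), maxLines = 10)
  expect_identical(nrow(res$cores), 10L)
})

test_that("case-variant canonical keys are recognized and flagged", {
  hdr <- readFairHeader(c("##fileformat=VCFv4.3", "##filedate=20120921",
                          "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  expect_identical(fieldValues(hdr, "fileDate"), "20120921")
  expect_true("FVCF-CASE-001" %in% parseIssues(hdr)$rule_id)
})
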