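test_that("reference index records names, lengths and normalized digests", {
  idx <- buildReferenceIndex(c(">chrT", "ACGTACGTAC"))
  expect_identical(refNames(idx), "chrT")
  expect_identical(unname(refLengths(idx)), 10)
  expect_identical(unname(refMd5(idx)), pyMd5("ACGTACGTAC"))
})

test_that("digest normalization ignores case and line structure", {
  a <- buildReferenceIndex(c(">s", "acgt", "ACGTAC"))
  b <- buildReferenceIndex(c(">s", "ACGTACGTAC"))
  expect_identical(refMd5(a), refMd5(b))
  expect_identical(refLengths(a), refLengths(b))
})

test_that("index digests match the independent MD5 oracle on random sequences", {
  set.seed(909)
  for (rep in 1:8) {
    n <- sample(50:400, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t"), n,
                        replace = TRUE), collapse = "")
    width <- sample(c(7, 60, 101), 1)
    starts <- seq(1, nchar(seq), by = width)
    body <- substring(seq, starts, pmin(starts + width - 1, nchar(seq)))
    idx <- buildReferenceIndex(c(">r", body))
    expect_identical(unname(refMd5(idx)), pyMd5(seq))
    expect_identical(unname(refLengths(idx)), as.numeric(n))
  }
})

test_that("index lengths agree with Biostrings on a written FASTA", {
  skip_if_not_installed("Biostrings")
  ref <- makeReference(3, c(123, 61, 240), 55)
  path <- writeTemp(ref, ext = ".fa")
  idx <- buildReferenceIndex(path)
  bs <- Biostrings::fasta.seqlengths(path)
  expect_identical(unname(refLengths(idx)), unname(as.numeric(bs)))
  expect_identical(refNames(idx), names(bs))
})

test_that("degenerate FASTAs raise classed errors", {
  expect_error(buildReferenceIndex(writeTemp(character(), ext = ".fa")),
               class = "fvcf_empty_fasta")
  expect_error(buildReferenceIndex(c(">a", "ACGT", ">a", "ACGT")),
               class = "fvcf_duplicate_sequence")
  expect_error(buildReferenceIndex(c("ACGT", ">a", "ACGT")),
               class = "fvcf_bad_fasta")
})

test_that("contig declarations are checked against the reference index", {
  idx <- buildReferenceIndex(c(">chrT", "ACGTACGTAC"))
  md5 <- unname(refMd5(idx))
  mk <- function(contigLine) readFairHeader(c("##fileformat=VCFv4.3",
    contigLine, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))

  agree <- mk(sprintf("##contig=<ID=chrT,length=10,md5=%s>", md5))
  expect_identical(nrow(checkContigsVsReference(agree, idx)), 0L)

  shrt <- mk(sprintf("##contig=<ID=chrT,length=9,md5=%s>", md5))
  expect_identical(checkContigsVsReference(shrt, idx)$rule_id,
                   "FVCF-REF-003")

  upper <- mk(sprintf("##contig=<ID=chrT,length=10,md5=%s>", toupper(md5)))
  expect_identical(nrow(checkContigsVsReference(upper, idx)), 0L)

  wrong <- mk("##contig=<ID=chrT,length=10,md5=00000000000000000000000000000000>")
  expect_identical(checkContigsVsReference(wrong, idx)$rule_id,
                   "FVCF-REF-004")

  missing <- mk("##contig=<ID=chrX,length=10>")
  iss <- checkContigsVsReference(missing, idx)
  expect_setequal(iss$rule_id, c("FVCF-REF-001", "FVCF-REF-002"))
})

test_that("contig assembly attributes must agree with ##reference_ac", {
  mk <- function(...) readFairHeader(c("##fileformat=VCFv4.3", ...,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  same <- mk("##reference_ac=GCA_902498975.1",
             "##contig=<ID=c1,assembly=GCA_902498975.1>")
  expect_identical(nrow(checkContigAssemblyAgreement(same)), 0L)

  diff <- mk("##reference_ac=GCA_902498975.1",
             "##contig=<ID=c1,assembly=GCA_000005005.5>")
  expect_identical(checkContigAssemblyAgreement(diff)$rule_id,
                   "FVCF-REF-005")

  absent <- mk("##reference_ac=GCA_902498975.1", "##contig=<ID=c1>")
  expect_identical(checkContigAssemblyAgreement(absent)$rule_id,
                   "FVCF-REF-006")

  noac <- mk("##contig=<ID=c1,assembly=GCA_000005005.5>")
  expect_identical(nrow(checkContigAssemblyAgreement(noac)), 0L)
})

test_that("sample columns reconcile with SAMPLE records", {
  mk <- function(cols, sampleLines = character())
    readFairHeader(c("##fileformat=VCFv4.3", sampleLines,
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", cols), collapse = "\t")))

  clean <- mk("SAMEA104646767", "##SAMPLE=<ID=SAMEA104646767>")
  expect_identical(nrow(checkSampleColumns(clean)), 0L)

  loner <- mk("mySample1")
  iss <- checkSampleColumns(loner)
  expect_setequal(iss$rule_id, c("FVCF-COL-001", "FVCF-COL-003"))
  expect_true(all(iss$severity == "warning"))

  dup <- mk(c("S1", "S1"))
  expect_true("FVCF-COL-004" %in% checkSampleColumns(dup)$rule_id)

  orphanRec <- mk("SAMEA1", c("##SAMPLE=<ID=SAMEA1>", "##SAMPLE=<ID=SAMEA2>"))
  expect_true("FVCF-COL-002" %in% checkSampleColumns(orphanRec)$rule_id)
})

test_that("positions respect the inclusive [1, length] bound", {
  hdr <- readFairHeader(c("##fileformat=VCFv4.3",
    "##contig=<ID=chr1H,length=522466905>",
    "##contig=<ID=noLen>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  cores <- data.frame(line = 5:10,
                      chrom = c("chr1H", "chr1H", "chr1H", "chrZ", "chrZ",
                                "noLen"),
                      pos = c(522466905, 522466906, 0, 1, 2, 99),
                      n_fields = 8L)
  iss <- checkPositions(cores, hdr)
  expect_identical(sum(iss$rule_id == "FVCF-POS-002"), 1L)
  expect_identical(iss$line[iss$rule_id == "FVCF-POS-002"], 6L)
  expect_identical(sum(iss$rule_id == "FVCF-POS-003"), 1L)
  unknown <- iss[iss$rule_id == "FVCF-POS-001", ]
  expect_identical(nrow(unknown), 1L)
  expect_match(unknown$message, "2 data line")
  expect_identical(sum(iss$rule_id == "FVCF-POS-004"), 1L)
})

test_that("exactly k deliberately out-of-bounds positions yield k bound errors", {
  set.seed(31)
  for (k in c(1L, 3L, 7L)) {
    len <- 50
    ok <- sample.int(len, 10)
    bad <- len + sample.int(20, k)
    hdr <- readFairHeader(c("##fileformat=VCFv4.3",
      sprintf("##contig=<ID=c1,length=%d>", len),
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
    cores <- data.frame(line = seq_along(c(ok, bad)) + 3L, chrom = "c1",
                        pos = c(ok, bad), n_fields = 8L)
    iss <- checkPositions(cores, hdr)
    expect_identical(sum(iss$rule_id == "FVCF-POS-002"), k)
  }
})

test_that("annotator-derived contigs agree with the index they came from", {
  ref <- makeReference(2, c(150, 90), 8)
  idx <- buildReferenceIndex(ref)
  cts <- deriveContigs(idx, "GCA_000000001.1", "NCBITaxon:4513")
  lines <- c("##fileformat=VCFv4.3",
             "##reference_ac=GCA_000000001.1",
             vapply(cts, function(ct)
               serializeMeta(fairVCF:::contigToMeta(ct)), character(1)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  hdr <- readFairHeader(lines)
  expect_identical(nrow(checkContigsVsReference(hdr, idx)), 0L)
  expect_identical(nrow(checkContigAssemblyAgreement(hdr)), 0L)
})
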