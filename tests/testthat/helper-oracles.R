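# Shared fixtures and independent oracles for the test suite.

exampleLines <- function() {
  readLines(system.file("extdata", "profile_examples.txt",
                        package = "fairVCF"))
}

# Independent MD5 oracle: Python's hashlib on the normalization performed
# here (not by the package code).
pyMd5 <- function(seq) {
  norm <- toupper(gsub("[[:space:]]", "", paste(seq, collapse = "")))
  out <- system2("python",
                 c("-c",
                   shQuote("import hashlib, sys; print(hashlib.md5(sys.argv[1].encode()).hexdigest())"),
                   shQuote(norm)),
                 stdout = TRUE)
  trimws(out[1])
}

# Independent character-by-character reference splitter for structured
# attribute lists: split on top-level commas (quote- and escape-aware),
# then cut each piece at its first '='. Deliberately structured
# differently from the package tokenizer.
referenceSplit <- function(inner) {
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  pieces <- list(); buf <- character(); inQuote <- FALSE; i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (inQuote && ch == "\\" && i < length(chars) &&
        chars[i + 1L] %in% c("\"", "\\")) {
      buf <- c(buf, ch, chars[i + 1L]); i <- i + 2L; next
    }
    if (ch == "\"") inQuote <- !inQuote
    if (ch == "," && !inQuote) {
      pieces[[length(pieces) + 1L]] <- paste(buf, collapse = "")
      buf <- character()
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  pieces[[length(pieces) + 1L]] <- paste(buf, collapse = "")
  do.call(rbind, lapply(pieces, function(p) {
    eq <- regexpr("=", p, fixed = TRUE)
    key <- substr(p, 1L, eq - 1L)
    val <- substring(p, eq + 1L)
    quoted <- startsWith(val, "\"") && endsWith(val, "\"") && nchar(val) >= 2
    if (quoted) {
      val <- substr(val, 2L, nchar(val) - 1L)
      val <- gsub("\\\\(\"|\\\\)", "\\1", val)
    }
    data.frame(key = key, value = val, quoted = quoted,
               stringsAsFactors = FALSE)
  }))
}

# Random attribute lists exercising commas, quotes, spaces and escapes.
randomAttributes <- function(n) {
  keys <- paste0("k", seq_len(n))
  pool <- c("plain", "with space", "a,b", "x=y", "quote\"inside",
            "back\\slash", "doi.org/10.1000/a,b", "HOR 1361 BRG", "")
  values <- sample(pool, n, replace = TRUE)
  data.frame(key = keys, value = values, stringsAsFactors = FALSE)
}

writeTemp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

writeTempGz <- function(lines, ext = ".vcf.gz") {
  path <- tempfile(fileext = ext)
  con <- gzfile(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

minimalVcfLines <- function(sampleCols = "SAMEA90000001",
                            dataLines = "chr1\t42\t.\tA\tT\t.\t.\t.\tGT\t0/1") {
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
             "INFO", "FORMAT")
  c("##fileformat=VCFv4.3",
    paste(c(fixed, sampleCols), collapse = "\t"),
    dataLines)
}

runCli <- function(args, env = character()) {
  cli <- system.file("cli", "fairvcf.R", package = "fairVCF")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(cli, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status,
       output = paste(out, collapse = "\n"))
}
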