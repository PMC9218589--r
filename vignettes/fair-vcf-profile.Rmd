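---
title: "The fairVCF metadata profile: rules, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fairVCF metadata profile: rules, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairVCF)
```

## The problem and the model

VCF meta-information is a syntactic format: `##key=value` lines, with
structured lines carrying an angle-bracketed attribute list that requires
an ID unique within its type. The format prescribes no vocabulary, so in
practice genotyping VCFs circulate with sample names that identify no
biological material and no durable record of the reference assembly the
coordinates refer to. fairVCF implements a metadata profile for plant
genotyping that closes this gap with six fields — `##fileDate`,
`##bioinformatics_source`, `##reference_ac`, `##reference_url`,
`##contig` and `##SAMPLE` — each with a small formal grammar, a
cardinality, and cross-field consistency obligations.

The package is organized as a pipeline of pure stages. A parser turns the
header into a `FairHeader` object while preserving enough fidelity for
byte-identical re-serialization. A rule engine applies per-field
grammars, cardinalities and uniqueness. A consistency layer ties the
declarations to the data lines and, when a FASTA is supplied, to the
actual reference sequences. An annotator runs the pipeline in reverse,
deriving compliant metadata from a reference and injecting it. Every
finding is a row with a stable rule id from `ruleCatalogue()`, a
severity, a line anchor and a message; `runValidation()` aggregates them
into a `ValidationReport`.

## Parsing fidelity

Round-trip identity (`serializeMeta(parseMetaLine(x)) == x`) is a hard
invariant, because a repair tool that silently reformats untouched lines
produces unreviewable diffs. Three choices follow from it:

* attribute keys are kept verbatim (including any stray whitespace), and
  attribute order is never changed;
* which values were double-quoted is recorded per attribute, and
  re-serialization re-quotes exactly those; newly constructed entries
  quote any value containing a comma, `=`, `<`, `>`, a space or a quote;
* inside quoted values only `\"` and `\\` are treated as escapes, the
  convention of the underlying format standard; both are re-escaped on
  output, so the mapping is bijective.

Malformed lines (unterminated quote or bracket, empty key, missing `=`)
degrade to an unstructured representation carrying a parse issue; the
parser never throws on file content and never drops data — duplicated
attribute keys are kept and flagged. The canonical key casing is
`fileDate`, but case variants such as `##filedate` are recognized as the
same field and flagged separately (`FVCF-CASE-001`), since both spellings
occur in the wild. Unknown keys pass through untouched: the profile
constrains its own six fields and is silent on the rest.

## Grammar decisions

Where the profile's source material is ambiguous, the package resolves it
as follows:

* **Assembly accessions** require at least one version digit
  (`GC[AF]_\d{9}\.\d+`). A zero-digit version would be compatible with a
  looser reading of the pattern, but no published example omits the
  version.
* **BioSample accessions** make the `A`/`G` letter optional
  (`SAM[END][AG]?\d+`), following the upstream database's own prose
  ("there may be an A or a G") over a stricter pattern reading.
* **Locators** accept scheme-less hosts (`doi.org/...`,
  `github.com/...`) because the profile's own examples are scheme-less;
  the minimal requirements are no whitespace and either a scheme or a
  dotted host followed by a path.
* **Taxa** must read `NCBITaxon:<digits>`. Bare digits and prefix case
  variants get their own warning-level rules because both are mechanically
  fixable; anything else is an error.
* **External IDs** are disambiguated by arity alone: three
  colon-separated parts select the genebank encoding, four the DNS
  encoding, anything else is an error. The institute-code pattern
  `[A-Z]{3}[0-9]{3}` is generalized from a single published example, so
  violations are warnings, not errors. Multiple external IDs are accepted
  both as repeated `ext_ID` keys and as one quoted comma-separated value
  (acceptance is lossless); the annotator always emits repeated keys,
  which is unambiguous.

## Severity policy and strictness

Standard VCF treats meta-information as optional, so a profile that
hard-fails legacy files would never run in anger. Absence of a
recommended field is therefore a warning and presence-but-malformed an
error; `##fileformat` absence alone is an error, since that line is
obligatory in VCF itself. Strict mode does not mutate severities (rules
stay pure and deterministic); it changes only the verdict: default mode
passes at zero errors, strict mode at zero errors and zero warnings.
Strict passes are consequently a subset of default passes by
construction.

## Consistency checks and numerical choices

* **Coordinates.** POS is 1-based and valid on `[1, length]` inclusive:
  `POS == length` passes, `length + 1` fails. `POS 0` is the telomeric
  convention and draws a warning rather than an error. Lines on
  undeclared chromosomes are aggregated into one issue per name with a
  count, keeping reports bounded on large files; contigs without a
  declared length are skipped for the bound check under a single info
  notice.
* **Digests.** The per-sequence MD5 is computed over the normalized
  sequence — residues uppercased, all whitespace and line breaks removed —
  the checksum convention of the alignment-format ecosystem, which makes
  digests comparable across FASTA line wrappings. Hex comparison is
  case-insensitive. The FASTA reader streams records and accumulates the
  digest chunk-wise through a scratch file, so memory use is independent
  of sequence length; tests cross-check the digests against an
  independent MD5 implementation and the lengths against Biostrings.
* **Tie-breaks.** When a structured line repeats an attribute key, the
  first occurrence wins for record extraction and the duplication is
  flagged. When `##reference_ac` itself repeats, the first value anchors
  the contig-assembly agreement check and the multiplicity is an error.
  The legacy `##reference` key is reported as info only; its relation to
  `##reference_ac`/`##reference_url` is deliberately left open.
* **Issue ordering.** Reports sort by line number (file-level issues
  last), then rule id, then message, so repeated runs are byte-identical.

## Annotation

`injectMetadata()` writes the header in a fixed order — `##fileformat`,
the four scalar fields, contig lines, SAMPLE lines, all remaining
pre-existing meta lines in original order, the column header — chosen for
deterministic diffs; the profile constrains content, not ordering, beyond
fileformat-first. Existing lines conflicting with the fragment are kept
(and counted) unless `replace` is set; injection under `replace` is
idempotent. The data region is copied through unchanged, and fragments
are validated before any output is written, so the annotator cannot emit
metadata its own validator would reject. SAMPLE `DOI` and `ext_ID` values
are always quoted on output, matching the profile's worked examples even
when no character forces quoting.

## The fixture generator

`makeReference()` and `makeVcf()` generate the study material: uniform
random A/C/G/T sequences and VCFs at three compliance profiles. The
`fair` profile is constructed to close the loop exactly — contig records
are derived from the reference index itself, so lengths and digests are
real; sample accessions are grammatical synthetics from the high-numbered
`SAMEA9xxxxxxx` range (documented as unregistered); positions are sorted
and in bounds. `missing_fields` drops a seeded subset (one to three) of
the four recommended scalar fields, producing warnings only.
`malformed` always plants the same four canonical defects — a
separator-bearing date, a nine-digit-rule violation, a duplicated contig
ID and one out-of-bounds position — and returns them as a manifest, so
detection can be asserted defect-by-defect; the seed varies content, not
the defect set. Generation is byte-deterministic in (arguments, seed).

What the generator does *not* emulate: linkage structure or any
population-genetic realism in the genotypes (GT values are uniform
draws), INFO/FORMAT semantics, multi-allelic records, phasing, and
real-world header diversity (tool-specific keys, contig lines from
heterogeneous callers). Passing tests therefore demonstrate the metadata
machinery, not robustness to every VCF dialect in circulation.

Test and acceptance runs use small problem sizes — references of a few
hundred bp across two sequences, tens of variants, a handful of samples —
chosen because every rule in the catalogue is already exercised at that
scale; the streaming design (chunked readers, callback mode in
`streamDataCores()`, `maxDataLines`) is what carries the same code to
large files.

## Known limitations

* REF alleles are not verified against the reference sequence; that
  requires random access to the FASTA and is out of scope.
* Identifiers are checked by grammar only; no network resolution of
  DOIs, BioSample accessions or taxon IDs is attempted, so a well-formed
  but nonexistent accession passes.
* Genotype columns, INFO/FORMAT declarations and gVCF blocks are outside
  the profile and are not semantically parsed.
* The JSON report ships with a draft-07 schema under `inst/schema/`;
  conformance is asserted structurally in the tests rather than through a
  schema engine.
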