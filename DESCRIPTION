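Package: tagkit
Title: Design and In Silico Validation of Homologous-Recombination Protein-Tagging Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for C-terminal protein tagging by homologous recombination in
    hyper-recombinogenic cell lines (DT40-style workflows). Provides a deterministic
    in-silico molecular-biology engine (PCR, restriction digestion, self-ligation,
    SLIC assembly, Cre/loxP excision, targeted integration), an end-to-end targeting
    construct designer around an ORF stop codon with verification-primer design and
    predicted tagged-locus/fusion-protein output, peptide-level tools (TEV cleavage,
    tryptic digestion, monoisotopic masses, stable-isotope label shifts), AP-MS
    abundance/specificity scoring of co-immunoprecipitation intensity tables,
    quantification-peptide absolute quantification (copies per cell), a
    transcriptome-derived protein search database builder, and seeded synthetic
    fixture generators for every input format consumed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
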