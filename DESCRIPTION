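Package: chaovir
Title: Comparative Genomics of Headful-Packaged Haloviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative genome analysis of circularly
    permuted, terminally redundant (headful-packaged) archaeal viruses
    such as Halobacterium virus ChaoS9 and its relatives phiH1 and
    phiCh1.  Models restriction band patterns of headful virion
    populations and estimates packaging parameters from gels; computes
    nucleotide-composition statistics (G+C, cumulative AT-skew,
    stop-codon and codon usage, CDS spacing); corrects predicted protein
    molecular weights for the anomalous SDS-PAGE mobility of acidic
    proteomes; performs fragment-based average nucleotide identity
    (ANIb), dotplot, base-level revision diff, pac-site transfer and
    CRISPR-spacer scans; maps protein homologs with neighborhood-relaxed
    E-value thresholds, synteny blocks, translated similarity shading
    and invertible tail-fiber regions; and reconstructs neighbor-joining
    trees with bootstrap consensus.  A synthetic virus-genome generator
    provides test data with controlled composition, gene layout,
    divergence and virion structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
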