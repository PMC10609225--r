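Package: derepnet
Title: Molecular Networking and Neutral-Loss Dereplication of Glycosylated
    Polyketides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to dereplicate glycosylated aromatic polyketides
    (anthracyclines and angucyclines) from centroided LC-MS/MS data:
    modified-cosine spectral similarity and GNPS-style molecular network
    construction, detection of sequential deoxysugar neutral-loss ladders
    (-114/-130/-157 Da and relatives), accurate-mass molecular formula
    enumeration with RDBE filtering, seed-library matching with
    network-propagated analog annotation, and the turbidometric 96-well
    antibacterial screening statistic with its 60 percent activity
    threshold. A ground-truthed synthetic-data generator emulates
    glycoside fragment ladders, analog families and OD600 plate readings
    so that every stage can be validated end to end without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
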