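Package: PharmNetCompare
Title: Comparative Network Pharmacology of Western Drugs and Herbal Ingredients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Target-centred comparison of two compound classes (FDA-approved
    cardiovascular drugs versus active ingredients of anti-CVD Chinese herbs):
    Therapeutic Target Database status tallies, diseases-per-target (d/t)
    statistics, protein family, structural-domain and subcellular-location
    profiles, transcription-factor enrichment, one-sided Fisher's exact
    pathway enrichment with a basic/disease pathway split, bipartite
    target-pathway and compound-pathway network construction with degree
    distribution and power-law fitting, and curated disease-subnetwork
    coverage summaries. Includes a synthetic-data generator with planted
    class differences for end-to-end validation, and a deterministic fixture
    encoding the published marginal counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
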