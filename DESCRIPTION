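Package: gridflora
Title: Gridded Vascular Plant Species Richness from Merged Atlas and
    Vegetation-Plot Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for producing gridded species-richness data
    sets of the kind built for national floristic atlases: occurrence records
    from a cartogram-grid atlas and from georeferenced vegetation plots are
    merged onto a 10 x 10 km square grid, taxon names are harmonized against
    a checklist and collapsed into operational taxonomic units (species,
    aggregates, sensu-lato groups, collapsed microspecies genera), each unit
    is classified by floristic status (native, archeophyte, neophyte),
    Red-List and apophyte flags and frequency class under explicit
    minority-propagation rules, per-square richness statistics are computed,
    and cross-boundary and potentially undersampled squares are flagged using
    a benchmark-species ("wish list") detector. Includes a synthetic-data
    generator with known ground truth so every stage is testable without
    external downloads, and a validator for published deposits of the same
    schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
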