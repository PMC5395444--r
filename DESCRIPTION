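Package: TOPscreen
Title: Total Outcrossing Potential Screening for Crop-to-Wild Gene Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens the outcrossing (pollen-mediated gene flow) risk between
    a cultivated or genetically modified donor species and receptor species
    (other crops, or native and introduced wild flora). Combines a trait-based
    outcrossing-potential percentage (OP), a latitude-block regional
    pollinators index (RPI), and a species distribution probability (SDP) at a
    geographic point into a total outcrossing potential TOP = OP x RPI x SDP,
    classified on a quintile concept scale from very low to very high.
    Includes registry I/O for flora and pollinator tables, an ESRI ASCII
    raster reader/writer, a Gaussian climate-envelope suitability fitter,
    census-ratio occurrence for cultivated species, a seeded synthetic-data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
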