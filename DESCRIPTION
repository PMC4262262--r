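Package: woodsim
Title: Spatially Explicit Simulation of Woody Encroachment on Semi-Natural Grasslands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, raster-based simulator of bush and tree
    encroachment on temperate semi-natural grasslands. Bushes and trees are
    explicit agents with Bertalanffy height growth, crown allometry,
    self-thinning and senescence; the herbaceous layer is a cover-based
    difference-equation stand-in whose grasses inhibit seed-bank input.
    Seeds disperse with a double-exponential kernel (effective and maximum
    seeding distances), decay exponentially in per-cell seed banks and
    germinate under space limitation. Wild-boar soil disturbance and a
    density-dependent red-deer browsing budget (supply of available browse
    vs. herd demand, with nurse-shrub protection by blackthorn and bramble)
    couple wildlife to vegetation dynamics. Includes synthetic scenario
    generators, Esri ASCII raster input/output and annual observers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
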