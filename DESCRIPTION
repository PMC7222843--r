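Package: slurrycbc
Title: Buffer Capacity Determination from Acid-Base Titrations of Animal Slurry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts raw acid/base titration logs of animal slurry into
    current-buffer-capacity (CBC) curves by fitting a sixth-degree polynomial
    to the titration curve, differentiating it analytically and taking the
    reciprocal absolute slope. Extracts per-buffer-system peak capacities
    (volatile fatty acid, bicarbonate, carbonate and ammonia buffers) and
    quantifies titrant amounts per pH segment directly from the raw data.
    Includes a closed-system multi-buffer charge-balance titration simulator
    with van 't Hoff temperature correction that generates realistic
    instrument logs and serves as an independent oracle for the determination
    model, plus quality-control screening and batch verification workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
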