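Package: trichoproj
Title: Projection of Global Trichodesmium N2 Fixation Under Ocean
    Acidification and Phosphorus Limitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline projection of global nitrogen fixation by the marine
    cyanobacterium Trichodesmium under ocean acidification and phosphorus
    limitation. Provides a seeded synthetic gridded-ocean generator emulating
    Earth-system-model fields (pH on the total scale, phosphate, dissolved
    organic phosphorus, baseline N2 fixation and the Trichodesmium
    contribution fraction), chemostat culture-calibration arithmetic that
    derives hydrogen-ion effect parameters from paired ambient/acidified
    replicate measurements, dual-substrate Michaelis-Menten phosphorus
    limitation factors, nifH-based diazotroph rate upscaling, linear
    hydrogen-ion scaling projections with area-weighted global integration to
    Tg N per year, and a reproducible end-to-end pipeline with a
    machine-readable run summary.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
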