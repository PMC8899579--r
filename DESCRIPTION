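Package: msifuse
Title: Multimodal Fusion of Mass Spectrometry Imaging and Imaging Mass
    Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates desorption electrospray ionization mass spectrometry
    imaging (DESI-MSI) with imaging mass cytometry (IMC) single-cell data to
    resolve drug distribution across tumor-microenvironment compartments.
    Provides imzML input/output, total-ion-current and reference-ion
    normalization, k-means background detection, marker-positivity gating with
    the standard myeloid phenotype rules, supervised cell tissue
    classification, affine co-registration of the two modalities,
    majority-vote label transfer from cells to pixels followed by k-nearest
    neighbor classification of all pixels, cross-modal Pearson correlation and
    high-versus-low drug phenotype enrichment, compartment-resolved drug
    fraction quantification, and a synthetic paired-data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
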