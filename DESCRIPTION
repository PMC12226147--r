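Package: sozflow
Title: Directed-Connectivity Network Analysis and Seizure-Onset-Zone Localisation for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the direction of neural activity flow in and out of the
    seizure onset zone (SOZ) on multichannel intracranial EEG. Implements thirteen directed
    connectivity measures (multivariate autoregressive spectral measures DTF, DCOH, PDC and
    spectral Granger causality; phase-slope index and group delay; Gaussian directed
    information and causally conditioned entropy; bivariate cause-effect scores ANM, IGCI,
    CDS, RECI and a linear-model fit), six weighted directed graph node metrics (in/out
    strength, mean first passage time, clustering, eccentricity, betweenness), JZS
    Bayes-factor tests of the sink-SOZ and source-SOZ hypotheses, and random-forest SOZ
    localisation with label-shuffle chance distributions and permutation feature
    contributions. A synthetic cohort generator based on stable vector-autoregressive
    network models with planted inward (interictal) or outward (ictal) SOZ coupling makes
    the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
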