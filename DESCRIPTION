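Package: pcnet
Title: Predictive Coding Networks for Sequential Deep Learning Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A predictive coding learning engine for strictly sequential neural
    networks: per-layer error nodes, variational free-energy objective, iterative
    inference on activation nodes, and local Hebbian-style weight updates, with an
    exact chain-rule backpropagation oracle for equivalence testing under the fixed
    prediction assumption. Includes pipelines for class-incremental learning (with
    elastic weight consolidation and incremental moment matching variants),
    long-tailed recognition under an exponential class-imbalance profile with six
    classification objectives, and episodic few-shot recognition with prototypical
    networks, all exercisable end-to-end on a deterministic synthetic image
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), png, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
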