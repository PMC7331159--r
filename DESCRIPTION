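Package: cartstrain
Title: Kinematics-Driven Articular Cartilage Contact Strain and T2* Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in silico measurement chain for in vivo articular cartilage
    mechanics and quantitative MRI. Generates synthetic ball-and-socket joint
    models, marker-based gait recordings, and multi-echo MR volumes with known
    ground truth; estimates rigid bone poses from marker triads; maps
    cartilage thickness and overlap-based contact strain over a gait cycle;
    fits voxelwise mono-exponential T2* relaxation times with a synovial-fluid
    cutoff; bins surfaces into angular regions and correlates regional strain
    change against T2* change; and audits measurement accuracy with a two-block
    phantom study (bias/precision and error propagation to strain).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
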