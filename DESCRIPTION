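Package: hpuindex
Title: Newspaper-Based Health Policy Uncertainty Indexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs monthly health policy uncertainty (HPU) indexes from
    newspaper corpora by three-category keyword screening (health, policy,
    uncertainty terms), per-newspaper scaling of target-article counts to
    total article counts, unit-standard-deviation standardization,
    cross-newspaper averaging, and mean-100 normalization.  Supports splicing
    indexes across declared coverage gaps, subgroup robustness testing via
    pairwise Pearson correlation, stratified audit sampling with pass-rate
    tabulation, comparison against external monthly index series, and a
    fully parameterized synthetic newspaper-corpus generator with
    ground-truth bookkeeping for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
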