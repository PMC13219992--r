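Package: ligstab
Title: Contact-Persistence Stability Analysis of Protein-Ligand MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stability-driven evaluation of protein-ligand binding poses from
    molecular dynamics trajectories. Computes the R-value, a sigmoid-smoothed
    fraction-of-native-contacts score that measures how well the
    protein-ligand heavy-atom contacts of a reference structure persist over
    a trajectory, selects representative frames by minimum distance to the
    ensemble-averaged contact matrix, decomposes stability per residue and
    per ligand atom, classifies poses into stable/unstable x
    similar/dissimilar categories, and correlates stability with experimental
    binding affinity (pKd). Includes synthetic-trajectory generators with
    planted contact persistence for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
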