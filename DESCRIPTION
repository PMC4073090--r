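Package: canrecall
Title: Categorization-Activation-Novelty Network Simulations of Free Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates immediate free recall with a
    categorization-activation-novelty (CAN) network: a limited-capacity
    lexical activation buffer with self-excitation and global lateral
    inhibition, a semantic-features layer with adaptation, a fast-Hebbian
    prefrontal categorization layer, a single-unit list context, and a
    novelty ("surprise") mechanism that boosts encoding of distinctive
    items.  Provides list designs (CVLT-like categorized lists, Von
    Restorff isolate lists, same-category and unrelated baselines), a
    frontal-lesion mode, and behavioural metrics (serial-position and
    first-recall curves, the chance-corrected semantic clustering index,
    isolate-advantage measures, and lag-CRP) applicable to simulated or
    empirical recall transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
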