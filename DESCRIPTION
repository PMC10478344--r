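Package: ipcssm
Title: Interpersonal Circumplex Structural Summary Analysis with Bootstrapped Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpersonal construct validation on the interpersonal
    circumplex (IPC). Scores circumplex instruments and external scales from
    item-level responses, screens protocols for missingness and infrequent
    responding, estimates McDonald's omega-total reliability, fits the
    correlation-based structural summary method (SSM) cosine curve in closed
    form (elevation, amplitude, angular displacement, prototypicality R2),
    computes percentile bootstrap confidence intervals for SSM parameters and
    for between-scale parameter differences with circular handling of angles,
    tests circumplex structure with a randomization test of hypothesized order
    relations (correspondence index), generates synthetic participant data with
    prescribed circumplex structure and scale profiles, and orchestrates the
    full screen-score-profile-contrast workflow from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
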