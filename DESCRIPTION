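Package: plantdeb
Title: Dynamic Energy Budget Simulation of Carbon-Nitrogen Allocation in Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-plant growth with a generic Dynamic Energy
    Budget (DEB) model for terrestrial vascular plants: two coupled organs
    (shoot and root), each with structural biomass and reduced-carbon and
    nitrogen-rich reserves, linked by synthesizing-unit (SU) kinetics and a
    surplus-sharing translocation rule. Also provides a three-organ
    root-stem-leaf allocation model contrasting Liebig minimum-rule and
    parallel complementary SU growth, an availability-ratio sweep, stiff ODE
    integration with starvation event detection, elemental mass-balance
    auditing, and scenario/config tooling with CSV and JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
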