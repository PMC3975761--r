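Package: ffquant
Title: Food Frequency Questionnaire Processing into Daily Nutrient and Food Group Intakes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts per-participant food frequency questionnaire (FFQ)
    responses into average daily nutrient and food group intakes using a
    fully data-driven model: delimited-text tables define the questionnaire
    lines, portion weights, frequency multipliers, line-to-food-code
    mappings, a food composition table and part-2 reference lists.  The
    engine resolves free-text milk, breakfast cereal and cooking fat
    answers against reference lists, substitutes cooking fat into modified
    "without fat" foods, flags implausible reporters by the ratio of energy
    intake to Schofield-predicted basal metabolic rate and by excessive
    missingness, writes four output granularities with structured run logs,
    and tabulates quintile shifts between two processing configurations.
    A seeded synthetic-fixture generator emulates both the data-model
    bundle and cohort files so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
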