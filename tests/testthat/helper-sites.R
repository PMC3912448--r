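# Reference sites used across test files: two rows of the packaged
# experiment table, re-entered here by hand so tests do not depend on the
# fixture loader they also exercise.
balanites <- function() {
  site_conditions(rain = 721, gi = 0.32, fire = 4 / 9, ligcell = 0.341,
                  sand_pct = 51, name = "Balanites",
                  se_gi = 0.14, se_ligcell = 0.023, se_rain = 86)
}
barafu <- function() {
  site_conditions(rain = 472, gi = 0.65, fire = 2 / 9, ligcell = 0.345,
                  sand_pct = 27.6, name = "Barafu",
                  se_gi = 0.04, se_ligcell = 0.019, se_rain = 31)
}
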