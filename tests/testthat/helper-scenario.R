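# Shared fixtures: a default scenario and the reference replicate panel.

default_cfg <- function(seed = 1) scenario_config(seed = seed)

default_system <- function() extraction_system(v_aq = 3, q = 0.375, il_mass = 0.7)

# Expected summary statistics for the bundled cotinine replicate panel, as
# printed in the assay report (mean/SD/CV to 3 decimals, relative error to
# the report's decimals; the 0.1 mg/mL after-extraction relative error is
# reported as a magnitude).
panel_expected <- function() {
  data.frame(
    hb = c(0, 0.05, 0.1, 0.2, 0.05, 0.1, 0.2),
    extracted = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    mean = c(21.608, 23.246, 22.900, 26.436, 22.133, 17.074, 19.982),
    sd = c(1.532, 1.484, 1.409, 1.548, 1.538, 0.671, 0.630),
    cv = c(7.090, 6.382, 6.153, 5.856, 6.951, 3.932, 3.153),
    re = c(8.04, 16.23, 14.5, 32.18, 10.66, 14.6, -0.09),
    re_digits = c(2, 2, 1, 2, 2, 1, 2),
    re_is_magnitude = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

panel_report <- function(hb, extracted) {
  panel <- cotinine_replicates()
  sub <- panel[panel$hb_mg_per_ml == hb & panel$extracted == extracted, ]
  replicate_stats(replicate_set(sub$concentration_ng_per_ml,
                                nominal = sub$nominal_ng_per_ml[1]))
}
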