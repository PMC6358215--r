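# Build a count table from phenotype-class rows written as compact vectors.
ct <- function(sex, dsred, egfp, body, count, design = NA_character_) {
  count_table(data.frame(sex = sex, dsred = dsred, egfp = egfp, body = body,
                         count = as.integer(count), stringsAsFactors = FALSE),
              design = design)
}

# dsRed-only table: k dsRed of n offspring, phenotype channels inert.
ct_dsred <- function(k, n, sex = "female") {
  ct(sex = c(sex, sex), dsred = c(TRUE, FALSE),
     egfp = "not_applicable", body = "wild", count = c(k, n - k))
}

# Yellow-body readout table for daughters: of n_dsred dsRed daughters,
# k_yellow fully yellow; extra non-dsRed daughters to keep totals honest.
ct_yellow_daughters <- function(k_yellow, n_dsred, n_other = 50) {
  ct(sex = "female", dsred = c(TRUE, TRUE, FALSE),
     egfp = "not_applicable", body = c("yellow", "wild", "wild"),
     count = c(k_yellow, n_dsred - k_yellow, n_other))
}

split_cfg <- function() drive_system_config("split", "X", FALSE, "yellow_body")
std_cfg <- function() drive_system_config("standard", "X", TRUE, "yellow_body")
syn_cfg <- function() drive_system_config("synthetic_target", "autosome", TRUE, "egfp_eye")
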