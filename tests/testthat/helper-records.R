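# build check-up record rows with healthy defaults; override any field
make_record <- function(subject_id = "S1", visit_time = 0, age = 40,
                        sex = "female", bmi = 22, fpg = 5.0, pg2h = NA_real_,
                        sbp = 110, dbp = 70, tg = 0.9, hdl = 1.5, ldl = 2.6,
                        uric_acid = 250, smoker = 0L, drinker = 0L,
                        drug_glucose = 0L, drug_bp = 0L, drug_lipid = 0L,
                        geno_dose = 1L, cvd = 0L) {
  data.frame(subject_id = subject_id, visit_time = visit_time, age = age,
             sex = sex, bmi = bmi, fpg = fpg, pg2h = pg2h, sbp = sbp,
             dbp = dbp, tg = tg, hdl = hdl, ldl = ldl, uric_acid = uric_acid,
             smoker = smoker, drinker = drinker, drug_glucose = drug_glucose,
             drug_bp = drug_bp, drug_lipid = drug_lipid,
             geno_dose = geno_dose, cvd = cvd, stringsAsFactors = FALSE)
}

# stack several records (lists of make_record args)
make_records <- function(...) do.call(rbind, list(...))

# a record that trips >= 3 components (MetS)
sick_record <- function(subject_id, visit_time, age = 40, ...) {
  make_record(subject_id = subject_id, visit_time = visit_time, age = age,
              bmi = 27, fpg = 6.8, sbp = 150, dbp = 95, tg = 2.0, ...)
}
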