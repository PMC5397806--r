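# hand-constructable claims bundle pieces for cohort-selection tests
make_registry <- function(person_id, birth_day = 0L, coverage_start_day = 0L,
                          coverage_end_day = 10000L, death_day = NA_integer_,
                          sex = "M", ...) {
  data.frame(person_id = person_id, birth_day = birth_day, sex = sex,
             coverage_start_day = coverage_start_day,
             coverage_end_day = coverage_end_day, death_day = death_day,
             ..., stringsAsFactors = FALSE)
}

make_hosp <- function(person_id, admit_day, discharge_day,
                      primary_dx = "MI") {
  data.frame(person_id = person_id, admit_day = admit_day,
             discharge_day = discharge_day, primary_dx = primary_dx,
             stringsAsFactors = FALSE)
}

make_disp <- function(person_id, dispense_day, days_supplied = 34L,
                      drug_class = "statin") {
  data.frame(person_id = person_id, dispense_day = dispense_day,
             days_supplied = days_supplied, drug_class = drug_class,
             stringsAsFactors = FALSE)
}

make_bundle <- function(registry, hospitalizations, dispensations) {
  structure(list(dispensations = dispensations,
                 hospitalizations = hospitalizations, registry = registry),
            class = "claims_bundle")
}

# a person fully eligible under the default criteria unless fields are
# overridden: index discharge at day 3000, statin fill 5 days later,
# censored alive at day 6000
eligible_person <- function(id, birth_day = 3000L - 60L * 365L,
                            coverage_start_day = 1000L,
                            coverage_end_day = 6000L,
                            death_day = NA_integer_,
                            admit_day = 2993L, discharge_day = 3000L,
                            primary_dx = "MI", fill_day = 3005L) {
  list(registry = make_registry(id, birth_day, coverage_start_day,
                                coverage_end_day, death_day),
       hosp = make_hosp(id, admit_day, discharge_day, primary_dx),
       disp = make_disp(id, fill_day))
}

bundle_of <- function(persons) {
  make_bundle(do.call(rbind, lapply(persons, `[[`, "registry")),
              do.call(rbind, lapply(persons, `[[`, "hosp")),
              do.call(rbind, lapply(persons, `[[`, "disp")))
}

# two-group exponential survival data with known hazard ratio, in the
# fixed-dataset layout used by fit_cox()
sim_two_group <- function(n, hr, lambda0 = 0.002, censor = 1000) {
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, lambda0 * hr^x)
  data.frame(person_id = as.character(seq_len(n)),
             time = pmin(t, censor), event = t <= censor,
             adherent = factor(ifelse(x == 1, "optimal", "suboptimal"),
                               levels = c("suboptimal", "optimal")),
             stringsAsFactors = FALSE)
}
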