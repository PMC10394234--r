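# Full default-cohort study, simulated once and shared by the acceptance
# checks (the control arm serves the recovery check and the whole cohort the
# group-separation check).

get_full_study <- function() {
  if (is.null(fx$full_study)) {
    fx$full_study <- run_study(default_study_design(), seed = 1)
  }
  fx$full_study
}
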