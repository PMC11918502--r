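# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs quickly on one CPU.

# A tiny complete panel with known values for hand computations.
tiny_panel <- function() {
  y <- rbind(c(5, 7, 9), c(3, 4, 6), c(10, 12, 11), c(0, 1, 2))
  panel_dataset(y, subject_id = c("a", "b", "c", "d"))
}

# A small default-structure cohort (all five classes, integer scores).
small_cohort <- function(n = 600, seed = 11, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}

# Well-separated two-class configuration for fast, stable EM tests.
two_class_config <- function(n = 400, seed = 5, residual_sd = 1.5,
                             integer_scores = FALSE) {
  generator_config(
    n = n, seed = seed,
    class_proportions = c(0.4, 0.6),
    trajectory = list(eta1 = c(4, 18),
                      deltas = rbind(c(2, 1, 0), c(-3, -1, 0))),
    residual_sd = residual_sd,
    covariate_model = list(x = list(type = "bernoulli", p = 0.5)),
    membership_coefs = matrix(0, 1, 1, dimnames = list("x", NULL)),
    retention_schedule = c(1, 0.9, 0.9, 0.9),
    distal_probs = rbind(treatment_seeking = c(0.5, 0.1),
                         diagnosis_T9 = c(0.6, 0.1)),
    integer_scores = integer_scores)
}

# Mean curves of a config as a K x T matrix.
config_curves <- function(cfg) {
  t(vapply(seq_len(cfg$K), class_mean_curve, numeric(cfg$n_waves),
           config = cfg))
}
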