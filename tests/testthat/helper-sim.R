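# Small fixtures built in code.

# tiny chromosome layout for fast simulations
small_layout <- function(n_chr = 2L, n_markers = 5L, length_cM = 50) {
  tibble::tibble(chr = paste0("C", seq_len(n_chr)),
                 n_markers = n_markers, length_cM = length_cM)
}

# noise-free logistic records for one animal at the standard seven ages
noise_free_records <- function(alpha1 = 90, alpha2 = 113, alpha3 = 32,
                               ages = c(0, 21, 42, 63, 77, 105, 150),
                               id = "A1") {
  tibble::tibble(animal_id = id, age_days = ages,
                 weight_kg = logistic_predict(ages, alpha1, alpha2, alpha3))
}

# recovery-scenario config: 300 animals, 100 markers over five chromosomes,
# five strong mature-weight QTL on distinct chromosomes. The weight-noise
# schedule induces a mature-weight estimation SD of about 1.8 kg, so the
# planted per-allele effects (>= 9 kg) are at least five times that spread.
recovery_config <- function(seed, het = FALSE) {
  effects <- c(C1_M005 = 9, C2_M010 = -10, C3_M015 = 9.5, C4_M003 = 11,
               C5_M018 = -9)
  sim_config(
    n_animals = 300L,
    chromosomes = tibble::tibble(chr = paste0("C", 1:5),
                                 n_markers = 20L, length_cM = 100),
    residual_sd_by_age = seq(0.1, 0.4, length.out = 7),
    true_effects = list(alpha1 = effects),
    trait_noise_sd = if (het) c(alpha1 = 4, alpha2 = 0, alpha3 = 0)
                     else c(alpha1 = 0, alpha2 = 0, alpha3 = 0),
    het_scale = if (het) 1.5 else 0,
    seed = seed
  )
}
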