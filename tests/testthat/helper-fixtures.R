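# Small in-code fixtures shared across the suite.

# Per-centre results table for one trait.
make_results <- function(effect_sizes, q_values, trait_id = "trait_a",
                         n_per_sex = 50L) {
  k <- length(effect_sizes)
  data.frame(centre_id = sprintf("C%02d", seq_len(k)),
             trait_id = trait_id,
             n_male = n_per_sex, n_female = n_per_sex,
             effect_size = effect_sizes,
             effect_se = vapply(effect_sizes, effect_se, numeric(1),
                                n_a = n_per_sex, n_b = n_per_sex),
             p_value = q_values,
             q_value = q_values,
             stringsAsFactors = FALSE)
}

# One-centre, one-trait measurement frame with explicit groups.
make_group <- function(males, females, bw = 20, batch = "2024-01-01",
                       centre = "C01", trait = "trait_a") {
  n <- length(males) + length(females)
  data.frame(centre_id = centre,
             specimen_id = sprintf("%s_%03d", centre, seq_len(n)),
             sex = rep(c("male", "female"), c(length(males), length(females))),
             body_weight = rep_len(bw, n),
             batch = rep_len(batch, n),
             strain = "C57BL/6N",
             trait_id = trait,
             value = c(males, females),
             stringsAsFactors = FALSE)
}

# Minimal single-centre simulation (no batch structure -> fast OLS path).
quick_config <- function(true_d, n_per_sex = 100L, seed = 1L) {
  simulation_config(n_centres = 1L,
                    traits = list(list(trait_id = "t", true_d = true_d,
                                       beta_bw = 0.03)),
                    n_per_sex = n_per_sex, n_batches = 1L, batch_sd = 0,
                    seed = seed)
}

# Direct transcription of the scoring rule, kept deliberately separate
# from the package implementation for oracle checks.
score_oracle <- function(q, rho, M, c = 3, q_hat = 0.05, rho_hat = 0.5) {
  m_bar <- length(q)
  if (m_bar <= c) return(NA_real_)
  if (abs(sum(sign(rho))) <= c) return(1)
  sum(q * sqrt(abs(rho))) / (m_bar^2 * q_hat * sqrt(rho_hat)) *
    max(M / 2, m_bar)
}

# Brute-force step-up FDR definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m),
                     function(i) min(1, min(sorted[i:m] * m / (i:m))),
                     numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}
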