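# shared fixtures: small pedigrees and simulation configs built in code

trio_ped <- function() {
  as_pedigree(data.frame(animal = c("S", "D", "O"), sire = c(0, 0, "S"),
                         dam = c(0, 0, "D"), sex = c("M", "F", "M"),
                         stringsAsFactors = FALSE))
}

# random-mating pedigree: nf founders then no offspring generations with
# parents drawn from the previous generation
random_mating_ped <- function(n_founders = 10, n_offspring = 40, gens = 2,
                              seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  df <- data.frame(animal = ids, sire = "0", dam = "0", sex = sex,
                   stringsAsFactors = FALSE)
  per_gen <- ceiling(n_offspring / gens)
  k <- n_founders
  for (g in seq_len(gens)) {
    males <- df$animal[df$sex == "M"]
    females <- df$animal[df$sex == "F"]
    for (j in seq_len(per_gen)) {
      k <- k + 1
      df <- rbind(df, data.frame(
        animal = sprintf("P%03d", k),
        sire = sample(males, 1), dam = sample(females, 1),
        sex = sample(c("M", "F"), 1), stringsAsFactors = FALSE))
    }
  }
  as_pedigree(df)
}

# small single-disease-trait config for threshold fits
small_disease_config <- function(seed, n_sires = 30, n_dams = 90,
                                 kits = 6, sigma2_a = c(S = 0.3, Ch = 0.3),
                                 sigma2_litter = c(S = 0.1, Ch = 0.1),
                                 prevalence = c(S = 0.3, Ch = 0.3)) {
  sim_config(
    n_sires = n_sires, n_dams = n_dams, parities = 1, kits_per_litter = kits,
    n_batches = 6, fraction_batches_ch = 0, seed = seed,
    composite_resist = FALSE, production = NULL, fostering_rate = 0,
    diseases = list(resist = disease_trait(
      "resist", sigma2_a, sigma2_litter, prevalence = prevalence,
      r_env = 1)))
}
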