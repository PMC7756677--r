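# the 20-dog erythrocyte comparison, reconstructed from its printed
# summary statistics (n = 20, mean difference -0.012, SD 0.047)
dog_summary <- function() diff_summary(20, -0.012, 0.047)

dog_sample <- function(seed = 3) {
  calibrate_to_summary(
    generate_paired_fixture(20, true_bias = -0.012, sd_diff = 0.047,
                            base_level = 6, base_sd = 0.5, seed = seed),
    target_mean = -0.012, target_sd = 0.047)
}

# random difference summaries for property tests
random_summaries <- function(n_cases, seed = 2024) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    diff_summary(sample(5:200, 1),
                 stats::rnorm(1, 0, 10),
                 stats::runif(1, 0.01, 10))
  })
}

# exactly log-normal paired sample: log10 differences have the given
# mean and SD by construction (calibrated on the log scale)
lognormal_sample <- function(n = 12, log_mean = 0.1, log_sd = 0.25,
                             seed = 11) {
  set.seed(seed)
  lt <- stats::rnorm(n, log10(0.05), 0.5)
  ld <- stats::rnorm(n, log_mean, log_sd)
  ld <- log_mean + (ld - mean(ld)) * (log_sd / stats::sd(ld))
  paired_sample(10^(lt + ld), 10^lt)
}

write_temp_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
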