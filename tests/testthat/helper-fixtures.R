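# Shared fixtures and independent oracles, built in code at test time.

# Simple right-censored Cox data with known coefficients.
sim_cox_data <- function(n, beta, censor_rate = 0.5, seed = 1) {
  withr::with_seed(seed, {
    p <- length(beta)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    death <- rexp(n, rate = exp(drop(x %*% beta)))
    censor <- rexp(n, rate = censor_rate)
    data.frame(x, time = pmin(death, censor),
               status = as.integer(death <= censor))
  })
}

# Brute-force all-pairs Harrell C-index: the independent oracle.
brute_force_cindex <- function(time, status, risk) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (time[i] == time[j]) next
      first <- if (time[i] < time[j]) i else j
      second <- if (time[i] < time[j]) j else i
      if (status[first] != 1L) next
      den <- den + 1
      if (risk[first] > risk[second]) num <- num + 1
      else if (risk[first] == risk[second]) num <- num + 0.5
    }
  }
  num / den
}

# A tiny engineered-style dataset for fast model fits: a handful of the
# real predictor columns with a strong planted effect on creatinine_max.
mini_engineered <- function(n = 300, seed = 1, beta_creat = 1.2) {
  withr::with_seed(seed, {
    df <- data.frame(
      creatinine_max = rlnorm(n, log(0.45), 0.4),
      urea_max = rlnorm(n, log(33), 0.4),
      age_at_surgery = round(rlnorm(n, log(200), 1)),
      open_thorax = factor(sample(c("no", "yes"), n, TRUE, c(0.9, 0.1)),
                           levels = c("no", "yes")),
      disease_group = factor(sample(DISEASE_GROUPS, n, TRUE,
                                    c(0.04, 0.09, 0.22, 0.65)),
                             levels = DISEASE_GROUPS)
    )
    lp <- beta_creat * scale(df$creatinine_max)[, 1] +
      0.5 * (df$open_thorax == "yes")
    death <- rweibull(n, shape = 1.2, scale = 30 * exp(-lp / 1.2))
    discharge <- rlnorm(n, log(8), 0.6)
    df$time <- pmin(death, discharge)
    df$status <- as.integer(death <= discharge)
    df
  })
}

# Memoised reduced-profile end-to-end run on the default synthetic cohort,
# shared by the acceptance checks so the heavy pipeline runs once.
e2e_cache <- new.env(parent = emptyenv())
get_default_e2e_run <- function() {
  if (is.null(e2e_cache$run)) {
    outdir <- file.path(tempdir(), "survxplain_e2e")
    config <- pipeline_config(cohort = cohort_spec(seed = 2024L),
                              outdir = outdir, seed = 7L,
                              profile = "reduced")
    e2e_cache$run <- run_end_to_end(config)
  }
  e2e_cache$run
}
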