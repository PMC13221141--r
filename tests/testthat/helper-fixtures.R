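# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# tiny hand-built failure dataset with known group sizes
make_grouped_dataset <- function(sizes = c(5, 10, 15),
                                 temps = seq(35, by = 2,
                                             length.out = length(sizes))) {
  rows <- mapply(function(n, T) {
    data.frame(species = "sp", temperature = T,
               time = exp(seq(0.5, 1.5, length.out = n)) * 10,
               trial_id = paste0("tr", T))
  }, sizes, temps, SIMPLIFY = FALSE)
  failure_dataset(do.call(rbind, rows))
}

# default synthetic generator truth, shared across tests
truth_pars <- list(beta0 = 35.6, beta1 = -0.9, gamma0 = 4.7, gamma1 = -0.1)

truth_model <- function() {
  tdt_model(truth_pars$beta0, truth_pars$beta1, truth_pars$gamma0,
            truth_pars$gamma1)
}

# exact TDT regression object for hand-computed predictions:
# t50(T) = exp(intercept + slope * T)
exact_tdt <- function(intercept, slope) {
  structure(list(slope = slope, intercept = intercept, r_squared = 1,
                 residuals = numeric(0), table = NULL),
            class = "tdt_regression")
}
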