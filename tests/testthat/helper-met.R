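# Small fixtures built in code.

# Fully enumerated toy dataset from explicit effect values (no RNG), so
# brute-force oracles can be written against the same numbers.
toy_met <- function(G = 3, E = 2, R = 2, mu = 10,
                    g = seq_len(G) - mean(seq_len(G)),
                    e = (seq_len(E) - mean(seq_len(E))) * 2,
                    ge = matrix(0, G, E),
                    block = matrix(0, E, R),
                    eps = array(0, dim = c(G, E, R))) {
  grid <- expand.grid(GEN = paste0("G", seq_len(G)),
                      ENV = paste0("E", seq_len(E)),
                      REP = paste0("R", seq_len(R)),
                      stringsAsFactors = FALSE)
  i <- as.integer(sub("G", "", grid$GEN))
  j <- as.integer(sub("E", "", grid$ENV))
  r <- as.integer(sub("R", "", grid$REP))
  grid$Y <- mu + g[i] + e[j] + ge[cbind(i, j)] + block[cbind(j, r)] +
    eps[cbind(i, j, r)]
  met_data(grid[, c("ENV", "GEN", "REP", "Y")], traits = "Y")
}

# Random toy dataset with noise, seeded.
random_met <- function(G = 4, E = 3, R = 2, seed = 11, sd = 1) {
  set.seed(seed)
  toy_met(G, E, R,
          g = rnorm(G), e = rnorm(E),
          ge = matrix(rnorm(G * E), G, E),
          eps = array(rnorm(G * E * R, sd = sd), dim = c(G, E, R)))
}

trial_design_config <- function(seed, ...) {
  synth_config(n_gen = 30, n_env = 6, n_rep = 6,
               mu = 938, sigma2_g = 25425, sigma2_gei = 1663,
               sigma2_e = 2374, seed = seed, ...)
}
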