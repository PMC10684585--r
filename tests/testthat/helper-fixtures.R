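# Shared fixtures, all generated in code.

# the 2x2 worked distribution with maximal correlation exactly 0.6
worked_pmf <- function() joint_pmf(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2))

# random strictly-positive joint pmf
random_pmf <- function(nx, ny) {
  m <- matrix(stats::rexp(nx * ny) + 1e-3, nx, ny)
  joint_pmf(m / sum(m))
}

# product (independent) pmf from two marginals
product_pmf <- function(px, py) joint_pmf(outer(px / sum(px), py / sum(py)))

# the d = 1 worked ensemble: feature (-1,-1,+1,+1), labels (0,0,1,1)
worked_bank <- function() {
  feature_bank("s1", paste0("a", 1:4), matrix(c(-1, -1, 1, 1), 4, 1))
}
worked_few_shot <- function() {
  few_shot_set(paste0("a", 1:4), c("0", "0", "1", "1"))
}

# small fast scenario for pipeline tests
tiny_scenario <- function(seed = 1L) {
  make_scenario(scenario_spec(n_sources = 2L, n_classes = 3L,
                              feature_dim = 8L, separations = c(3, 0),
                              noise_sd = 1, seed = seed))
}
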