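# Monte-Carlo efficiency tables are expensive enough to share between
# module tests and the acceptance suite; compute each configuration once.

mc_table <- local({
  cache <- list()
  function(rho, n = 200, reps = 2000, seed = 202) {
    key <- paste(rho, n, reps, seed, sep = "|")
    if (is.null(cache[[key]])) {
      spec <- population_spec(
        N = 1e5, times = 1,
        study = data.frame(name = "y", mean = 10, sd = 2, phi = 0),
        aux = data.frame(name = "a", type = "continuous", rho = rho,
                         study = "y", time = 1)
      )
      cache[[key]] <<- monte_carlo_efficiency(spec, n = n, reps = reps,
                                              seed = seed)
    }
    cache[[key]]
  }
})
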