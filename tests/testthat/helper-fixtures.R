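# shared fixtures, all built in code

universal_profile <- function(...) species_profile(name = "testsp", ...)

linear_cooling <- function(rate = 0.5, t_start = 18)
  cooling_schedule("linear", t_start = t_start, rate = rate)

constant_night <- function(t_start = 18)
  cooling_schedule("constant", t_start = t_start)

# small multi-species dataset for pipeline tests
small_dataset <- function(seed, n_species = 6, replicates = c(4, 8),
                          sampling = 10, noise_sd = 0.03)
  gen_dataset(n_species = n_species, replicates = replicates,
              sampling = sampling, noise_sd = noise_sd, seed = seed)

# a species aggregate taken exactly from a curve, single sample per bin centre
curve_aggregate <- function(a = 0.08, b = 0.54, hours = 0:9 + 0.5,
                            sem = rep(0, length(hours))) {
  data.frame(species = "exact", bin = floor(hours), h = hours,
             mean_ratio = 1 - a * hours^b, sem = sem,
             n_rep = 1L, h_samples = I(lapply(hours, function(x) list(x))))
}
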