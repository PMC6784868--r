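# Shared synthetic worlds, memoised so expensive objects (in particular
# MCMC fits) are built once per test run.

.world_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (is.null(.world_cache[[name]])) {
    .world_cache[[name]] <- maker()
  }
  .world_cache[[name]]
}

# small world for fast module-level model tests
tiny_world <- function() {
  cached("tiny", function() {
    cfg <- world_config(n_super_regions = 2, regions_per_super = 2,
                        countries_per_region = 2, years = 1998:2009,
                        age_groups = data.frame(age_lo = c(20, 30, 40),
                                                age_hi = c(29, 39, 49)),
                        surveys_per_country = 6, sexes = "female",
                        seed = 11)
    truth <- generate_truth(cfg)
    pop <- generate_population_table(cfg)
    obs <- sample_observations(truth, pop, cfg)
    list(cfg = cfg, truth = truth, pop = pop, obs = obs)
  })
}

tiny_model_config <- function(truth, n_draws = 400, burnin = 200) {
  model_config(truth$hierarchy, truth$years,
               est_age_groups = truth$est_ages,
               n_draws = n_draws, burnin = burnin)
}

tiny_fit <- function() {
  cached("tiny_fit", function() {
    w <- tiny_world()
    cfg <- tiny_model_config(w$truth)
    inputs <- build_model_inputs(w$obs, w$pop, cfg, "female")
    suppressWarnings(fit_mcmc(inputs, cfg, seed = 5))
  })
}

# the default study world: 3 super-regions x 2 regions x 4 countries,
# 33 years, one sex, ~8 surveys per country
default_world <- function() {
  cached("default", function() {
    cfg <- world_config(sexes = "female", seed = 7)
    truth <- generate_truth(cfg)
    pop <- generate_population_table(cfg)
    obs <- sample_observations(truth, pop, cfg)
    list(cfg = cfg, truth = truth, pop = pop, obs = obs)
  })
}

default_world_fit <- function() {
  cached("default_fit", function() {
    w <- default_world()
    cfg <- model_config(w$truth$hierarchy, w$cfg$years,
                        est_age_groups = w$truth$est_ages,
                        n_draws = 1000, burnin = 400)
    inputs <- build_model_inputs(w$obs, w$pop, cfg, "female")
    suppressWarnings(fit_mcmc(inputs, cfg, seed = 11))
  })
}

# noise-free variant of a config: no offsets, no study effects, no extra
# residual noise, enormous effective sample sizes
noise_free <- function(cfg, ...) {
  args <- list(...)
  base <- list(n_super_regions = cfg$n_super_regions,
               regions_per_super = cfg$regions_per_super,
               countries_per_region = cfg$countries_per_region,
               years = cfg$years, age_groups = cfg$age_groups,
               sexes = cfg$sexes, seed = cfg$seed,
               coverage_offsets = c(subnational = 0, community = 0),
               coverage_extra_sd = c(national = 0, subnational = 0,
                                     community = 0),
               study_sd = c(national = 0, subnational = 0, community = 0),
               n_eff_median = 1e14)
  do.call(world_config, utils::modifyList(base, args))
}
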