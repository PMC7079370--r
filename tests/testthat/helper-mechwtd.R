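# shared fixture builders; everything is generated in code at test time

# small fast configuration: desk-scaled default network
tiny_config <- function(duration = 1000, scale = 1 / 40, magnitude = 10000,
                        period = 1000) {
  cfg <- default_config(magnitude = magnitude, period = period,
                        duration = duration)
  if (scale != 1) cfg <- apply_scale(cfg, scale)
  cfg
}

# a one-species inert configuration (no rules) for motion/containment tests
free_config <- function(count = 500, duration = 100, diffusion_step = 0.5,
                        cell_radius = 10, nucleus_radius = 3,
                        extra_radius = 15, compartment = "cytoplasm",
                        init_active = 0, state_rules = NULL) {
  cfg <- default_config(duration = duration)
  cfg$species <- data.frame(name = "X", count = count,
                            init_active = init_active,
                            compartment = compartment, static = FALSE,
                            stringsAsFactors = FALSE)
  cfg$bind_rules <- cfg$bind_rules[0, ]
  cfg$channels <- cfg$channels[0, ]
  cfg$state_rules <- if (is.null(state_rules)) cfg$state_rules[0, ] else
    state_rules
  cfg$geometry <- list(nucleus_radius = nucleus_radius,
                       cell_radius = cell_radius,
                       extracellular_radius = extra_radius)
  cfg$diffusion_step <- diffusion_step
  cfg$stimulus$magnitude <- cfg$stimulus$baseline  # no load channel
  validate_config(cfg)
  cfg
}

# two-species binding configuration: A(active) + B(inactive) -> complex,
# dissociating through a single channel with the given timer
pair_config <- function(nA = 50, nB = 50, duration = 200, R_inter = 1,
                        timer_mean = 10, cell_radius = 10,
                        diffusion_step = 0.5) {
  cfg <- default_config(duration = duration)
  cfg$species <- data.frame(
    name = c("A", "B"), count = c(nA, nB), init_active = c(nA, 0),
    compartment = "cytoplasm", static = FALSE, stringsAsFactors = FALSE)
  cfg$bind_rules <- data.frame(
    name = "AB", a_species = "A", a_active = TRUE, b_species = "B",
    b_active = FALSE, complex = TRUE, a_active_after = TRUE,
    b_active_after = FALSE, stringsAsFactors = FALSE)
  cfg$channels <- data.frame(
    bind_rule = "AB", timer_name = "AB->A+B", stage = 0, mean = timer_mean,
    lo = 0, hi = 2 * timer_mean, a_active_out = TRUE, b_active_out = FALSE,
    dissociate = TRUE, produce = NA_character_, stringsAsFactors = FALSE)
  cfg$state_rules <- cfg$state_rules[0, ]
  cfg$geometry$cell_radius <- cell_radius
  cfg$geometry$extracellular_radius <- cell_radius + 5
  cfg$R_inter <- R_inter
  cfg$diffusion_step <- diffusion_step
  cfg$stimulus$magnitude <- cfg$stimulus$baseline
  validate_config(cfg)
  cfg
}
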