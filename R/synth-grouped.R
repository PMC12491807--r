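#' Generate a grouped (animal/unit) pre/post observation table
#'
#' Simulates the repeated-measures structure of a paired pharmacology
#' experiment: each unit (pericyte or vessel) nested in an animal is
#' measured under both treatment conditions (`"pre"` and `"post"`).
#' Observations follow
#' `y = mu + delta * [post] + a_animal + b_unit + eps` with independent
#' Gaussian components.
#'
#' @param n_animals Number of animals (>= 2).
#' @param units_per_animal Units (pericytes/vessels) per animal.
#' @param trials_per_unit Trials per unit per treatment condition.
#' @param treatment_effect Fixed treatment effect `delta` on the
#'   post condition.
#' @param sd_animal,sd_unit,sd_resid Standard deviations of the animal
#'   random intercept, unit random intercept, and residual (all >= 0).
#' @param mu Grand mean.
#' @param seed Integer seed (uses no global RNG state).
#'
#' @return A list with `table` -- a long-format data frame with columns
#'   `animal_id`, `unit_id`, `compartment`, `branch_order`, `treatment`,
#'   `trial`, `value` -- and `truth` holding `delta` and the variance
#'   components.
#' @export
gen_grouped_observations <- function(n_animals = 7, units_per_animal = 6,
                                     trials_per_unit = 1,
                                     treatment_effect = 1,
                                     sd_animal = 0.5, sd_unit = 0.5,
                                     sd_resid = 1, mu = 10, seed = 1L) {
  stopifnot(n_animals >= 2, units_per_animal >= 1, trials_per_unit >= 1,
            sd_animal >= 0, sd_unit >= 0, sd_resid >= 0)
  withr::with_seed(as.integer(seed), {
    a_eff <- rnorm(n_animals, 0, sd_animal)
    grid <- expand.grid(trial = seq_len(trials_per_unit),
                        treatment = c("pre", "post"),
                        unit = seq_len(units_per_animal),
                        animal = seq_len(n_animals),
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    unit_key <- paste0("a", grid$animal, "_u", grid$unit)
    u_levels <- unique(unit_key)
    u_eff <- rnorm(length(u_levels), 0, sd_unit)
    names(u_eff) <- u_levels
    y <- mu + treatment_effect * (grid$treatment == "post") +
      a_eff[grid$animal] + u_eff[unit_key] +
      rnorm(nrow(grid), 0, sd_resid)
    tab <- data.frame(animal_id = paste0("a", grid$animal),
                      unit_id = unit_key,
                      compartment = "soma",
                      branch_order = 1L,
                      treatment = factor(grid$treatment,
                                         levels = c("pre", "post")),
                      trial = grid$trial,
                      value = y,
                      stringsAsFactors = FALSE)
    list(table = tab,
         truth = list(delta = treatment_effect, mu = mu,
                      sd_animal = sd_animal, sd_unit = sd_unit,
                      sd_resid = sd_resid))
  })
}
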