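# Seeded generators for synthetic qPCR and nodule-count data with the
# replicate structure the analysis assumes, so every pipeline stage is
# testable without external data.

#' Generate a synthetic qPCR Ct table
#'
#' Emulates the data shape of a knockdown-quantification experiment:
#' biological replicates each measured in technical triplicate for a
#' target and a reference gene, in a treatment and a control condition.
#' For each biological replicate a shared sample effect (biological noise)
#' shifts both genes; the target sits `target_offset` cycles above the
#' reference minus `log2(true fold)`, so the Livak analysis recovers the
#' configured fold:
#' `Ct(ref) = baseline + bio; Ct(tgt) = baseline + bio + offset - log2(fold)`,
#' each measurement with independent Gaussian technical noise on the cycle
#' scale.
#'
#' @param true_fold True relative expression in the treatment condition
#'   (control is 1 by construction).
#' @param n_bio,n_tech Biological and technical replicate counts per
#'   condition (defaults 6 and 3).
#' @param baseline_ct Reference-gene Ct level, cycles.
#' @param target_offset Cycles by which the target trails the reference at
#'   fold 1.
#' @param sd_bio,sd_tech Biological and technical noise standard
#'   deviations, cycles.
#' @param seed Optional integer seed; fixed seed gives an identical table.
#' @return A `"ct_table"` (see [as_ct_table()]).
#' @examples
#' tab <- generate_ct_table(0.25, sd_bio = 0, sd_tech = 0)
#' attr(delta_delta_ct(tab), "mean_fold")   # exactly 0.25
#' @export
generate_ct_table <- function(true_fold, n_bio = 6L, n_tech = 3L,
                              baseline_ct = 20, target_offset = 2,
                              sd_bio = 0.5, sd_tech = 0.1, seed = NULL) {
  stopifnot(is.numeric(true_fold), length(true_fold) == 1L, true_fold > 0,
            n_bio >= 1, n_tech >= 1, sd_bio >= 0, sd_tech >= 0,
            baseline_ct > 0)
  if (!is.null(seed)) set.seed(seed)
  conditions <- c(control = 1, treatment = true_fold)
  rows <- list()
  for (cond in names(conditions)) {
    fold <- conditions[[cond]]
    for (b in seq_len(n_bio)) {
      bio <- stats::rnorm(1, 0, sd_bio)
      ref_level <- baseline_ct + bio
      tgt_level <- ref_level + target_offset - log2(fold)
      for (t in seq_len(n_tech)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_b%d", substr(cond, 1, 4), b),
          condition = cond,
          role = c("reference", "target"),
          tech_rep = t,
          ct = c(ref_level, tgt_level) + stats::rnorm(2, 0, sd_tech),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  as_ct_table(do.call(rbind, rows))
}

#' Generate synthetic per-plant nodule counts
#'
#' Emulates the infected-nodule readout of a complementation experiment:
#' plants in groups whose predicted phenotype class sets the mean count —
#' rescued/wild-type roots form infected nodules, mutant roots form almost
#' none ("empty" nodules are not counted).  Counts are i.i.d. Poisson by
#' default; a negative binomial is offered because real per-plant counts
#' are typically overdispersed.
#'
#' @param groups Named character vector mapping group label to phenotype
#'   class (`"wild-type"` or `"mutant"`).
#' @param mean_wt Mean infected nodules per plant for wild-type/rescued
#'   groups (default 8).
#' @param mean_mutant Mean for mutant groups (default 0.2, near zero).
#' @param n_plants Plants per group (default 10).
#' @param distribution `"poisson"` or `"nbinom"`.
#' @param dispersion Negative-binomial size parameter (ignored for
#'   Poisson).
#' @param seed Optional integer seed.
#' @return Data frame `(plant, group, class, count)`.
#' @examples
#' generate_nodule_counts(c(rescued = "wild-type", brush = "mutant"),
#'                        seed = 1)
#' @export
generate_nodule_counts <- function(groups, mean_wt = 8, mean_mutant = 0.2,
                                   n_plants = 10L,
                                   distribution = c("poisson", "nbinom"),
                                   dispersion = 2, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(length(groups) >= 1L, !is.null(names(groups)),
            all(groups %in% .PHENOTYPE_CLASSES),
            mean_wt >= 0, mean_mutant >= 0, n_plants >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(groups), function(g) {
    mu <- if (groups[[g]] == "mutant") mean_mutant else mean_wt
    counts <- switch(distribution,
      poisson = stats::rpois(n_plants, mu),
      nbinom = stats::rnbinom(n_plants, size = dispersion, mu = mu)
    )
    data.frame(
      plant = sprintf("%s_p%02d", g, seq_len(n_plants)),
      group = g,
      class = groups[[g]],
      count = counts,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Generate a self-consistent synthetic scenario suite
#'
#' Bundles the six genotype/intervention scenarios with synthetic data that
#' encode the model parameters end to end: the RNAi scenario's Ct table is
#' generated at true fold equal to the knockdown fraction used by the
#' phenotype calls, and nodule-count means follow the expected phenotype
#' class of each scenario.  Pushing the bundle back through
#' [delta_delta_ct()], [fold_to_knockdown()], [build_pool()] and
#' [call_phenotype()] recovers the generating parameters.
#'
#' @param seed Integer seed driving all randomness in the bundle.
#' @param knockdown_fraction True retained expression after RNAi, encoded
#'   in the Ct data (default 0.25).
#' @param oe_weight Overexpression transgene weight (default 8).
#' @param ... Further arguments passed to [generate_ct_table()] (noise
#'   levels, replicate counts) and applied to the RNAi Ct table.
#' @return A list with elements `scenarios`, `ct_table`, `nodule_counts`
#'   and `manifest` (generating parameters and seed).
#' @examples
#' suite <- generate_scenario_suite(seed = 1)
#' names(suite)
#' @export
generate_scenario_suite <- function(seed, knockdown_fraction = 0.25,
                                    oe_weight = 8, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  scenarios <- default_scenarios(oe_weight = oe_weight,
                                 knockdown_fraction = knockdown_fraction)
  ct <- generate_ct_table(true_fold = knockdown_fraction, seed = seed, ...)
  groups <- vapply(scenarios, `[[`, "", "expected")
  names(groups) <- gsub("[^A-Za-z0-9]+", "_", names(scenarios))
  nodules <- generate_nodule_counts(groups, seed = seed + 1L)
  list(
    scenarios = scenarios,
    ct_table = ct,
    nodule_counts = nodules,
    manifest = list(
      seed = seed,
      knockdown_fraction = knockdown_fraction,
      oe_weight = oe_weight,
      generated = "tetradose::generate_scenario_suite"
    )
  )
}
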