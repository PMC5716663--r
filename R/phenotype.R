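# Penetrance model: maps assembly statistics to phenotype classes and
# encodes the genetic observations as consistency constraints.

.PHENOTYPE_CLASSES <- c("wild-type", "mutant")

#' Define a penetrance model
#'
#' Maps per-cell leaky-tetramer statistics to a phenotype class: a scenario
#' is called `"mutant"` when the statistic reaches the threshold `tau`.
#' Two statistics are offered, reflecting two readings of how much leaky
#' channel a cell tolerates: `"p_any_leaky"` (default) is the probability
#' that a cell of `n` tetramers assembles at least one leaky tetramer — a
#' cell-autonomous hit model; `"expected_leaky_fraction"` is the expected
#' fraction of leaky tetramers.
#'
#' @param tau Phenotype threshold on the statistic, in (0, 1).
#' @param n Tetramers per cell (default 64, the 8 x 8 grid).
#' @param rule An [activity_rule()] or integer `k` (default 4: only the
#'   mutant homotetramer is active).
#' @param statistic `"p_any_leaky"` or `"expected_leaky_fraction"`.
#' @return An object of class `"penetrance_model"`.
#' @examples
#' penetrance_model()
#' @export
penetrance_model <- function(tau = 0.1, n = 64L, rule = activity_rule(4L),
                             statistic = c("p_any_leaky",
                                           "expected_leaky_fraction")) {
  statistic <- match.arg(statistic)
  if (is.numeric(rule)) rule <- activity_rule(rule)
  stopifnot(inherits(rule, "activity_rule"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("'tau' must be a single number strictly between 0 and 1")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer")
  }
  structure(
    list(tau = tau, n = as.integer(n), rule = rule, statistic = statistic),
    class = "penetrance_model"
  )
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf(
    "Penetrance model: %s >= %.3g -> mutant  (n = %d tetramers/cell, k = %d)\n",
    x$statistic, x$tau, x$n, x$rule$k))
  invisible(x)
}

#' Evaluate the penetrance statistic for a pool
#'
#' @param model A [penetrance_model()].
#' @param pool A `"subunit_pool"`.
#' @return The statistic value in \[0, 1\].
#' @export
penetrance_statistic <- function(model, pool) {
  stopifnot(inherits(model, "penetrance_model"))
  switch(model$statistic,
    p_any_leaky = prob_at_least_one_leaky(pool, model$n, model$rule),
    expected_leaky_fraction = as.numeric(leaky_fraction(pool, model$rule))
  )
}

#' Define a genotype/intervention scenario
#'
#' A scenario bundles a genotype and interventions with the phenotype class
#' the corresponding experiment produced, so that a parameterization of the
#' model can be checked against it.
#'
#' @param name Scenario label.
#' @param genotype A [genotype()].
#' @param interventions List of [overexpression()] / [knockdown()] objects.
#' @param expected Expected phenotype class, `"wild-type"` or `"mutant"`.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, genotype, interventions = list(),
                     expected = c("wild-type", "mutant")) {
  expected <- match.arg(expected)
  if (inherits(interventions, "intervention")) {
    interventions <- list(interventions)
  }
  stopifnot(is.character(name), length(name) == 1L,
            inherits(genotype, "cluster_genotype"),
            all(vapply(interventions, inherits, TRUE, "intervention")))
  structure(
    list(name = name, genotype = genotype, interventions = interventions,
         expected = expected),
    class = "scenario"
  )
}

#' The six reported genotype/intervention scenarios
#'
#' The genetic observations the model must reproduce with one
#' parameterization: (1) the heterozygote is wild-type; (2) the homozygote
#' is mutant; (3) constitutive overexpression of a WT cluster gene in the
#' homozygote rescues; (4) RNAi knockdown of the mutant transcript in the
#' homozygote rescues; (5) overexpression of the mutant allele in wild-type
#' recapitulates the phenotype; (6) the premature-stop null homozygote is
#' wild-type.
#'
#' @param oe_weight Transgene expression weight for the overexpression
#'   scenarios, in baseline-weight units (default 8: a strong constitutive
#'   promoter matched to the total native cluster expression of 8 allele
#'   copies).
#' @param knockdown_fraction Retained mutant expression after RNAi
#'   (default 0.25: strong but incomplete silencing).
#' @return A named list of six [scenario()] objects.
#' @export
default_scenarios <- function(oe_weight = 8, knockdown_fraction = 0.25) {
  het <- genotype(BRUSH = c(WT = 1, brush = 1))
  hom <- genotype(BRUSH = c(brush = 2))
  wt <- genotype()
  nul <- genotype(BRUSH = c(null = 2))
  sc <- list(
    scenario("heterozygote", het, expected = "wild-type"),
    scenario("homozygote", hom, expected = "mutant"),
    scenario("homozygote + WT overexpression", hom,
             overexpression("WT", oe_weight), expected = "wild-type"),
    scenario("homozygote + RNAi knockdown", hom,
             knockdown("brush", knockdown_fraction), expected = "wild-type"),
    scenario("wild-type + brush overexpression", wt,
             overexpression("brush", oe_weight), expected = "mutant"),
    scenario("null homozygote", nul, expected = "wild-type")
  )
  stats::setNames(sc, vapply(sc, `[[`, "", "name"))
}

#' Call the phenotype of a scenario under a penetrance model
#'
#' Resolves the scenario to a subunit pool, evaluates the penetrance
#' statistic analytically, and calls `"mutant"` iff statistic >= tau.
#'
#' @param scenario A [scenario()].
#' @param model A [penetrance_model()].
#' @param loci Locus definitions (default [default_loci()]).
#' @return A one-row data frame of class `"phenotype_call"`: scenario name,
#'   mutant subunit fraction `f`, statistic, called class, expected class
#'   and agreement flag.
#' @examples
#' call_phenotype(default_scenarios()[["homozygote"]], penetrance_model())
#' @export
call_phenotype <- function(scenario, model = penetrance_model(),
                           loci = default_loci()) {
  stopifnot(inherits(scenario, "scenario"),
            inherits(model, "penetrance_model"))
  pool <- build_pool(scenario$genotype, loci, scenario$interventions)
  mut <- pool$mutant_class
  f <- if (mut %in% pool$class) pool$frequency[[mut]] else 0
  stat <- penetrance_statistic(model, pool)
  call <- if (stat >= model$tau) "mutant" else "wild-type"
  out <- data.frame(
    scenario = scenario$name,
    f = f,
    statistic = stat,
    call = call,
    expected = scenario$expected,
    agree = call == scenario$expected,
    stringsAsFactors = FALSE
  )
  class(out) <- c("phenotype_call", "data.frame")
  out
}

#' Check a parameterization against all scenarios
#'
#' Evaluates every scenario under one model and reports per-scenario calls,
#' the overall agreement flag, and the feasible threshold interval.
#'
#' @param model A [penetrance_model()].
#' @param scenarios List of [scenario()] objects (default
#'   [default_scenarios()]).
#' @param loci Locus definitions.
#' @return A data frame of class `"consistency_report"` with one row per
#'   scenario; attributes `all_agree` (logical) and `feasible_interval`
#'   (from [feasible_threshold_interval()]).
#' @examples
#' check_consistency(penetrance_model())
#' @export
check_consistency <- function(model = penetrance_model(),
                              scenarios = default_scenarios(),
                              loci = default_loci()) {
  calls <- lapply(scenarios, call_phenotype, model = model, loci = loci)
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  attr(out, "all_agree") <- all(out$agree)
  attr(out, "feasible_interval") <-
    feasible_threshold_interval(scenarios, model, loci)
  attr(out, "model") <- model
  class(out) <- c("consistency_report", "data.frame")
  out
}

#' @export
print.consistency_report <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$f <- signif(df$f, digits)
  df$statistic <- signif(df$statistic, digits)
  print.data.frame(df, row.names = FALSE)
  iv <- attr(x, "feasible_interval")
  cat(sprintf("all scenarios agree: %s\n", attr(x, "all_agree")))
  if (iv$empty) {
    cat("feasible tau interval: empty\n")
  } else {
    cat(sprintf("feasible tau interval: (%.4g, %.4g]\n",
                iv$lower, iv$upper))
  }
  invisible(x)
}

#' Feasible threshold interval for a scenario set
#'
#' The interval of `tau` values under which every scenario is classified as
#' expected: `(max statistic over expected-wild-type scenarios,
#' min statistic over expected-mutant scenarios]`.  Empty when the lower
#' bound reaches the upper.  Because the statistic is monotone in the
#' mutant fraction, any consistent region is a single interval.
#'
#' @param scenarios List of [scenario()] objects; at least one of each
#'   expected class.
#' @param model A [penetrance_model()] supplying `n`, `k` and the statistic
#'   (its `tau` is ignored).
#' @param loci Locus definitions.
#' @return A list with `lower`, `upper`, `empty` and a `contains(tau)`
#'   helper field is not stored; test membership as
#'   `tau > lower && tau <= upper`.
#' @export
feasible_threshold_interval <- function(scenarios,
                                        model = penetrance_model(),
                                        loci = default_loci()) {
  expected <- vapply(scenarios, `[[`, "", "expected")
  if (!all(.PHENOTYPE_CLASSES %in% expected)) {
    stop("need at least one scenario of each expected phenotype class")
  }
  stat <- vapply(scenarios, function(sc) {
    pool <- build_pool(sc$genotype, loci, sc$interventions)
    penetrance_statistic(model, pool)
  }, 0)
  lower <- max(stat[expected == "wild-type"])
  upper <- min(stat[expected == "mutant"])
  list(lower = lower, upper = upper, empty = lower >= upper)
}

#' Penetrance curve over a grid of mutant fractions
#'
#' @param model A [penetrance_model()].
#' @param f_grid Numeric vector of mutant subunit fractions in \[0, 1\].
#' @return A data frame `(f, statistic, call)` sorted by `f`; the statistic
#'   is non-decreasing in `f`.
#' @examples
#' penetrance_curve(penetrance_model(), c(0, 1/8, 1/4, 1/2, 1))
#' @export
penetrance_curve <- function(model = penetrance_model(),
                             f_grid = seq(0, 1, by = 1 / 64)) {
  stopifnot(is.numeric(f_grid), all(f_grid >= 0 & f_grid <= 1))
  f_grid <- sort(f_grid)
  stat <- vapply(f_grid, function(f) {
    penetrance_statistic(model, pool_from_fraction(f))
  }, 0)
  data.frame(
    f = f_grid,
    statistic = stat,
    call = ifelse(stat >= model$tau, "mutant", "wild-type"),
    stringsAsFactors = FALSE
  )
}
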