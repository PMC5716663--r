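# Run configuration, validation, provenance and the high-level analytic /
# simulate / check entry points wrapped by the command-line script.

.default_run_config <- function() {
  list(
    model = list(tau = 0.1, n = 64L, k = 4L, statistic = "p_any_leaky"),
    oe_weight = 8,
    knockdown_fraction = 0.25,
    locus_weights = NULL,
    seed = 1L,
    n_cells = 1e4
  )
}

#' Validate and canonicalise a run configuration
#'
#' Fills defaults and checks every field against the documented schema:
#' `model` (`tau` in (0,1), `n` positive integer, `k` in 1..4, `statistic`
#' one of the two penetrance statistics), `oe_weight` >= 0,
#' `knockdown_fraction` in \[0,1\], optional named `locus_weights`, integer
#' `seed`, positive `n_cells`.
#'
#' @param config A named list, e.g. from [read_run_config()].
#' @return A canonical `"run_config"` list.
#' @export
validate_run_config <- function(config = list()) {
  if (!is.list(config)) stop("config must be a list")
  def <- .default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(def, config)
  m <- cfg$model
  unknown_m <- setdiff(names(m), names(def$model))
  if (length(unknown_m)) {
    stop("unknown model field(s): ", paste(unknown_m, collapse = ", "))
  }
  m <- utils::modifyList(def$model, m)
  if (!is.numeric(m$tau) || m$tau <= 0 || m$tau >= 1) {
    stop("model$tau must lie strictly between 0 and 1")
  }
  if (!is.numeric(m$n) || m$n < 1 || m$n != round(m$n)) {
    stop("model$n must be a positive integer")
  }
  if (!is.numeric(m$k) || !(m$k %in% 1:4)) {
    stop("model$k must be an integer between 1 and 4")
  }
  if (!m$statistic %in% c("p_any_leaky", "expected_leaky_fraction")) {
    stop("model$statistic must be 'p_any_leaky' or 'expected_leaky_fraction'")
  }
  # canonical types, so YAML and JSON round-trips compare identical
  m$tau <- as.numeric(m$tau)
  m$n <- as.integer(m$n)
  m$k <- as.integer(m$k)
  cfg$model <- m
  if (!is.numeric(cfg$oe_weight) || cfg$oe_weight < 0) {
    stop("oe_weight must be non-negative")
  }
  if (!is.numeric(cfg$knockdown_fraction) || cfg$knockdown_fraction < 0 ||
      cfg$knockdown_fraction > 1) {
    stop("knockdown_fraction must lie in [0, 1]")
  }
  if (!is.null(cfg$locus_weights)) {
    lw <- unlist(cfg$locus_weights)
    if (is.null(names(lw)) || !is.numeric(lw) || any(lw < 0)) {
      stop("locus_weights must be a named list of non-negative numbers")
    }
    cfg$locus_weights <- lw
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed)) {
    stop("seed must be a single integer")
  }
  if (!is.numeric(cfg$n_cells) || cfg$n_cells < 1) {
    stop("n_cells must be a positive number")
  }
  cfg$oe_weight <- as.numeric(cfg$oe_weight)
  cfg$knockdown_fraction <- as.numeric(cfg$knockdown_fraction)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_cells <- as.numeric(cfg$n_cells)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; format inferred from the extension.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare key `n:` as boolean FALSE; restore the field name
  if (is.list(raw$model) && "FALSE" %in% names(raw$model)) {
    names(raw$model)[names(raw$model) == "FALSE"] <- "n"
  }
  validate_run_config(raw)
}

.config_pieces <- function(config) {
  config <- validate_run_config(unclass(config))
  list(
    config = config,
    model = penetrance_model(
      tau = config$model$tau, n = config$model$n,
      rule = activity_rule(config$model$k),
      statistic = config$model$statistic
    ),
    scenarios = default_scenarios(
      oe_weight = config$oe_weight,
      knockdown_fraction = config$knockdown_fraction
    ),
    loci = default_loci(config$locus_weights)
  )
}

# FNV-1a over the deparsed config: a dependency-free fingerprint for
# provenance blocks (not cryptographic)
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Machine-readable provenance block for a run
#'
#' @param config A `"run_config"`.
#' @return List with package version, config hash and seed — sufficient to
#'   reproduce outputs byte-for-byte.
#' @export
run_provenance <- function(config) {
  config <- validate_run_config(unclass(config))
  list(
    package = "tetradose",
    version = as.character(utils::packageVersion("tetradose")),
    config_hash = .config_hash(config),
    seed = config$seed
  )
}

#' Analytic report over the scenario suite
#'
#' For every scenario: the mutant subunit fraction, the homotetramer
#' probability in odds form (`"1:4096"` for the heterozygote, `"1:256"`
#' for the homozygote under the defaults), and the penetrance statistic
#' and call.
#'
#' @param config A `"run_config"` or plain list (validated).
#' @return Data frame with one row per scenario; attribute `provenance`.
#' @examples
#' run_analytic(list())
#' @export
run_analytic <- function(config = list()) {
  p <- .config_pieces(config)
  rows <- lapply(p$scenarios, function(sc) {
    pool <- build_pool(sc$genotype, p$loci, sc$interventions)
    hp <- homotetramer_probability(pool)
    odds <- tryCatch(odds_form(hp),
                     tetradose_infinite_odds = function(e) "1:Inf")
    cbind(
      call_phenotype(sc, p$model, p$loci)[, c("scenario", "f")],
      data.frame(homotetramer_prob = as.numeric(hp), odds = odds,
                 statistic = penetrance_statistic(p$model, pool),
                 stringsAsFactors = FALSE),
      call_phenotype(sc, p$model, p$loci)[, c("call", "expected")]
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "provenance") <- run_provenance(p$config)
  out
}

#' Monte Carlo summary of leaky-tetramer counts
#'
#' Simulates `n_cells` cells for each scenario-relevant mutant fraction and
#' reports empirical mean and variance of the per-cell leaky count and the
#' empirical P(>= 1 leaky), side by side with their analytic expectations.
#'
#' @param config A `"run_config"` or plain list.
#' @param f Mutant fractions to simulate (default: heterozygote 1/8 and
#'   homozygote 1/4).
#' @return Data frame with one row per `f`; attribute `provenance`.
#' @examples
#' run_simulate(list(n_cells = 2000))
#' @export
run_simulate <- function(config = list(), f = c(1 / 8, 1 / 4)) {
  p <- .config_pieces(config)
  cfg <- p$config
  rows <- lapply(seq_along(f), function(i) {
    pool <- pool_from_fraction(f[i])
    counts <- simulate_cells(pool, cfg$n_cells, n = cfg$model$n,
                             rule = p$model$rule,
                             seed = cfg$seed + i - 1L)
    p_leaky <- as.numeric(leaky_fraction(pool, p$model$rule))
    data.frame(
      f = f[i],
      n_cells = cfg$n_cells,
      mean_leaky = mean(counts),
      var_leaky = stats::var(counts),
      expected_leaky = cfg$model$n * p_leaky,
      p_any_leaky = mean(counts >= 1),
      expected_p_any = 1 - (1 - p_leaky)^cfg$model$n
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "provenance") <- run_provenance(cfg)
  out
}

#' Scenario consistency check with status code
#'
#' Runs [check_consistency()] under the configured model and reports a
#' CLI-style status: 0 when all scenarios agree, 2 when the model is
#' inconsistent with at least one observation (or the feasible threshold
#' interval is empty).
#'
#' @param config A `"run_config"` or plain list.
#' @return The `"consistency_report"`, with extra attributes `status` and
#'   `provenance`.
#' @examples
#' attr(run_check(list()), "status")        # 0
#' attr(run_check(list(model = list(k = 1))), "status")  # 2
#' @export
run_check <- function(config = list()) {
  p <- .config_pieces(config)
  rep <- check_consistency(p$model, p$scenarios, p$loci)
  iv <- attr(rep, "feasible_interval")
  attr(rep, "status") <- if (attr(rep, "all_agree") && !iv$empty) 0L else 2L
  attr(rep, "provenance") <- run_provenance(p$config)
  rep
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
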