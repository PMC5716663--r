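# Tetramer assembly: analytic multinomial composition distributions and
# seeded Monte Carlo, in infinite-pool (i.i.d. draws) and finite-pool
# (subunit-conserving partition) modes.

.TETRAMER_SIZE <- 4L

# all weak compositions of `total` into `k` ordered parts, as a matrix with
# one row per composition; C(total + k - 1, k - 1) rows
.compositions <- function(total, k) {
  if (k == 1L) return(matrix(total, ncol = 1L))
  out <- NULL
  for (first in total:0) {
    rest <- .compositions(total - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  dimnames(out) <- NULL
  out
}

#' Exact distribution of tetramer compositions from a subunit pool
#'
#' Under random assembly each of the four subunit slots is filled by an
#' independent draw from the pool, so the composition (count per subunit
#' class) follows a multinomial distribution with 4 trials.  Probabilities
#' are exact rationals whenever the pool is exact.
#'
#' @param pool A `"subunit_pool"`.
#' @return A data frame of class `"composition_distribution"`: one count
#'   column per subunit class, plus `prob` and (in exact mode) `num`/`den`
#'   columns with the probability as a reduced fraction.
#' @examples
#' composition_distribution(pool_from_fraction(1 / 4))
#' @export
composition_distribution <- function(pool) {
  stopifnot(inherits(pool, "subunit_pool"))
  k <- length(pool$class)
  comp <- .compositions(.TETRAMER_SIZE, k)
  coef <- apply(comp, 1L, function(cc) {
    factorial(.TETRAMER_SIZE) / prod(factorial(cc))
  })

  num <- den <- rep(NA_real_, nrow(comp))
  exact <- FALSE
  if (pool$exact) {
    D <- Reduce(.lcm2, pool$den, accumulate = FALSE)
    a <- pool$num * (D / pool$den)  # f_i = a_i / D, sum(a) == D
    D4 <- D^.TETRAMER_SIZE
    if (D4 <= .MAX_EXACT) {
      exact <- TRUE
      for (i in seq_len(nrow(comp))) {
        r <- .rat(coef[i] * prod(a^comp[i, ]), D4)
        if (is.null(r)) { exact <- FALSE; break }
        num[i] <- r[[1]]; den[i] <- r[[2]]
      }
    }
  }

  prob <- if (exact) num / den else {
    apply(comp, 1L, function(cc) stats::dmultinom(cc, prob = pool$frequency))
  }
  out <- as.data.frame(comp)
  names(out) <- pool$class
  out$prob <- prob
  if (exact) { out$num <- num; out$den <- den }
  attr(out, "pool") <- pool
  attr(out, "exact") <- exact
  class(out) <- c("composition_distribution", "data.frame")
  out
}

# wrap a probability with its exact fraction, when known
.exact_prob <- function(value, num = NULL, den = NULL) {
  attr(value, "num") <- if (!is.null(num)) num else NULL
  attr(value, "den") <- if (!is.null(den)) den else NULL
  class(value) <- "tetra_prob"
  value
}

#' @export
print.tetra_prob <- function(x, ...) {
  num <- attr(x, "num"); den <- attr(x, "den")
  if (!is.null(num)) {
    cat(sprintf("%s/%s (= %.6g)\n", format(num, scientific = FALSE),
                format(den, scientific = FALSE), as.numeric(x)))
  } else {
    cat(sprintf("%.6g\n", as.numeric(x)))
  }
  invisible(x)
}

#' Probability that a tetramer is a homotetramer of one class
#'
#' Equals `f^4` for the class frequency `f`: with the mutant fraction 1/8 of
#' a heterozygote this is 1/4096, and with the 1/4 of a homozygote, 1/256.
#'
#' @param pool A `"subunit_pool"`.
#' @param class Subunit class (default the pool's mutant class).
#' @return The probability, carrying exact `num`/`den` attributes when the
#'   pool is exact.
#' @examples
#' homotetramer_probability(pool_from_fraction(1 / 8))  # 1/4096
#' @export
homotetramer_probability <- function(pool, class = pool$mutant_class) {
  stopifnot(inherits(pool, "subunit_pool"))
  i <- match(class, pool$class)
  if (is.na(i)) stop("class '", class, "' not present in pool")
  if (pool$exact) {
    r <- .rat_pow(c(pool$num[i], pool$den[i]), .TETRAMER_SIZE)
    if (!is.null(r)) {
      return(.exact_prob(.rat_value(r), r[[1]], r[[2]]))
    }
  }
  .exact_prob(pool$frequency[[i]]^.TETRAMER_SIZE)
}

#' Activity rule for leaky tetramers
#'
#' A tetramer counts as leaky (phenotype-triggering) when it contains at
#' least `k` mutant subunits.  The default `k = 4` encodes the model in
#' which only the mutant homotetramer is inappropriately active and all
#' mixed tetramers are silent; smaller `k` is an exploratory alternative.
#'
#' @param k Minimum number of mutant subunits (integer, 1--4).
#' @return An object of class `"activity_rule"`.
#' @export
activity_rule <- function(k = 4L) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > 4) {
    stop("'k' must be an integer between 1 and 4")
  }
  structure(list(k = as.integer(k)), class = "activity_rule")
}

#' Probability that a random tetramer is leaky
#'
#' Sums the multinomial composition masses with mutant-subunit count >= k;
#' equivalently the upper tail of the Binomial(4, f) marginal of the mutant
#' class.  For `k = 4` this is [homotetramer_probability()].
#'
#' @param pool A `"subunit_pool"`.
#' @param rule An [activity_rule()] or integer `k`.
#' @param class Mutant class name.
#' @return Probability with exact fraction attributes when available.
#' @examples
#' leaky_fraction(pool_from_fraction(1 / 4))                    # 1/256
#' leaky_fraction(pool_from_fraction(1 / 4), activity_rule(1))  # 175/256
#' @export
leaky_fraction <- function(pool, rule = activity_rule(4L),
                           class = pool$mutant_class) {
  stopifnot(inherits(pool, "subunit_pool"))
  if (is.numeric(rule)) rule <- activity_rule(rule)
  k <- rule$k
  i <- match(class, pool$class)
  if (is.na(i)) stop("class '", class, "' not present in pool")
  if (pool$exact) {
    a <- .rat(pool$num[i], pool$den[i])
    b <- .rat(pool$den[i] - pool$num[i], pool$den[i])
    terms <- lapply(k:.TETRAMER_SIZE, function(j) {
      t <- .rat_mul(.rat(choose(.TETRAMER_SIZE, j), 1),
                    .rat_mul(.rat_pow(a, j), .rat_pow(b, .TETRAMER_SIZE - j)))
      t
    })
    s <- .rat_sum(terms)
    if (!is.null(s)) return(.exact_prob(.rat_value(s), s[[1]], s[[2]]))
  }
  f <- pool$frequency[[i]]
  .exact_prob(sum(stats::dbinom(k:.TETRAMER_SIZE, .TETRAMER_SIZE, f)))
}

#' Render a probability in "1:N" odds form
#'
#' The presentation used for homotetramer probabilities: `N = 1/p`, printed
#' exactly when `p` is an exact rational with unit numerator (so 1/4096
#' becomes `"1:4096"`), otherwise rounded to `digits` decimal places.
#'
#' @param p A probability in (0, 1\], e.g. from
#'   [homotetramer_probability()].
#' @param digits Decimal places for the inexact case.
#' @return A string `"1:N"`.  A zero probability raises a condition of
#'   class `"tetradose_infinite_odds"` (there is no finite N).
#' @examples
#' odds_form(homotetramer_probability(pool_from_fraction(1 / 8)))
#' @export
odds_form <- function(p, digits = 2) {
  v <- as.numeric(p)
  if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
    stop("'p' must be a single probability in [0, 1]")
  }
  if (v == 0) {
    stop(errorCondition(
      "odds are infinite: the probability is zero",
      class = c("tetradose_infinite_odds", "error", "condition")
    ))
  }
  num <- attr(p, "num"); den <- attr(p, "den")
  if (!is.null(num) && num == 1) {
    return(paste0("1:", format(den, scientific = FALSE)))
  }
  N <- 1 / v
  if (N == round(N)) {
    paste0("1:", format(N, scientific = FALSE))
  } else {
    sprintf("1:%.*f", digits, N)
  }
}

#' Per-cell probability of at least one leaky tetramer
#'
#' For a cell assembling `n` tetramers independently (infinite-pool model),
#' returns `1 - (1 - p_leaky)^n` — the package's default cell-level
#' penetrance statistic.
#'
#' @inheritParams leaky_fraction
#' @param n Tetramers per cell (default 64, the illustrative 8 x 8 grid).
#' @return A probability.
#' @examples
#' prob_at_least_one_leaky(pool_from_fraction(1 / 4))  # ~0.2215
#' @export
prob_at_least_one_leaky <- function(pool, n = 64L, rule = activity_rule(4L),
                                    class = pool$mutant_class) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  p <- as.numeric(leaky_fraction(pool, rule, class))
  1 - (1 - p)^n
}

# largest-remainder rounding of 4n * f to integer per-class subunit counts;
# ties broken by class order (earlier class wins)
.finite_pool_counts <- function(pool, n) {
  total <- .TETRAMER_SIZE * n
  target <- pool$frequency * total
  base <- floor(target)
  short <- total - sum(base)
  if (short > 0) {
    rem <- target - base
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), pool$class)
}

#' Simulate the tetramer complement of one cell
#'
#' In `"infinite"` mode each tetramer is an independent multinomial draw of
#' 4 subunits from the pool frequencies.  In `"finite"` mode the pool is
#' first fixed to integer per-class counts summing to `4n`
#' (largest-remainder rounding) and a uniformly random partition of that
#' subunit multiset into `n` unordered 4-subsets is drawn, so subunits are
#' conserved exactly.
#'
#' @param pool A `"subunit_pool"`.
#' @param n Number of tetramers in the cell (default 64).
#' @param mode `"infinite"` or `"finite"`.
#' @param seed Optional integer seed; recorded in the result.
#' @return An object of class `"cell_assembly"`: an `n x k` count matrix
#'   `composition` plus the mode, seed and pool.
#' @examples
#' simulate_cell(pool_from_fraction(1 / 4), seed = 1)
#' @export
simulate_cell <- function(pool, n = 64L, mode = c("infinite", "finite"),
                          seed = NULL) {
  stopifnot(inherits(pool, "subunit_pool"),
            is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  k <- length(pool$class)
  if (mode == "infinite") {
    counts <- t(stats::rmultinom(n, .TETRAMER_SIZE, pool$frequency))
  } else {
    supply <- .finite_pool_counts(pool, n)
    if (sum(supply) != .TETRAMER_SIZE * n) {
      stop("finite-pool rounding failed to conserve subunits")
    }
    subunits <- sample(rep.int(seq_len(k), supply))
    grp <- rep(seq_len(n), each = .TETRAMER_SIZE)
    counts <- matrix(0L, nrow = n, ncol = k)
    tab <- table(factor(grp, levels = seq_len(n)),
                 factor(subunits, levels = seq_len(k)))
    counts[] <- as.integer(tab)
  }
  colnames(counts) <- pool$class
  structure(
    list(composition = counts, n = n, mode = mode, seed = seed, pool = pool),
    class = "cell_assembly"
  )
}

#' @export
print.cell_assembly <- function(x, ...) {
  cat(sprintf("Cell assembly: %d tetramers (%s-pool mode%s)\n", x$n, x$mode,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  print(utils::head(x$composition, 4L))
  if (x$n > 4L) cat("  ...\n")
  invisible(x)
}

#' Count leaky tetramers in a cell assembly
#'
#' @param cell A `"cell_assembly"`.
#' @param rule An [activity_rule()] or integer `k`.
#' @param class Mutant class name.
#' @return Integer count of tetramers with >= k mutant subunits.
#' @export
leaky_count <- function(cell, rule = activity_rule(4L),
                        class = cell$pool$mutant_class) {
  stopifnot(inherits(cell, "cell_assembly"))
  if (is.numeric(rule)) rule <- activity_rule(rule)
  i <- match(class, colnames(cell$composition))
  if (is.na(i)) stop("class '", class, "' not present in assembly")
  sum(cell$composition[, i] >= rule$k)
}

#' Monte Carlo leaky-tetramer counts over many cells
#'
#' Simulates the per-cell number of leaky tetramers for `n_cells`
#' independent cells of `n` tetramers each, under the infinite-pool model.
#' The mutant-subunit count of each tetramer is drawn from its exact
#' Binomial(4, f) marginal, which is equivalent to (and far cheaper than)
#' storing the full multinomial composition of every tetramer.
#'
#' @param pool A `"subunit_pool"`.
#' @param n_cells Number of cells to simulate.
#' @param n Tetramers per cell.
#' @param rule An [activity_rule()] or integer `k`.
#' @param class Mutant class name.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n_cells`: leaky tetramers per cell.
#' @examples
#' counts <- simulate_cells(pool_from_fraction(1 / 4), 1000, seed = 1)
#' mean(counts)          # ~ 64/256 = 0.25
#' mean(counts >= 1)     # ~ 1 - (255/256)^64
#' @export
simulate_cells <- function(pool, n_cells, n = 64L, rule = activity_rule(4L),
                           class = pool$mutant_class, seed = NULL) {
  stopifnot(inherits(pool, "subunit_pool"),
            is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
  if (is.numeric(rule)) rule <- activity_rule(rule)
  i <- match(class, pool$class)
  if (is.na(i)) stop("class '", class, "' not present in pool")
  if (!is.null(seed)) set.seed(seed)
  f <- pool$frequency[[i]]
  draws <- stats::rbinom(n_cells * n, .TETRAMER_SIZE, f)
  leaky <- draws >= rule$k
  as.integer(colSums(matrix(leaky, nrow = n)))
}

#' Render a cell assembly as a character grid
#'
#' One symbol per subunit, four per tetramer, arranged in a square grid
#' when `n` is a perfect square (the default 64 gives the familiar 8 x 8
#' layout).  Mutant subunits print as `b`, WT as `.`, other classes by
#' their first letter.
#'
#' @param cell A `"cell_assembly"`.
#' @param symbols Optional named character vector mapping class to symbol.
#' @return Character vector of grid lines (class `"tetramer_grid"`).
#' @export
render_grid <- function(cell, symbols = NULL) {
  stopifnot(inherits(cell, "cell_assembly"))
  cls <- colnames(cell$composition)
  if (is.null(symbols)) {
    symbols <- stats::setNames(substr(cls, 1L, 1L), cls)
    symbols[cls == "WT"] <- "."
    symbols[cls == cell$pool$mutant_class] <- "b"
  }
  tet <- apply(cell$composition, 1L, function(cc) {
    paste(rep(symbols[cls], cc), collapse = "")
  })
  side <- sqrt(cell$n)
  lines <- if (side == round(side)) {
    apply(matrix(tet, nrow = side, byrow = TRUE), 1L, paste, collapse = " ")
  } else {
    tet
  }
  structure(lines, class = "tetramer_grid")
}

#' @export
print.tetramer_grid <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
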