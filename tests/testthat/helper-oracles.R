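# Independent oracles used across the suite.

# Exhaustive enumeration of all ordered 4-draws from a pool given as
# integer per-class counts a (frequencies a / sum(a)).  Returns the exact
# probability numerator of every reachable composition over denominator
# sum(a)^4.  Independent of the package's multinomial code.
oracle_composition <- function(a) {
  k <- length(a)
  slots <- as.matrix(expand.grid(rep(list(seq_len(k)), 4L)))
  key <- apply(slots, 1L, function(dr) paste(tabulate(dr, k), collapse = ","))
  wt <- apply(slots, 1L, function(dr) prod(a[dr]))
  num <- tapply(wt, key, sum)
  list(key = names(num), num = as.numeric(num), den = sum(a)^4)
}

# pool with frequencies a / sum(a)
pool_from_counts <- function(a, classes = paste0("c", seq_along(a)),
                             mutant_class = classes[length(classes)]) {
  subunit_pool(stats::setNames(a / sum(a), classes),
               mutant_class = mutant_class)
}

# composition keys of a composition_distribution, matching oracle keys
dist_keys <- function(cd) {
  cls <- attr(cd, "pool")$class
  apply(as.matrix(cd[, cls, drop = FALSE]), 1L, paste, collapse = ",")
}

# scenario helpers used by several files
het_genotype <- function() genotype(BRUSH = c(WT = 1, brush = 1))
hom_genotype <- function() genotype(BRUSH = c(brush = 2))
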