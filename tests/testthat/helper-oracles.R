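# Independent oracles used across tests.

# Atomic monoisotopic masses, restated independently of the package table.
ORACLE_MASSES <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196)

# Hand-summed monoisotopic mass from a named count vector.
oracle_mass <- function(counts) {
  sum(counts * ORACLE_MASSES[names(counts)])
}

# Brute-force neutral-loss search: enumerate every ordered tuple of losses
# up to max_losses via expand.grid, reduce to multisets, and return the
# best (smallest cardinality, then smallest |delta|) within tolerance.
oracle_fragment <- function(precursor_counts, fragment_mz, losses,
                            max_losses = 3, tol = 0.02) {
  mz0 <- oracle_mass(precursor_counts) - 1.00727646
  best <- NULL
  consider <- function(loss_names) {
    delta <- (mz0 - sum(losses[loss_names])) - fragment_mz
    if (abs(delta) > tol) return()
    if (is.null(best) || length(loss_names) < length(best$losses) ||
        (length(loss_names) == length(best$losses) &&
         abs(delta) < abs(best$delta)))
      best <<- list(losses = sort(loss_names), delta = delta)
  }
  consider(character(0))
  for (k in seq_len(max_losses)) {
    grid <- do.call(expand.grid,
                    c(rep(list(names(losses)), k),
                      list(stringsAsFactors = FALSE)))
    seen <- character(0)
    for (r in seq_len(nrow(grid))) {
      tuple <- sort(as.character(grid[r, ]))
      key <- paste(tuple, collapse = "+")
      if (key %in% seen) next
      seen <- c(seen, key)
      consider(tuple)
    }
  }
  best
}

# Textbook one-way ANOVA from sums of squares.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# Random plausible glycoside-like formula for property tests.
random_formula <- function() {
  counts <- c(C = sample(10:60, 1), H = sample(20:100, 1),
              O = sample(5:30, 1))
  if (stats::runif(1) < 0.3) counts <- c(counts, N = sample(1:3, 1))
  counts
}
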